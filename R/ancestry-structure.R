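#' Long-range-LD region mask
#'
#' Closed genomic intervals excluded before ancestry PCA. The default mask
#' removes the MHC region on chromosome 6 (25-35 Mb) and the large inversion
#' polymorphism on chromosome 8 (7-13 Mb), the two regions whose internal LD
#' is strong enough to dominate genotype principal components.
#'
#' @param chromosome,start,end parallel vectors defining closed intervals
#'   (1-based, inclusive on both ends)
#' @return `data.table` region mask
#' @export
region_mask <- function(chromosome, start, end) {
  if (any(start > end)) stop("mask intervals must have start <= end")
  data.table::data.table(chromosome = as.character(chromosome),
                         start = as.numeric(start), end = as.numeric(end))
}

#' @rdname region_mask
#' @export
default_region_mask <- function() {
  region_mask(c("6", "8"), c(25e6, 7e6), c(35e6, 13e6))
}

#' Exclude variants falling inside masked regions
#'
#' A variant is removed when its position lies inside any masked interval,
#' inclusive of both endpoints. Chromosome labels are compared with and
#' without a "chr" prefix.
#'
#' @param x a [genotype_matrix()] or a variant metadata `data.table`
#' @param mask a [region_mask()] (default [default_region_mask()])
#' @return object of the same kind as `x`, with masked variants removed and a
#'   [filter_log()] attached
#' @export
exclude_regions <- function(x, mask = default_region_mask()) {
  variants <- if (inherits(x, "genotype_matrix")) x$variants else data.table::as.data.table(x)
  chrom <- sub("^chr", "", variants$chromosome)
  inside <- rep(FALSE, nrow(variants))
  for (r in seq_len(nrow(mask))) {
    mc <- sub("^chr", "", mask$chromosome[r])
    inside <- inside | (chrom == mc &
                          variants$position >= mask$start[r] &
                          variants$position <= mask$end[r])
  }
  lg <- list(input = nrow(variants), removed = sum(inside), retained = sum(!inside))
  if (inherits(x, "genotype_matrix")) {
    out <- subset_genotypes(x, variants = !inside)
  } else {
    out <- variants[!inside]
  }
  attr(out, "filter_log") <- lg
  out
}

#' Sliding-window greedy LD pruning
#'
#' Within each window of `window_variants` consecutive variants (per
#' chromosome, position order), while any pair exceeds `r2_max` the member of
#' the worst offending pair with the lower minor-allele frequency is removed
#' (tie: the later position); the window then advances by `step`. The output
#' is a fixed point: re-pruning it changes nothing.
#'
#' @param gm a [genotype_matrix()]
#' @param window_variants window size in variants (> `step`)
#' @param step advance in variants (>= 1)
#' @param r2_max maximum tolerated pairwise r-squared
#' @return a [genotype_matrix()] restricted to the surviving variants, with a
#'   [filter_log()]
#' @export
ld_prune <- function(gm, window_variants = 50L, step = 5L, r2_max = 0.2) {
  stopifnot(window_variants > step, step >= 1L)
  v <- gm$variants
  ord <- order(v$chromosome, v$position)
  keep <- rep(TRUE, nrow(v))
  mafs <- maf(gm)
  d <- gm$dosages
  prune_window <- function(win) {
    removed <- FALSE
    repeat {
      wl <- win[keep[win]]
      if (length(wl) < 2L) break
      cm <- suppressWarnings(stats::cor(d[, wl, drop = FALSE],
                                        use = "pairwise.complete.obs"))^2
      diag(cm) <- 0
      cm[is.na(cm)] <- 0
      mx <- max(cm)
      if (mx <= r2_max) break
      pr <- which(cm == mx, arr.ind = TRUE)[1L, ]
      a <- wl[pr[1L]]; b <- wl[pr[2L]]
      drop <- if (mafs[a] < mafs[b]) a
      else if (mafs[b] < mafs[a]) b
      else if (v$position[a] >= v$position[b]) a else b
      keep[drop] <<- FALSE
      removed <- TRUE
    }
    removed
  }
  # sliding-window passes repeated to a fixed point, so re-pruning the
  # output is a no-op by construction
  repeat {
    removed_any <- FALSE
    for (chr in unique(v$chromosome[ord])) {
      chr_idx <- ord[v$chromosome[ord] == chr]
      live <- chr_idx[keep[chr_idx]]
      start <- 1L
      while (start <= length(live)) {
        win <- live[seq(start, min(start + window_variants - 1L, length(live)))]
        if (length(win) >= 2L && prune_window(win)) removed_any <- TRUE
        if (start + window_variants - 1L >= length(live)) break
        start <- start + step
      }
    }
    if (!removed_any) break
  }
  out <- subset_genotypes(gm, variants = keep)
  attr(out, "filter_log") <- list(input = nrow(v), removed = sum(!keep),
                                  retained = sum(keep))
  out
}

#' Genotype principal-component analysis
#'
#' Columns are centered at twice the cohort alt-allele frequency and, under
#' the default frequency-based scaling, divided by `sqrt(2 f (1 - f))` (the
#' binomial standard deviation), the standard normalization for ancestry
#' PCA; missing dosages are mean-imputed before decomposition. Components
#' come from the singular value decomposition; each is oriented so that its
#' largest-magnitude sample coordinate is positive, making results stable to
#' sample/variant order.
#'
#' @param gm a [genotype_matrix()]
#' @param n_components number of components (default 20, the conventional
#'   depth for structure scans)
#' @param scaling `"patterson"` (frequency-based, default) or `"unit"`
#'   (empirical unit variance)
#' @return list of class `pc_result`: `scores` (samples x components),
#'   `loadings` (variants x components, orthonormal), `eigenvalues`,
#'   `var_explained`, `samples`
#' @export
pca <- function(gm, n_components = 20L, scaling = c("patterson", "unit")) {
  scaling <- match.arg(scaling)
  d <- gm$dosages
  f <- alt_freq(gm)
  poly <- !is.nan(f) & f > 0 & f < 1
  if (sum(poly) < n_components)
    stop("fewer polymorphic variants (", sum(poly), ") than components (",
         n_components, ")")
  d <- d[, poly, drop = FALSE]
  f <- f[poly]
  if (n_samples(gm) < n_components)
    stop("fewer samples than requested components")
  ctr <- 2 * f
  X <- sweep(d, 2L, ctr)
  if (anyNA(X)) X[is.na(X)] <- 0          # mean-imputation after centering
  sdv <- if (scaling == "patterson") sqrt(2 * f * (1 - f))
         else apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  X <- sweep(X, 2L, sdv, `/`)
  sv <- svd(X, nu = n_components, nv = n_components)
  k <- n_components
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  # sign convention: largest-|coordinate| sample positive
  for (j in seq_len(k)) {
    i_max <- which.max(abs(scores[, j]))
    if (scores[i_max, j] < 0) {
      scores[, j] <- -scores[, j]
      sv$v[, j] <- -sv$v[, j]
    }
  }
  ev <- sv$d^2 / (nrow(X) - 1)
  dimnames(scores) <- list(gm$samples, paste0("PC", seq_len(k)))
  structure(list(scores = scores, loadings = sv$v,
                 eigenvalues = ev[seq_len(k)],
                 var_explained = ev[seq_len(k)] / sum(ev),
                 samples = gm$samples),
            class = "pc_result")
}

#' @export
print.pc_result <- function(x, ...) {
  cat("pc_result: ", length(x$samples), " samples x ", ncol(x$scores),
      " components\n  var explained: ",
      paste(sprintf("%.3f", utils::head(x$var_explained, 5)), collapse = " "),
      if (ncol(x$scores) > 5) " ..." else "", "\n", sep = "")
  invisible(x)
}

#' Scan polygenic scores against principal components
#'
#' Pearson correlation (with its two-sided p-value) between every score
#' column of the grid and every principal component. Columns with zero score
#' variance are flagged `undefined` and excluded from any multiplicity
#' adjustment. Benjamini-Hochberg adjustment across the full scan is
#' available but off by default (raw correlations are the primary readout).
#'
#' @param prs a `prs_matrix` from [score_grid()]
#' @param pcs a `pc_result` from [pca()] over the same samples in the same
#'   order
#' @param adjust `"none"` or `"bh"`
#' @return `data.table`: `clump_label`, `p_T`, `component`, `r`, `p`,
#'   `p_adj` (when adjusted), `undefined`
#' @export
prs_pc_scan <- function(prs, pcs, adjust = c("none", "bh")) {
  adjust <- match.arg(adjust)
  prs <- data.table::as.data.table(prs)
  cells <- unique(prs[, .(clump_label, p_T)])
  res <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    sub <- prs[clump_label == cells$clump_label[ci] & p_T == cells$p_T[ci]]
    if (!identical(as.character(sub$sample), as.character(pcs$samples)))
      stop("prs and pcs must cover the same samples in the same order")
    s <- sub$score
    und <- stats::var(s) == 0
    k <- ncol(pcs$scores)
    if (und) {
      res[[ci]] <- data.table::data.table(
        clump_label = cells$clump_label[ci], p_T = cells$p_T[ci],
        component = seq_len(k), r = NA_real_, p = NA_real_, undefined = TRUE)
    } else {
      r <- as.vector(stats::cor(s, pcs$scores))
      n <- length(s)
      tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
      p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
      res[[ci]] <- data.table::data.table(
        clump_label = cells$clump_label[ci], p_T = cells$p_T[ci],
        component = seq_len(k), r = r, p = p, undefined = FALSE)
    }
  }
  out <- data.table::rbindlist(res)
  if (adjust == "bh") {
    out[, p_adj := NA_real_]
    out[undefined == FALSE, p_adj := stats::p.adjust(p, method = "BH")]
  }
  out[]
}
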