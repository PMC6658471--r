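#' Clumping specification
#'
#' Parameters of one greedy LD-clumping pass: the physical window, the
#' r-squared threshold above which a variant is absorbed into a more
#' significant index variant's clump, p-value ceilings for index (`p1`) and
#' clumped (`p2`) variants, and the reference population supplying LD. The
#' defaults (500 kb window, `p1 = p2 = 1`, r-squared in \{0.2, 0.05, 0.01\})
#' are the standard PLINK-style settings varied in the construction grid.
#'
#' @param window_kb physical window half-width in kb (closed interval)
#' @param r2_threshold r-squared threshold in `(0, 1]`
#' @param p1 index-variant p ceiling
#' @param p2 clumped-variant p ceiling
#' @param reference_population population or superpopulation code, or `"ALL"`
#' @return a `clump_spec` list with a `label` field
#' @export
clump_spec <- function(window_kb = 500L, r2_threshold = 0.2, p1 = 1, p2 = 1,
                       reference_population = "ALL") {
  stopifnot(window_kb > 0, r2_threshold > 0, r2_threshold <= 1, p2 >= 0)
  structure(list(window_kb = as.integer(window_kb), r2_threshold = r2_threshold,
                 p1 = p1, p2 = p2,
                 reference_population = as.character(reference_population),
                 label = sprintf("r2_%g_ref_%s", r2_threshold, reference_population)),
            class = "clump_spec")
}

#' The standard 13-threshold p_T ladder
#'
#' @return increasing numeric vector of 13 p-value thresholds from 5e-8 to 1
#' @export
default_thresholds <- function() {
  c(5e-8, 1e-6, 1e-4, 1e-3, 1e-2, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5, 0.75, 1)
}

# join key used when variant ids are absent: chrom:pos:sorted alleles
.allele_key <- function(chrom, pos, a1, a2) {
  swap <- a1 > a2
  lo <- ifelse(swap, a2, a1); hi <- ifelse(swap, a1, a2)
  paste(chrom, pos, lo, hi, sep = ":")
}

.is_missing_id <- function(id) is.na(id) | id == "" | id == "."

#' Harmonize summary-statistic weights to a target genotype panel
#'
#' Matches each summary-statistic row to a target variant (by `variant_id`,
#' falling back to a chromosome:position:sorted-alleles key when ids are
#' missing) and orients the effect to the target's alt allele: effects whose
#' effect allele is the target ref allele are sign-flipped. Rows whose
#' alleles match neither orientation are dropped as mismatches;
#' strand-ambiguous pairs (A/T, C/G) are dropped when `drop_ambiguous` is
#' set; rows absent from the target are dropped as absent. Every source row
#' receives an `action` and drops are counted, never raised.
#'
#' @param ss summary-statistics table
#' @param gm target [genotype_matrix()]
#' @param drop_ambiguous drop strand-ambiguous variants? (default `TRUE`)
#' @return `data.table` with columns `variant_id` (target id), `weight`
#'   (aligned to target alt allele), `p`, `action`; retained rows have action
#'   `match` or `sign_flip`. [filter_log()] carries per-action counts.
#' @export
harmonize <- function(ss, gm, drop_ambiguous = TRUE) {
  if (nrow(ss) == 0L || n_variants(gm) == 0L)
    stop("harmonize requires non-empty summary statistics and genotypes")
  tv <- gm$variants
  idx <- match(ss$variant_id, tv$variant_id)
  need_key <- .is_missing_id(ss$variant_id)
  if (any(need_key) || anyNA(idx)) {
    tkey <- .allele_key(tv$chromosome, tv$position, tv$ref_allele, tv$alt_allele)
    skey <- .allele_key(ss$chromosome, ss$position, ss$effect_allele, ss$other_allele)
    fb <- is.na(idx) | need_key
    idx[fb] <- match(skey[fb], tkey)
  }
  action <- rep("dropped_absent", nrow(ss))
  weight <- rep(NA_real_, nrow(ss))
  hit <- !is.na(idx)
  ea <- ss$effect_allele; oa <- ss$other_allele
  ambiguous <- (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
  tr <- tv$ref_allele[idx]; ta <- tv$alt_allele[idx]
  fwd <- hit & ea == ta & oa == tr
  rev <- hit & ea == tr & oa == ta
  action[hit] <- "dropped_mismatch"
  action[fwd] <- "match";      weight[fwd] <- ss$beta[fwd]
  action[rev] <- "sign_flip";  weight[rev] <- -ss$beta[rev]
  if (drop_ambiguous) {
    amb <- hit & ambiguous & (fwd | rev)
    action[amb] <- "dropped_ambiguous"; weight[amb] <- NA_real_
  }
  out <- data.table::data.table(
    source_id = ss$variant_id,
    variant_id = tv$variant_id[idx],
    weight = weight, p = ss$p, action = action
  )
  keep <- out$action %in% c("match", "sign_flip")
  res <- out[keep]
  counts <- as.list(table(factor(out$action,
    levels = c("match", "sign_flip", "dropped_ambiguous",
               "dropped_mismatch", "dropped_absent"))))
  attr(res, "filter_log") <- c(list(input = nrow(ss), retained = sum(keep)), counts)
  attr(res, "actions") <- out
  res[]
}

#' Squared genotype correlation (composite LD) between two variants
#'
#' Squared Pearson correlation of dosages over pairwise-complete samples --
#' the LD measure computable from unphased dosage data.
#'
#' @param gm a [genotype_matrix()]
#' @param variant_i,variant_j variant ids (or integer column indices)
#' @return r-squared value in `[0, 1]`
#' @export
ld_r2 <- function(gm, variant_i, variant_j) {
  ix <- if (is.character(variant_i)) match(variant_i, gm$variants$variant_id) else variant_i
  jx <- if (is.character(variant_j)) match(variant_j, gm$variants$variant_id) else variant_j
  if (is.na(ix) || is.na(jx)) stop("variant not present in genotype matrix")
  gi <- gm$dosages[, ix]; gj <- gm$dosages[, jx]
  ok <- !is.na(gi) & !is.na(gj)
  if (sum(ok) < 2L) stop("fewer than 2 pairwise-complete samples")
  gi <- gi[ok]; gj <- gj[ok]
  if (stats::var(gi) == 0 || stats::var(gj) == 0)
    stop("undefined LD: variant monomorphic over pairwise-complete samples")
  stats::cor(gi, gj)^2
}

#' Greedy LD clumping of summary statistics
#'
#' PLINK-style clumping: variants are visited in order of ascending p-value
#' (ties broken by chromosome, then position, then variant id); each
#' unassigned variant with `p <= p1` becomes an index, and every unassigned
#' variant with `p <= p2`, on the same chromosome within `window_kb` kb
#' (closed interval), and with r-squared at least `r2_threshold` to the index
#' in the reference panel is assigned to its clump. Variants absent from the
#' reference are dropped before clumping (counted; optionally kept as
#' singleton indices via `keep_unmatched`).
#'
#' @param ss summary-statistics table
#' @param reference [genotype_matrix()] supplying LD
#' @param spec a [clump_spec()]
#' @param keep_unmatched keep variants absent from the reference as singleton
#'   index variants instead of dropping them (default `FALSE`)
#' @return list: `index` (summary-statistics rows of the index variants, in
#'   greedy order), `assignment` (`data.table` variant_id -> index_id),
#'   `n_dropped_absent`
#' @export
clump <- function(ss, reference, spec = clump_spec(), keep_unmatched = FALSE) {
  tv <- reference$variants
  idx <- match(ss$variant_id, tv$variant_id)
  need_key <- .is_missing_id(ss$variant_id)
  if (any(need_key) || anyNA(idx)) {
    tkey <- .allele_key(tv$chromosome, tv$position, tv$ref_allele, tv$alt_allele)
    skey <- .allele_key(ss$chromosome, ss$position, ss$effect_allele, ss$other_allele)
    fb <- is.na(idx) | need_key
    idx[fb] <- match(skey[fb], tkey)
  }
  absent <- is.na(idx)
  work <- data.table::data.table(
    variant_id = ss$variant_id, chromosome = ss$chromosome,
    position = ss$position, p = ss$p, ref_col = idx, absent = absent
  )
  n_dropped <- if (keep_unmatched) 0L else sum(absent)
  if (!keep_unmatched) work <- work[!(absent)]
  if (nrow(work) == 0L || !any(work$p <= spec$p1))
    stop("no variants remain after matching to the reference (or none pass p1)")
  data.table::setorder(work, p, chromosome, position, variant_id)

  n <- nrow(work)
  assigned <- rep(FALSE, n)
  clump_of <- rep(NA_character_, n)
  index_rows <- integer(0)
  win <- spec$window_kb * 1000L
  dmat <- reference$dosages
  for (i in seq_len(n)) {
    if (assigned[i]) next
    if (work$p[i] > spec$p1) { next }   # cannot index; may still be clumped
    assigned[i] <- TRUE
    clump_of[i] <- work$variant_id[i]
    index_rows <- c(index_rows, i)
    if (is.na(work$ref_col[i])) next    # unmatched singleton (keep_unmatched)
    cand <- which(!assigned & work$p <= spec$p2 &
                    work$chromosome == work$chromosome[i] &
                    abs(work$position - work$position[i]) <= win &
                    !is.na(work$ref_col))
    if (!length(cand)) next
    gi <- dmat[, work$ref_col[i]]
    for (j in cand) {
      gj <- dmat[, work$ref_col[j]]
      ok <- !is.na(gi) & !is.na(gj)
      if (sum(ok) < 2L) next
      if (stats::var(gi[ok]) == 0 || stats::var(gj[ok]) == 0) next
      if (stats::cor(gi[ok], gj[ok])^2 >= spec$r2_threshold) {
        assigned[j] <- TRUE
        clump_of[j] <- work$variant_id[i]
      }
    }
  }
  index_ids <- work$variant_id[index_rows]
  out <- ss[match(index_ids, ss$variant_id)]
  list(index = out,
       assignment = data.table::data.table(variant_id = work$variant_id,
                                           index_id = clump_of),
       n_dropped_absent = n_dropped)
}

#' Apply a p-value threshold to harmonized weights
#'
#' Retains rows with `p < p_T`, except at `p_T = 1` where all rows are
#' retained (the full-genome score is inclusive of p = 1).
#'
#' @param weights harmonized-weights table from [harmonize()]
#' @param p_T threshold in `(0, 1]`
#' @return subset of `weights`
#' @export
threshold_weights <- function(weights, p_T) {
  stopifnot(p_T > 0, p_T <= 1)
  if (p_T == 1) weights[p <= 1] else weights[p < p_T]
}

#' Additive polygenic score
#'
#' `sum` mode computes the weighted dosage sum per sample; `average` mode
#' divides by twice the number of weighted variants (per-allele average).
#' Missing dosages are imputed per `missing_policy`: the cohort mean dosage
#' of the variant (default) or zero.
#'
#' @param gm target [genotype_matrix()]
#' @param weights harmonized weights (`variant_id`, `weight`)
#' @param mode `"sum"` or `"average"`
#' @param missing_policy `"mean"` or `"zero"`
#' @return named numeric vector of scores, one per sample; attribute
#'   `n_variants` gives the number of weighted variants used
#' @export
score <- function(gm, weights, mode = c("sum", "average"),
                  missing_policy = c("mean", "zero")) {
  mode <- match.arg(mode); missing_policy <- match.arg(missing_policy)
  if (nrow(weights) == 0L) {
    out <- stats::setNames(rep(0, n_samples(gm)), gm$samples)
    attr(out, "n_variants") <- 0L
    return(out)
  }
  ix <- match(weights$variant_id, gm$variants$variant_id)
  if (all(is.na(ix))) stop("none of the weighted variants are present in the genotypes")
  w <- weights$weight[!is.na(ix)]
  ix <- ix[!is.na(ix)]
  d <- gm$dosages[, ix, drop = FALSE]
  if (anyNA(d)) {
    fill <- if (missing_policy == "mean") colMeans(d, na.rm = TRUE) else rep(0, ncol(d))
    fill[is.nan(fill)] <- 0
    na_idx <- which(is.na(d))
    d[na_idx] <- fill[((na_idx - 1L) %/% nrow(d)) + 1L]
  }
  s <- as.vector(d %*% w)
  if (mode == "average") s <- s / (2 * length(w))
  out <- stats::setNames(s, gm$samples)
  attr(out, "n_variants") <- length(w)
  out
}

#' Full clumping-by-thresholding score grid
#'
#' For each clumping specification: select the LD reference samples (a
#' population, a superpopulation, or `ALL`), clump the summary statistics
#' against them, harmonize the surviving index variants to the target panel,
#' then score the target at every p_T threshold. The result is the factorial
#' grid of scores whose construction choices (r-squared, reference
#' population, p_T) are the methodological axes of the analysis.
#'
#' @param gm target [genotype_matrix()] (scored cohort)
#' @param ss summary statistics
#' @param panel sample panel for `gm` (used to select LD reference samples)
#' @param specs list of [clump_spec()]s
#' @param thresholds increasing p_T vector (default [default_thresholds()])
#' @param mode,missing_policy passed to [score()]
#' @param reference optional separate [genotype_matrix()] to draw LD reference
#'   samples from (defaults to `gm` itself, with `panel` describing it)
#' @param drop_ambiguous passed to [harmonize()]
#' @return long `data.table` with class `prs_matrix`: columns `sample`,
#'   `clump_label`, `r2_threshold`, `reference_population`, `p_T`, `score`,
#'   `n_variants`
#' @export
score_grid <- function(gm, ss, panel, specs = list(clump_spec()),
                       thresholds = default_thresholds(),
                       mode = "sum", missing_policy = "mean",
                       reference = NULL, drop_ambiguous = TRUE) {
  stopifnot(all(diff(thresholds) > 0), all(thresholds > 0), all(thresholds <= 1))
  if (is.null(reference)) reference <- gm
  out <- vector("list", length(specs))
  for (si in seq_along(specs)) {
    spec <- specs[[si]]
    refpop <- spec$reference_population
    ref_samples <- if (identical(refpop, "ALL")) panel$sample
      else panel[panel$pop == refpop | panel$super_pop == refpop, ][["sample"]]
    if (!length(ref_samples))
      stop("reference population '", refpop, "' not present in the panel")
    ref_gm <- subset_genotypes(reference, samples = ref_samples)
    cl <- clump(ss, ref_gm, spec)
    hw <- harmonize(cl$index, gm, drop_ambiguous = drop_ambiguous)
    cells <- vector("list", length(thresholds))
    for (ti in seq_along(thresholds)) {
      wt <- threshold_weights(hw, thresholds[ti])
      sc <- score(gm, wt, mode = mode, missing_policy = missing_policy)
      cells[[ti]] <- data.table::data.table(
        sample = gm$samples, clump_label = spec$label,
        r2_threshold = spec$r2_threshold, reference_population = refpop,
        p_T = thresholds[ti], score = as.vector(sc),
        n_variants = attr(sc, "n_variants")
      )
    }
    out[[si]] <- data.table::rbindlist(cells)
  }
  res <- data.table::rbindlist(out)
  data.table::setattr(res, "class", c("prs_matrix", class(res)))
  res[]
}
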