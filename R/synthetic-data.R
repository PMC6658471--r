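#' Simulation configuration for the synthetic multi-population cohort
#'
#' Bundles the generative parameters used across the synthetic-data
#' operations. Defaults describe a small three-population cohort with
#' continental-scale differentiation (FST about 0.1), moderate block LD and a
#' half-heritable quantitative trait -- the regime the downstream portability
#' and structure analyses assume.
#'
#' @param n_pops number of populations (>= 1)
#' @param n_per_pop samples per population
#' @param n_variants number of biallelic variants
#' @param fst per-population Balding-Nichols differentiation in `[0, 1)`
#'   (recycled to `n_pops`)
#' @param block_size variants per LD block
#' @param within_block_r latent haplotype correlation inside a block, `[0, 1)`
#' @param n_causal number of causal variants (<= `n_variants`)
#' @param h2 narrow-sense heritability in `[0, 1]`
#' @param strat_bias stratification-bias multiplier delta (see
#'   [inject_stratification()])
#' @param seed integer RNG seed
#' @return a `sim_config` list
#' @export
sim_config <- function(n_pops = 3L, n_per_pop = 200L, n_variants = 2000L,
                       fst = 0.1, block_size = 10L, within_block_r = 0.5,
                       n_causal = 100L, h2 = 0.5, strat_bias = 0, seed = 1L) {
  fst <- rep_len(fst, n_pops)
  stopifnot(n_pops >= 1L, n_per_pop >= 1L, n_variants >= 1L,
            all(fst >= 0), all(fst < 1),
            block_size >= 1L, within_block_r >= 0, within_block_r < 1,
            n_causal >= 0L, n_causal <= n_variants,
            h2 >= 0, h2 <= 1)
  structure(list(n_pops = as.integer(n_pops), n_per_pop = as.integer(n_per_pop),
                 n_variants = as.integer(n_variants), fst = fst,
                 block_size = as.integer(block_size),
                 within_block_r = within_block_r,
                 n_causal = as.integer(n_causal), h2 = h2,
                 strat_bias = strat_bias, seed = as.integer(seed)),
            class = "sim_config")
}

#' Draw ancestral allele frequencies
#'
#' Ancestral alt-allele frequencies are i.i.d. Uniform(0.05, 0.95): common
#' enough that drifted descendants rarely fix, matching the post-MAF-filter
#' variant pool the analyses operate on.
#'
#' @param n_variants number of variants (>= 1)
#' @param seed integer seed
#' @return numeric vector of frequencies
#' @export
sample_ancestral_freqs <- function(n_variants, seed) {
  if (n_variants < 1L) stop("n_variants must be >= 1")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed, kind = "Mersenne-Twister")
  stats::runif(n_variants, 0.05, 0.95)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Per-population frequencies under the Balding-Nichols drift model
#'
#' For differentiation `F > 0` the population frequency at a variant with
#' ancestral frequency `p` is drawn from `Beta(p(1-F)/F, (1-p)(1-F)/F)`,
#' which has mean `p` and variance `F p (1-p)`. `F = 0` returns the ancestral
#' frequencies exactly.
#'
#' @param ancestral_freqs numeric vector of ancestral frequencies
#' @param fst_per_pop vector of F values, one per population, each in `[0, 1)`
#' @param seed integer seed
#' @return matrix, variants x populations
#' @export
balding_nichols_freqs <- function(ancestral_freqs, fst_per_pop, seed) {
  if (any(fst_per_pop < 0) || any(fst_per_pop >= 1))
    stop("each F must be in [0, 1)")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed, kind = "Mersenne-Twister")
  p <- ancestral_freqs
  out <- matrix(NA_real_, length(p), length(fst_per_pop))
  for (k in seq_along(fst_per_pop)) {
    f <- fst_per_pop[k]
    out[, k] <- if (f == 0) p
    else stats::rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
  }
  colnames(out) <- paste0("POP", seq_along(fst_per_pop))
  out
}

#' Simulate genotypes with block LD via a Gaussian copula
#'
#' Haplotypes are generated per LD block from a latent multivariate normal
#' with exchangeable correlation `within_block_r` inside the block and zero
#' across blocks; each latent value is thresholded at the `(1 - f)` quantile
#' of its variant's population frequency `f`, and two haplotypes are summed
#' to a dosage. Variants are laid out on chromosome "1" with 1 kb spacing
#' inside a block and a 10 Mb gap between blocks, so blocks are far outside
#' any clumping window of each other.
#'
#' @param pop_freqs matrix of per-population alt-allele frequencies
#'   (variants x populations), e.g. from [balding_nichols_freqs()]
#' @param n_per_pop samples per population (recycled)
#' @param block_size variants per block
#' @param within_block_r exchangeable latent correlation, `[0, 1)`
#' @param seed integer seed
#' @return list with `genotypes` ([genotype_matrix()]) and `panel`
#'   (`data.table` sample/pop/super_pop; superpopulation = population here)
#' @export
simulate_genotypes <- function(pop_freqs, n_per_pop, block_size = 10L,
                               within_block_r = 0.5, seed = 1L) {
  stopifnot(within_block_r >= 0, within_block_r < 1, block_size >= 1L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed, kind = "Mersenne-Twister")
  pop_freqs <- as.matrix(pop_freqs)
  m <- nrow(pop_freqs)
  pops <- colnames(pop_freqs)
  if (is.null(pops)) pops <- paste0("POP", seq_len(ncol(pop_freqs)))
  n_per_pop <- rep_len(n_per_pop, length(pops))
  block <- rep(seq_len(ceiling(m / block_size)), each = block_size)[seq_len(m)]
  r <- within_block_r

  dos_list <- vector("list", length(pops))
  for (k in seq_along(pops)) {
    nh <- 2L * n_per_pop[k]
    f <- pop_freqs[, k]
    thr <- stats::qnorm(1 - f)        # carrier iff latent > threshold
    hap_sum <- matrix(0L, n_per_pop[k], m)
    for (b in unique(block)) {
      idx <- which(block == b)
      z_shared <- stats::rnorm(nh)
      z <- sqrt(r) * matrix(z_shared, nh, length(idx)) +
        sqrt(1 - r) * matrix(stats::rnorm(nh * length(idx)), nh, length(idx))
      carrier <- sweep(z, 2L, thr[idx], `>`)
      hap_sum[, idx] <- carrier[seq_len(n_per_pop[k]), , drop = FALSE] +
        carrier[n_per_pop[k] + seq_len(n_per_pop[k]), , drop = FALSE]
    }
    dos_list[[k]] <- hap_sum
  }
  dosages <- do.call(rbind, dos_list)
  samples <- unlist(lapply(seq_along(pops), function(k)
    sprintf("%s_S%04d", pops[k], seq_len(n_per_pop[k]))))
  # 250 blocks per chromosome, 2 Mb between block starts, 1 kb inside a
  # block: blocks always sit far outside a 500 kb clumping window of each
  # other and positions stay well below .Machine$integer.max
  chrom_of_block <- (block - 1L) %/% 250L + 1L
  block_in_chrom <- (block - 1L) %% 250L
  idx_in_block <- seq_len(m) - (block - 1L) * block_size
  variants <- data.table::data.table(
    variant_id = sprintf("rs%06d", seq_len(m)),
    chromosome = as.character(chrom_of_block),
    position = block_in_chrom * 2000000L + idx_in_block * 1000L,
    ref_allele = "A",
    alt_allele = "G"
  )
  panel <- data.table::data.table(
    sample = samples,
    pop = rep(pops, n_per_pop),
    super_pop = rep(pops, n_per_pop)
  )
  list(genotypes = genotype_matrix(dosages, variants, samples), panel = panel)
}

#' Simulate an additive quantitative phenotype
#'
#' `n_causal` variants are chosen uniformly at random; their true effects are
#' i.i.d. standard normal and the genetic value is the weighted dosage sum.
#' Environmental noise is first residualized against the genetic value and
#' then scaled so that the in-sample variance ratio Var(G)/Var(y) equals `h2`
#' exactly (so the regression R-squared of y on G is `h2` by construction).
#'
#' @param gm a [genotype_matrix()]
#' @param n_causal number of causal variants
#' @param h2 heritability in `[0, 1]`
#' @param seed integer seed
#' @return list: `phenotype` (named numeric, one per sample), `truth`
#'   (`data.table` variant_id, beta_true, causal), `genetic_value`
#' @export
simulate_phenotype <- function(gm, n_causal, h2, seed = 1L) {
  stopifnot(h2 >= 0, h2 <= 1, n_causal <= n_variants(gm))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed, kind = "Mersenne-Twister")
  m <- n_variants(gm)
  causal <- sort(sample.int(m, n_causal))
  beta_true <- numeric(m)
  beta_true[causal] <- stats::rnorm(n_causal)
  d <- gm$dosages
  d[is.na(d)] <- 0L
  g <- as.vector(d %*% beta_true)
  if (stats::var(g) == 0 && h2 > 0)
    stop("genetic value has zero variance but h2 > 0")
  e <- stats::rnorm(length(g))
  if (h2 == 0) {
    y <- as.vector(scale(e))
  } else if (h2 == 1) {
    y <- as.vector(scale(g)) # affine in G
  } else {
    e_orth <- stats::resid(stats::lm(e ~ g))
    y <- sqrt(h2) * as.vector(scale(g)) + sqrt(1 - h2) * as.vector(scale(e_orth))
  }
  names(y) <- gm$samples
  truth <- data.table::data.table(
    variant_id = gm$variants$variant_id,
    beta_true = beta_true,
    causal = seq_len(m) %in% causal
  )
  list(phenotype = y, truth = truth, genetic_value = stats::setNames(g, gm$samples))
}

#' Marginal-OLS discovery GWAS
#'
#' Regresses the phenotype on each variant's dosage separately (no
#' covariates): `beta` is the OLS slope, `se` its standard error, and `p` the
#' two-sided Wald p-value on n-2 degrees of freedom. Monomorphic variants are
#' assigned `beta = 0`, `se = NA`, `p = 1`. Missing dosages are excluded
#' pairwise.
#'
#' @param gm a [genotype_matrix()]
#' @param phenotype numeric vector, one value per sample of `gm`
#' @param discovery_samples optional character vector restricting the scan to
#'   a discovery subset (>= 30 samples)
#' @return summary-statistics `data.table` (same layout as [read_sumstats()])
#' @export
run_gwas <- function(gm, phenotype, discovery_samples = NULL) {
  if (!is.null(discovery_samples)) {
    keep <- gm$samples %in% discovery_samples
    gm <- subset_genotypes(gm, samples = keep)
    phenotype <- phenotype[keep]
  }
  n <- n_samples(gm)
  if (n < 30L) stop("need >= 30 discovery samples, got ", n)
  d <- gm$dosages
  y <- as.numeric(phenotype)
  ok <- !is.na(d)
  nv <- colSums(ok)
  d0 <- d; d0[!ok] <- 0
  ymat_sum <- as.vector(crossprod(ok, y))          # sum of y over non-missing
  sum_d <- colSums(d0)
  mean_d <- sum_d / nv
  mean_y <- ymat_sum / nv
  sxy <- as.vector(crossprod(d0, y)) - nv * mean_d * mean_y
  sxx <- colSums(d0^2) - nv * mean_d^2
  syy <- as.vector(crossprod(ok, y^2)) - nv * mean_y^2
  mono <- sxx <= 0 | nv < 3L
  beta <- ifelse(mono, 0, sxy / sxx)
  rss <- pmax(syy - beta * sxy, 0)
  se <- ifelse(mono, NA_real_, sqrt(rss / (nv - 2) / sxx))
  tval <- beta / se
  p <- ifelse(mono | is.na(se) | se == 0, 1,
              2 * stats::pt(abs(tval), df = nv - 2, lower.tail = FALSE))
  p <- pmax(p, .Machine$double.xmin)   # keep p in (0, 1]
  v <- gm$variants
  data.table::data.table(
    variant_id = v$variant_id, chromosome = v$chromosome, position = v$position,
    effect_allele = v$alt_allele, other_allele = v$ref_allele,
    beta = beta, se = se, p = p
  )
}

#' Inject uncorrected-stratification bias into summary statistics
#'
#' Adds `delta * (f_popA - f_popB)` to each variant's effect estimate, where
#' the `f` are the designated populations' true allele frequencies. This is
#' the textbook signature of a GWAS confounded by population structure: the
#' bias is proportional to the between-population frequency difference, so
#' scores built from the biased weights track ancestry axes.
#'
#' @param ss summary-statistics table
#' @param pop_freqs variants x populations frequency matrix with column names;
#'   rows must align with `ss` via `rownames` or cover all variants in order
#'   of a `variant_id` attribute/column match (see Details)
#' @param delta bias scalar
#' @param pops length-2 character vector naming (popA, popB)
#' @param variant_ids character vector giving the variant id of each
#'   `pop_freqs` row (defaults to `rownames(pop_freqs)`)
#' @return summary statistics with biased `beta`; all other fields unchanged
#' @export
inject_stratification <- function(ss, pop_freqs, delta, pops,
                                  variant_ids = rownames(pop_freqs)) {
  pop_freqs <- as.matrix(pop_freqs)
  if (length(pops) != 2L) stop("pops must name exactly two populations")
  missing_pop <- setdiff(pops, colnames(pop_freqs))
  if (length(missing_pop))
    stop("unknown population code(s): ", paste(missing_pop, collapse = ", "))
  if (is.null(variant_ids)) {
    if (nrow(pop_freqs) != nrow(ss))
      stop("pop_freqs has no variant ids and its rows do not align with ss")
    variant_ids <- ss$variant_id
  }
  idx <- match(ss$variant_id, variant_ids)
  if (anyNA(idx))
    stop("frequency table does not cover all variants: e.g. ",
         ss$variant_id[which(is.na(idx))[1]])
  out <- data.table::copy(ss)
  out[, beta := beta + delta * (pop_freqs[idx, pops[1]] - pop_freqs[idx, pops[2]])]
  out[]
}

#' Simulate a study-comparison table
#'
#' Generates the input for the portability meta-analysis: per ancestry group,
#' `n_per_group` matched (European, non-European) effect pairs whose true
#' relative performance is `true_ratio` plus Gaussian noise. Metric types are
#' assigned round-robin over variance_explained, beta, odds_ratio, auc; for
#' odds-ratio rows the ratio is imposed on the log scale, matching how those
#' rows are later normalized.
#'
#' @param n_per_group rows per ancestry group
#' @param true_ratio_per_group named numeric of true ratios (> 0), names are
#'   ancestry groups
#' @param noise_sd standard deviation of the additive ratio noise
#' @param seed integer seed
#' @return study-comparison `data.table` (layout of [read_study_table()])
#' @export
simulate_study_table <- function(n_per_group,
                                 true_ratio_per_group = c(African = 0.42,
                                                          `South Asian` = 0.60,
                                                          `East Asian` = 0.95),
                                 noise_sd = 0.05, seed = 1L) {
  if (any(true_ratio_per_group <= 0)) stop("ratios must be > 0")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed, kind = "Mersenne-Twister")
  groups <- names(true_ratio_per_group)
  rows <- list()
  for (g in groups) {
    n <- n_per_group
    if (n == 0L) next
    metric <- .metric_types[((seq_len(n) - 1L) %% 4L) + 1L]
    ratio <- true_ratio_per_group[[g]] + stats::rnorm(n, 0, noise_sd)
    base <- stats::runif(n, 0.02, 0.30)       # generic positive EUR effect
    eur <- numeric(n); noneur <- numeric(n)
    is_or <- metric == "odds_ratio"
    eur[!is_or] <- base[!is_or]
    noneur[!is_or] <- base[!is_or] * ratio[!is_or]
    eur[is_or] <- exp(base[is_or])            # log OR_eur = base > 0
    noneur[is_or] <- exp(base[is_or] * ratio[is_or])
    rows[[g]] <- data.table::data.table(
      study_id = sprintf("SIM-%s-%03d", gsub(" ", "", g), seq_len(n)),
      phenotype = "simulated_trait",
      ancestry_group = g,
      metric_type = metric,
      effect_eur = eur,
      effect_noneur = noneur,
      significant_noneur = stats::runif(n) < 0.5
    )
  }
  if (!length(rows))
    return(data.table::data.table(study_id = character(), phenotype = character(),
                                  ancestry_group = character(), metric_type = character(),
                                  effect_eur = numeric(), effect_noneur = numeric(),
                                  significant_noneur = logical()))
  data.table::rbindlist(rows)[]
}

#' Simulate a full multi-population cohort
#'
#' Convenience orchestrator: ancestral frequencies -> Balding-Nichols
#' per-population frequencies -> genotypes with block LD -> additive
#' phenotype. Seeds for the stages are derived deterministically from
#' `config$seed`.
#'
#' @param config a [sim_config()]
#' @return list: `genotypes`, `panel`, `phenotype`, `truth`, `genetic_value`,
#'   `pop_freqs`, `ancestral_freqs`
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  s <- config$seed
  anc <- sample_ancestral_freqs(config$n_variants, seed = s)
  pf <- balding_nichols_freqs(anc, config$fst, seed = s + 1L)
  sim <- simulate_genotypes(pf, config$n_per_pop, config$block_size,
                            config$within_block_r, seed = s + 2L)
  ph <- simulate_phenotype(sim$genotypes, config$n_causal, config$h2, seed = s + 3L)
  rownames(pf) <- sim$genotypes$variants$variant_id
  list(genotypes = sim$genotypes, panel = sim$panel,
       phenotype = ph$phenotype, truth = ph$truth,
       genetic_value = ph$genetic_value,
       pop_freqs = pf, ancestral_freqs = anc)
}
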