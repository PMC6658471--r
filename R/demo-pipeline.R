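#' End-to-end synthetic demonstration pipeline
#'
#' Runs the whole analysis on a simulated world: a multi-population target
#' cohort and a separate discovery cohort are drawn from shared ancestral
#' frequencies under the Balding-Nichols model; a marginal-OLS GWAS on the
#' discovery cohort supplies summary statistics; scores are built over the
#' full construction grid (clumping r-squared x LD reference population x
#' the 13 p_T thresholds); and the three downstream readouts are computed:
#' per-population score-distribution summaries with dispersion, the PRS
#' versus principal-component correlation scan, and the population-mean
#' score versus population-mean phenotype correlation. All tables are
#' written as CSV; outputs are byte-stable for a fixed seed. Optional
#' figures (score-density grid, PRS-phenotype scatter) are written as PDF.
#'
#' @param seed integer seed controlling every random draw
#' @param outdir output directory (created if needed)
#' @param n_pops number of target populations
#' @param n_per_pop target samples per population
#' @param n_discovery discovery-cohort size
#' @param n_variants number of variants
#' @param fst target-population differentiation (recycled)
#' @param discovery_fst differentiation of the discovery population
#' @param h2 phenotype heritability
#' @param n_causal number of causal variants
#' @param strat_bias stratification-bias delta added to discovery effects
#'   (0 = unbiased)
#' @param r2_grid clumping r-squared levels
#' @param reference_pops LD reference populations for the grid
#' @param thresholds p_T ladder (default [default_thresholds()])
#' @param n_pcs principal components for the structure scan
#' @param make_figures write PDF figures (default `TRUE`)
#' @return invisibly, a list with every intermediate object and the paths of
#'   the files written
#' @export
run_demo <- function(seed, outdir,
                     n_pops = 3L, n_per_pop = 150L, n_discovery = 600L,
                     n_variants = 1200L, fst = c(0.02, 0.08, 0.15),
                     discovery_fst = 0.02, h2 = 0.5, n_causal = 80L,
                     strat_bias = 0,
                     r2_grid = c(0.2, 0.05, 0.01),
                     reference_pops = NULL,
                     thresholds = default_thresholds(),
                     n_pcs = 10L, make_figures = TRUE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed)
  fst <- rep_len(fst, n_pops)

  anc <- sample_ancestral_freqs(n_variants, seed = seed)
  pf_target <- balding_nichols_freqs(anc, fst, seed = seed + 1L)
  colnames(pf_target) <- sprintf("POP%d", seq_len(n_pops))
  pf_disc <- balding_nichols_freqs(anc, discovery_fst, seed = seed + 2L)
  colnames(pf_disc) <- "DISC"

  target <- simulate_genotypes(pf_target, n_per_pop, block_size = 8L,
                               within_block_r = 0.5, seed = seed + 3L)
  disc <- simulate_genotypes(pf_disc, n_discovery, block_size = 8L,
                             within_block_r = 0.5, seed = seed + 4L)
  ph_d <- simulate_phenotype(disc$genotypes, n_causal, h2, seed = seed + 5L)
  ss <- run_gwas(disc$genotypes, ph_d$phenotype)
  if (strat_bias != 0) {
    fr <- pf_target
    rownames(fr) <- target$genotypes$variants$variant_id
    ss <- inject_stratification(ss, fr, strat_bias,
                                pops = colnames(pf_target)[c(1L, n_pops)])
  }

  # target phenotype shares the discovery architecture (same true betas)
  beta_true <- ph_d$truth$beta_true
  g_t <- as.vector(target$genotypes$dosages %*% beta_true)
  set.seed(seed + 6L)
  y_t <- if (h2 >= 1) as.vector(scale(g_t)) else {
    e <- stats::resid(stats::lm(stats::rnorm(length(g_t)) ~ g_t))
    sqrt(h2) * as.vector(scale(g_t)) + sqrt(1 - h2) * as.vector(scale(e))
  }
  names(y_t) <- target$genotypes$samples

  if (is.null(reference_pops))
    reference_pops <- c("ALL", colnames(pf_target)[seq_len(min(2L, n_pops))])
  specs <- list()
  for (r2 in r2_grid) for (rp in reference_pops)
    specs[[length(specs) + 1L]] <- clump_spec(r2_threshold = r2,
                                              reference_population = rp)
  prs <- score_grid(target$genotypes, ss, target$panel, specs,
                    thresholds = thresholds)

  summ <- population_summaries(prs, target$panel)
  gm_pca <- ld_prune(exclude_regions(target$genotypes))
  pcs <- pca(gm_pca, n_components = min(n_pcs, n_samples(gm_pca) - 1L))
  scan <- prs_pc_scan(prs, pcs, adjust = "bh")

  # population phenotype table from the simulated target phenotype means
  pheno_tab <- data.table::data.table(
    pop = target$panel$pop, y = y_t[target$panel$sample]
  )[, .(mean_phenotype = mean(y)), by = pop]
  cell <- summ$summaries[r2_threshold == r2_grid[1] &
                           reference_population == reference_pops[1] & p_T == 1]
  pcor <- phenotype_correlation(cell[, .(pop, mean)], pheno_tab)
  pcor_dt <- data.table::data.table(
    r2_threshold = r2_grid[1], reference_population = reference_pops[1],
    p_T = 1, r = pcor$r, p = pcor$p, n_populations = pcor$n_populations)

  paths <- c(
    scores = file.path(outdir, "scores.csv"),
    population_summaries = file.path(outdir, "population_summaries.csv"),
    dispersion = file.path(outdir, "dispersion.csv"),
    prs_pc_scan = file.path(outdir, "prs_pc_scan.csv"),
    phenotype_correlation = file.path(outdir, "phenotype_correlation.csv")
  )
  write_scores(prs, paths["scores"])
  data.table::fwrite(summ$summaries, paths["population_summaries"])
  data.table::fwrite(summ$dispersion, paths["dispersion"])
  data.table::fwrite(scan, paths["prs_pc_scan"])
  data.table::fwrite(pcor_dt, paths["phenotype_correlation"])

  if (make_figures) {
    fig1 <- file.path(outdir, "score_distribution_grid.pdf")
    grDevices::pdf(fig1, width = 9, height = 7)
    on.exit(grDevices::dev.off(), add = TRUE)
    .plot_distribution_grid(prs, target$panel,
                            p_T_levels = c(thresholds[1], 1))
    paths <- c(paths, score_distribution_grid = fig1)
  }
  invisible(list(paths = paths, prs = prs, summaries = summ, scan = scan,
                 phenotype_correlation = pcor_dt, pcs = pcs,
                 panel = target$panel, sumstats = ss,
                 phenotype = y_t, truth = ph_d$truth))
}

# density grid: rows = (r2 x reference), columns = p_T level, one density
# line per population
.plot_distribution_grid <- function(prs, panel, p_T_levels) {
  prs <- data.table::as.data.table(prs)
  dt <- merge(prs[p_T %in% p_T_levels], panel[, c("sample", "pop")],
              by = "sample", sort = FALSE)
  combos <- unique(dt[, .(r2_threshold, reference_population)])
  data.table::setorder(combos, -r2_threshold, reference_population)
  pops <- sort(unique(dt$pop))
  cols <- grDevices::hcl.colors(max(3L, length(pops)), "Dark 3")[seq_along(pops)]
  graphics::par(mfrow = c(nrow(combos), length(p_T_levels)),
                mar = c(2, 2, 1.5, 0.5))
  for (ci in seq_len(nrow(combos))) {
    for (pt in p_T_levels) {
      sub <- dt[r2_threshold == combos$r2_threshold[ci] &
                  reference_population == combos$reference_population[ci] &
                  p_T == pt]
      dens <- lapply(pops, function(p) {
        x <- sub[pop == p, score]
        if (length(x) > 1 && stats::sd(x) > 0) stats::density(x) else NULL
      })
      xr <- range(unlist(lapply(dens, function(d) if (!is.null(d)) d$x)))
      yr <- range(0, unlist(lapply(dens, function(d) if (!is.null(d)) d$y)))
      graphics::plot(NA, xlim = xr, ylim = yr, xlab = "", ylab = "",
                     main = sprintf("r2=%g ref=%s pT=%g",
                                    combos$r2_threshold[ci],
                                    combos$reference_population[ci], pt),
                     cex.main = 0.8)
      for (k in seq_along(pops))
        if (!is.null(dens[[k]])) graphics::lines(dens[[k]], col = cols[k])
    }
  }
}
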