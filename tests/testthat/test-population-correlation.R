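test_that("population summaries conserve counts, means, and detect dispersion", {
  panel <- data.table::data.table(
    sample = sprintf("S%03d", 1:60),
    pop = rep(c("P1", "P2", "P3"), each = 20),
    super_pop = rep(c("SP1", "SP1", "SP2"), each = 20))
  mk_prs <- function(s) data.table::data.table(
    sample = panel$sample, clump_label = "w", r2_threshold = 0.2,
    reference_population = "ALL", p_T = 1, score = s, n_variants = 5L)

  # identical scores: equal means, dispersion 0
  out <- population_summaries(mk_prs(rep(1.5, 60)), panel)
  expect_equal(unique(out$summaries$mean), 1.5)
  expect_equal(out$dispersion$dispersion, 0)
  expect_equal(sum(out$summaries$n), 60L)

  # shifted population means: positive dispersion; pooled mean conserved
  set.seed(31)
  s <- rnorm(60) + rep(c(0, 2, 4), each = 20)
  out2 <- population_summaries(mk_prs(s), panel)
  expect_gt(out2$dispersion$dispersion, 0)
  expect_equal(sum(out2$summaries$mean * out2$summaries$n) / 60, mean(s))

  # invariant to sample order
  perm <- sample(60)
  out3 <- population_summaries(mk_prs(s)[perm], panel)
  expect_equal(data.table::setorder(out3$summaries, pop),
               data.table::setorder(out2$summaries, pop))

  # standardization centers the pooled cohort
  out4 <- population_summaries(mk_prs(s), panel, standardize = TRUE)
  expect_equal(sum(out4$summaries$mean * out4$summaries$n) / 60, 0,
               tolerance = 1e-12)

  # single-sample population flagged
  p1 <- panel[c(1, 21, 41)]
  out5 <- population_summaries(mk_prs(s)[c(1, 21, 41)], p1)
  expect_true(all(out5$summaries$sd_undefined))
  expect_error(population_summaries(mk_prs(s), panel[1:10]), "absent from panel")
})

test_that("dispersion grows with p_T under stratification-biased weights", {
  direction <- logical(6)
  for (rep_i in 1:6) {
    anc <- sample_ancestral_freqs(600, seed = 300 + rep_i)
    pf <- balding_nichols_freqs(anc, c(0.08, 0.08), seed = 310 + rep_i)
    rownames(pf) <- sprintf("rs%06d", 1:600)
    tgt <- simulate_genotypes(pf, 100, block_size = 4, seed = 320 + rep_i)
    disc <- simulate_genotypes(balding_nichols_freqs(anc, 0, seed = 330 + rep_i),
                               300, block_size = 4, seed = 340 + rep_i)
    ph <- simulate_phenotype(disc$genotypes, 30, h2 = 0.5, seed = 350 + rep_i)
    ss <- inject_stratification(run_gwas(disc$genotypes, ph$phenotype),
                                pf, delta = 0.4, pops = c("POP1", "POP2"))
    prs <- score_grid(tgt$genotypes, ss, tgt$panel,
                      list(clump_spec(r2_threshold = 0.2)),
                      thresholds = c(5e-8, 1))
    disp <- population_summaries(prs, tgt$panel)$dispersion
    direction[rep_i] <- disp[p_T == 1, dispersion] > disp[p_T == 5e-8, dispersion]
  }
  expect_gt(mean(direction), 0.5)   # majority direction across replicates
})

test_that("dispersion_trend orders cells along one axis and flags monotonicity", {
  summ <- list(dispersion = data.table::data.table(
    clump_label = rep(c("a", "b"), each = 3),
    r2_threshold = rep(c(0.2, 0.05), each = 3),
    reference_population = "ALL",
    p_T = rep(c(5e-8, 0.05, 1), 2),
    dispersion = c(1, 2, 3, 5, 4, 3)))
  tr <- dispersion_trend(summ, axis = "p_T")
  expect_equal(nrow(tr), 6L)
  g1 <- tr[grepl("^0.2", group)]
  expect_true(all(g1$monotone_increasing))
  g2 <- tr[grepl("^0.05", group)]
  expect_true(all(g2$monotone_decreasing))

  single <- list(dispersion = summ$dispersion[c(1, 4)])
  tr2 <- dispersion_trend(single, axis = "p_T")
  expect_true(all(is.na(tr2$monotone_increasing)))

  # permuted population labels: dispersion collapses toward 0
  panel <- data.table::data.table(sample = sprintf("S%03d", 1:90),
                                  pop = rep(c("P1", "P2", "P3"), each = 30),
                                  super_pop = "SP")
  set.seed(32)
  s <- rnorm(90) + rep(c(0, 3, 6), each = 30)
  prs <- data.table::data.table(sample = panel$sample, clump_label = "w",
                                r2_threshold = 0.2, reference_population = "ALL",
                                p_T = 1, score = s, n_variants = 1L)
  d_true <- population_summaries(prs, panel)$dispersion$dispersion
  perm_panel <- data.table::copy(panel)[, pop := sample(pop)]
  d_perm <- population_summaries(prs, perm_panel)$dispersion$dispersion
  expect_lt(d_perm, d_true / 10)
})

test_that("population exclusions reproduce the 2577 -> 1940 bookkeeping", {
  panel <- synthetic_1kg_panel()
  expect_equal(nrow(panel), 2577L)
  out <- apply_population_exclusions(panel)
  expect_equal(nrow(out), 1940L)
  lg <- filter_log(out)
  expect_equal(lg$removed, 105 + 86 + 96 + 85 + 66 + 96 + 103)
  expect_equal(lg$input - lg$removed, lg$retained)
  expect_equal(lg$PUR, 105)
  expect_equal(lg$CEU, 103)

  # empty rule list is the identity
  none <- apply_population_exclusions(panel, rules = default_exclusions()[0])
  expect_equal(nrow(none), 2577L)
  # excluding everything empties the panel with a warning
  all_rules <- data.table::data.table(pop = unique(panel$pop), reason = "no_phenotype")
  expect_warning(empty <- apply_population_exclusions(panel, all_rules), "empty")
  expect_equal(nrow(empty), 0L)
  expect_error(apply_population_exclusions(panel,
    data.table::data.table(pop = "XXX", reason = "no_phenotype")), "unknown")
})

test_that("phenotype correlation matches hand values and is affine-invariant", {
  pm <- data.table::data.table(pop = paste0("P", 1:5), mean = 1:5)
  ph <- data.table::data.table(pop = paste0("P", 1:5),
                               mean_phenotype = c(2, 1, 4, 3, 5))
  res <- phenotype_correlation(pm, ph)
  expect_equal(res$r, 0.8, tolerance = 1e-12)
  expect_equal(res$n_populations, 5L)
  # p from the t-distribution on n-2 df
  tstat <- 0.8 * sqrt(3 / (1 - 0.64))
  expect_equal(res$p, 2 * pt(tstat, df = 3, lower.tail = FALSE), tolerance = 1e-10)

  # exact affine relation: r = 1, minuscule p
  ph2 <- data.table::data.table(pop = paste0("P", 1:5),
                                mean_phenotype = 3 + 2 * (1:5))
  expect_equal(phenotype_correlation(pm, ph2)$r, 1, tolerance = 1e-12)

  # affine rescaling of either axis leaves r unchanged
  pm2 <- data.table::copy(pm)[, mean := 100 - 7 * mean]
  expect_equal(abs(phenotype_correlation(pm2, ph)$r), 0.8, tolerance = 1e-12)

  expect_error(phenotype_correlation(pm[1:2], ph), ">= 3 populations")
  ph3 <- data.table::copy(ph)[, mean_phenotype := 5]
  expect_error(phenotype_correlation(pm, ph3), "zero variance")
})

test_that("unbiased weights recover a positive population-level correlation", {
  ok <- logical(5)
  for (rep_i in 1:5) {
    anc <- sample_ancestral_freqs(800, seed = 400 + rep_i)
    pf <- balding_nichols_freqs(anc, rep(0.08, 5), seed = 410 + rep_i)
    tgt <- simulate_genotypes(pf, 80, block_size = 4, seed = 420 + rep_i)
    disc <- simulate_genotypes(balding_nichols_freqs(anc, 0.02, seed = 430 + rep_i),
                               500, block_size = 4, seed = 440 + rep_i)
    ph <- simulate_phenotype(disc$genotypes, 50, h2 = 0.6, seed = 450 + rep_i)
    ss <- run_gwas(disc$genotypes, ph$phenotype)
    # population phenotype means proportional to true genetic means
    g_t <- as.vector(tgt$genotypes$dosages %*% ph$truth$beta_true)
    ptab <- data.table::data.table(pop = tgt$panel$pop, g = g_t)[
      , .(mean_phenotype = mean(g)), by = pop]
    prs <- score_grid(tgt$genotypes, ss, tgt$panel,
                      list(clump_spec(r2_threshold = 0.2)), thresholds = 1)
    cell <- population_summaries(prs, tgt$panel)$summaries
    res <- phenotype_correlation(cell[, .(pop, mean)], ptab)
    ok[rep_i] <- res$r > 0
  }
  expect_gte(mean(ok), 0.8)
})
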