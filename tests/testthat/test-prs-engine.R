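test_that("harmonize orients weights to the target alt allele and logs actions", {
  gm <- make_gm(matrix(c(0L, 1L, 2L), 3, 4),
                ref = c("A", "A", "A", "C"), alt = c("G", "G", "T", "G"),
                ids = c("v1", "v2", "v3", "v4"))
  ss <- make_ss(c("v1", "v2", "v3", "v4", "v9"), 1, c(1000, 2000, 3000, 4000, 9000),
                beta = c(0.5, 0.5, 0.2, 0.1, 1),
                p = rep(0.01, 5),
                effect_allele = c("G", "A", "A", "T", "G"),
                other_allele  = c("A", "G", "T", "C", "A"))
  hw <- harmonize(ss, gm, drop_ambiguous = TRUE)
  act <- attr(hw, "actions")
  expect_equal(act$action,
               c("match", "sign_flip", "dropped_ambiguous", "dropped_mismatch",
                 "dropped_absent"))
  expect_equal(hw$weight, c(0.5, -0.5))
  lg <- filter_log(hw)
  expect_equal(lg$input, 5L)
  expect_equal(lg$retained, 2L)
  expect_equal(Reduce(`+`, lg[c("match", "sign_flip", "dropped_ambiguous",
                                "dropped_mismatch", "dropped_absent")]), 5L)

  # A/T variant kept (as a sign-flip to the target A<-T orientation) when the
  # ambiguity filter is off
  hw2 <- harmonize(ss, gm, drop_ambiguous = FALSE)
  expect_true("v3" %in% hw2$variant_id)

  # id-less rows fall back to the chrom:pos:alleles key
  ss_noid <- data.table::copy(ss[1:2])
  ss_noid[, variant_id := c(".", "")]
  hw3 <- harmonize(ss_noid, gm)
  expect_equal(hw3$variant_id, c("v1", "v2"))
  expect_equal(hw3$weight, c(0.5, -0.5))
})

test_that("ld_r2 matches the hand-computed Pearson square", {
  gm <- make_gm(cbind(c(0L, 1L, 2L, 2L), c(0L, 1L, 1L, 2L)))
  expect_equal(ld_r2(gm, "v001", "v002"), 8 / 11, tolerance = 1e-12)
  expect_equal(ld_r2(gm, "v001", "v001"), 1)
  mono <- make_gm(cbind(c(0L, 1L, 2L, 2L), 1L))
  expect_error(ld_r2(mono, 1, 2), "monomorphic")

  # independent variants: near-zero r2 on average
  big <- random_gm(2000, 30, seed = 81)
  cm <- cor(big$dosages)^2
  diag(cm) <- NA
  expect_lt(mean(cm, na.rm = TRUE), 0.01)
})

test_that("clump reproduces the 3-variant toy under both r2 thresholds", {
  # A and B 50 kb apart with r2 = 0.5625; C is 1.9 Mb away from A
  dos <- cbind(A = c(0L, 0L, 1L, 1L, 2L, 2L),
               B = c(0L, 1L, 0L, 1L, 2L, 2L),
               C = c(0L, 2L, 1L, 0L, 2L, 1L))
  ref <- make_gm(dos, pos = c(100000, 150000, 2000000), ids = c("A", "B", "C"))
  expect_equal(ld_r2(ref, "A", "B"), 0.5625, tolerance = 1e-12)
  ss <- make_ss(c("A", "B", "C"), 1, c(100000, 150000, 2000000),
                beta = c(0.3, 0.2, 0.1), p = c(1e-8, 1e-6, 1e-4))

  low <- clump(ss, ref, clump_spec(window_kb = 500, r2_threshold = 0.2))
  expect_equal(low$index$variant_id, c("A", "C"))
  expect_equal(low$assignment[variant_id == "B", index_id], "A")

  high <- clump(ss, ref, clump_spec(window_kb = 500, r2_threshold = 0.6))
  expect_equal(sort(high$index$variant_id), c("A", "B", "C"))

  # single variant clumps to itself
  solo <- clump(ss[1], ref, clump_spec())
  expect_equal(solo$index$variant_id, "A")

  # variants absent from the reference are dropped and counted
  ss2 <- rbind(ss, make_ss("Z", 1, 3000000, 0.1, 1e-9))
  cl2 <- clump(ss2, ref, clump_spec(r2_threshold = 0.2))
  expect_equal(cl2$n_dropped_absent, 1L)
  expect_false("Z" %in% cl2$index$variant_id)
  cl3 <- clump(ss2, ref, clump_spec(r2_threshold = 0.2), keep_unmatched = TRUE)
  expect_true("Z" %in% cl3$index$variant_id)

  expect_error(clump(make_ss("Z", 1, 1, 0.1, 1e-9), ref, clump_spec()),
               "no variants")
})

test_that("clump equals the brute-force oracle on random instances", {
  for (trial in 1:50) {
    set.seed(trial + 500)
    m <- sample(5:50, 1)
    ref <- random_gm(80, m, seed = trial,
                     chrom = sample(c("1", "2"), m, replace = TRUE),
                     pos = sort(sample.int(3e6, m)))
    ss <- make_ss(ref$variants$variant_id, ref$variants$chromosome,
                  ref$variants$position, beta = rnorm(m),
                  p = runif(m)^2)
    spec <- clump_spec(window_kb = sample(c(100, 500, 1000), 1),
                       r2_threshold = sample(c(0.05, 0.2, 0.5, 0.9), 1),
                       p1 = sample(c(0.5, 1), 1), p2 = sample(c(0.8, 1), 1))
    if (!any(ss$p <= spec$p1)) ss$p[1] <- spec$p1 / 2
    mine <- clump(ss, ref, spec)
    oracle <- brute_force_clump(ss, ref, spec)
    expect_equal(mine$index$variant_id, oracle$index_ids)
    got <- mine$assignment[order(variant_id)]
    expect_equal(stats::setNames(got$index_id, got$variant_id),
                 oracle$assignment[order(names(oracle$assignment))])
  }
})

test_that("clumped indices are pairwise separated in distance or LD", {
  ref <- random_gm(150, 120, seed = 91, pos = sort(sample.int(5e6, 120)))
  set.seed(92)
  ss <- make_ss(ref$variants$variant_id, "1", ref$variants$position,
                beta = rnorm(120), p = runif(120))
  spec <- clump_spec(window_kb = 300, r2_threshold = 0.1)
  cl <- clump(ss, ref, spec)
  ids <- cl$index$variant_id
  for (i in seq_along(ids)) for (j in seq_len(i - 1L)) {
    a <- cl$index[i]; b <- cl$index[j]
    apart <- a$chromosome != b$chromosome ||
      abs(a$position - b$position) > spec$window_kb * 1000
    expect_true(apart || ld_r2(ref, a$variant_id, b$variant_id) < spec$r2_threshold)
  }
})

test_that("thresholding is strict except at p_T = 1, and sets nest", {
  hw <- data.table::data.table(
    variant_id = paste0("v", 1:4), weight = 1,
    p = c(1e-9, 1e-7, 0.5, 1), action = "match")
  expect_equal(threshold_weights(hw, 5e-8)$variant_id, "v1")
  expect_equal(nrow(threshold_weights(hw, 1)), 4L)        # inclusive at 1
  expect_equal(nrow(threshold_weights(hw, 0.5)), 2L)      # strict below 1
  prev <- character(0)
  for (pt in default_thresholds()) {
    cur <- threshold_weights(hw, pt)$variant_id
    expect_true(all(prev %in% cur))
    prev <- cur
  }
  expect_equal(length(default_thresholds()), 13L)
  expect_true(all(diff(default_thresholds()) > 0))
})

test_that("score computes weighted dosage sums with the stated conventions", {
  gm <- make_gm(matrix(c(2L, 1L, 0L), 3, 1), ids = "v1")
  w1 <- data.table::data.table(variant_id = "v1", weight = 0.5, p = 0.01)
  s <- score(gm, w1, mode = "sum")
  expect_equal(unname(as.vector(s)), c(1.0, 0.5, 0.0))
  # average mode divides the sum by 2 x (number of weighted variants)
  expect_equal(unname(as.vector(score(gm, w1, mode = "average"))[1]), 0.5)

  gm2 <- make_gm(cbind(c(2L, 2L), c(1L, 1L)), ids = c("v1", "v2"))
  w2 <- data.table::data.table(variant_id = c("v1", "v2"), weight = c(0.5, -1),
                               p = c(0.01, 0.01))
  expect_equal(unname(as.vector(score(gm2, w2))), c(0, 0))

  # zero weights give zero scores; fully absent weights are an error
  w0 <- data.table::data.table(variant_id = c("v1", "v2"), weight = 0, p = 0.5)
  expect_true(all(score(gm2, w0) == 0))
  wz <- data.table::data.table(variant_id = "nope", weight = 1, p = 0.5)
  expect_error(score(gm2, wz), "none of the weighted variants")

  # missing dosages: cohort-mean policy vs zero policy
  gm3 <- make_gm(matrix(c(2L, NA, 0L), 3, 1), ids = "v1")
  sm <- score(gm3, w1, missing_policy = "mean")
  expect_equal(unname(as.vector(sm)), c(1.0, 0.5, 0.0))   # mean dosage = 1
  sz <- score(gm3, w1, missing_policy = "zero")
  expect_equal(unname(as.vector(sz))[2], 0.0)

  # additivity over a partition of the weights
  gmr <- random_gm(40, 12, seed = 101)
  wr <- data.table::data.table(variant_id = gmr$variants$variant_id,
                               weight = rnorm(12), p = runif(12))
  whole <- score(gmr, wr)
  parts <- score(gmr, wr[1:5]) + score(gmr, wr[6:12])
  expect_equal(as.vector(whole), as.vector(parts), tolerance = 1e-12)
})

test_that("orientation invariance: flipped target coding leaves centered scores unchanged", {
  set.seed(111)
  for (trial in 1:5) {
    gm <- random_gm(60, 10, seed = trial + 200)
    ss <- make_ss(gm$variants$variant_id, "1", gm$variants$position,
                  beta = rnorm(10), p = runif(10))
    base <- score(gm, harmonize(ss, gm))
    flip_j <- sample(10, 3)
    gm2 <- gm
    gm2$variants <- data.table::copy(gm$variants)
    for (j in flip_j) {
      r <- gm2$variants$ref_allele[j]
      gm2$variants$ref_allele[j] <- gm2$variants$alt_allele[j]
      gm2$variants$alt_allele[j] <- r
      gm2$dosages[, j] <- 2L - gm2$dosages[, j]
    }
    flipped <- score(gm2, harmonize(ss, gm2))
    expect_equal(as.vector(flipped) - mean(flipped),
                 as.vector(base) - mean(base), tolerance = 1e-12)
  }
})

test_that("score_grid produces the factorial grid with nested variant counts", {
  cfg <- sim_config(seed = 15, n_pops = 3, n_per_pop = 60, n_variants = 300,
                    n_causal = 30, block_size = 6)
  sim <- simulate_cohort(cfg)
  ss <- run_gwas(sim$genotypes, sim$phenotype)
  specs <- list(clump_spec(r2_threshold = 0.2, reference_population = "ALL"),
                clump_spec(r2_threshold = 0.2, reference_population = "POP1"))
  prs <- score_grid(sim$genotypes, ss, sim$panel, specs)

  expect_equal(nrow(prs), 180 * 2 * 13)       # samples x specs x thresholds
  expect_equal(length(unique(prs$p_T)), 13L)
  # contributing-variant count never decreases with p_T
  counts <- unique(prs[, c("clump_label", "p_T", "n_variants")])
  for (lab in unique(counts$clump_label)) {
    x <- counts[counts$clump_label == lab, ][order(p_T)]
    expect_true(all(diff(x$n_variants) >= 0))
  }
  # sample order preserved in every cell
  expect_equal(prs$sample[1:180], sim$genotypes$samples)
  expect_error(
    score_grid(sim$genotypes, ss, sim$panel,
               list(clump_spec(reference_population = "NOPE"))),
    "not present in the panel")
})
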