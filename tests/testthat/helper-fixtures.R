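# Fixture builders and independent oracles shared across the suite.
# Everything is generated in code; nothing binary ships with the package.

# ---- VCF fixtures -----------------------------------------------------------

# 10-record VCF with 3 designed failures: one indel, one triallelic site and
# one monomorphic (MAF 0) SNP -> 7 biallelic polymorphic SNPs survive loading.
write_toy_vcf <- function(path, n_samples = 4L) {
  stopifnot(n_samples == 4L)
  gt <- function(...) paste(c(...), collapse = "\t")
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", paste0("S", 1:4)), collapse = "\t"),
    paste("1", 1000, "rs1", "A", "G", ".", "PASS", ".", "GT",
          gt("0/0", "0/1", "1/1", "0/1"), sep = "\t"),
    paste("1", 2000, "rs2", "C", "T", ".", "PASS", ".", "GT",
          gt("0/0", "0/0", "0/0", "0/1"), sep = "\t"),      # MAF 0.125
    paste("1", 3000, "rs3_indel", "CT", "C", ".", "PASS", ".", "GT",
          gt("0/0", "0/1", "0/0", "0/0"), sep = "\t"),      # indel: dropped
    paste("1", 4000, "rs4_tri", "G", "A,T", ".", "PASS", ".", "GT",
          gt("0/0", "0/1", "0/2", "0/0"), sep = "\t"),      # triallelic: dropped
    paste("1", 5000, "rs5_mono", "T", "C", ".", "PASS", ".", "GT",
          gt("0/0", "0/0", "0/0", "0/0"), sep = "\t"),      # MAF 0: dropped
    paste("2", 1000, "rs6", "G", "C", ".", "PASS", ".", "GT",
          gt("0/1", "0/1", "1/1", "0/0"), sep = "\t"),
    paste("2", 2000, "rs7", "A", "T", ".", "PASS", ".", "GT",
          gt("1/1", "0/1", "0/0", "0/1"), sep = "\t"),
    paste("2", 3000, "rs8", "C", "A", ".", "PASS", ".", "GT",
          gt("0/0", "./.", "0/1", "1/1"), sep = "\t"),      # has a missing call
    paste("2", 4000, "rs9", "T", "G", ".", "PASS", ".", "GT",
          gt("0/1", "0/0", "0/1", "0/1"), sep = "\t"),
    paste("2", 5000, "rs10", "G", "T", ".", "PASS", ".", "GT",
          gt("1/1", "1/1", "0/1", "0/0"), sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

# ---- small genotype fixtures ------------------------------------------------

make_gm <- function(dosages, chrom = NULL, pos = NULL, ref = NULL, alt = NULL,
                    ids = NULL) {
  m <- ncol(dosages)
  variants <- data.table::data.table(
    variant_id = if (is.null(ids)) sprintf("v%03d", seq_len(m)) else ids,
    chromosome = if (is.null(chrom)) rep("1", m) else chrom,
    position   = if (is.null(pos)) seq_len(m) * 1000L else as.integer(pos),
    ref_allele = if (is.null(ref)) rep("A", m) else ref,
    alt_allele = if (is.null(alt)) rep("G", m) else alt
  )
  genotype_matrix(dosages,
                  variants,
                  sprintf("S%03d", seq_len(nrow(dosages))))
}

random_gm <- function(n, m, freq = NULL, seed = 1L, chrom = NULL, pos = NULL) {
  set.seed(seed)
  if (is.null(freq)) freq <- runif(m, 0.1, 0.9)
  d <- sapply(freq, function(f) rbinom(n, 2L, f))
  make_gm(d, chrom = chrom, pos = pos)
}

make_ss <- function(variant_id, chromosome, position, beta, p,
                    effect_allele = "G", other_allele = "A", se = 0.1) {
  data.table::data.table(
    variant_id = variant_id, chromosome = as.character(chromosome),
    position = as.integer(position),
    effect_allele = rep_len(effect_allele, length(variant_id)),
    other_allele = rep_len(other_allele, length(variant_id)),
    beta = beta, se = rep_len(se, length(variant_id)), p = p)
}

# ---- independent clumping oracle -------------------------------------------
# Literal restatement of the greedy rules, written as a naive "pick the best
# remaining variant each round" loop (quadratic; instances stay tiny).
brute_force_clump <- function(ss, reference, spec) {
  tv <- reference$variants
  rows <- ss[!is.na(match(ss$variant_id, tv$variant_id))]
  rows <- rows[order(rows$p, rows$chromosome, rows$position, rows$variant_id)]
  unassigned <- rep(TRUE, nrow(rows))
  index_ids <- character(0)
  assignment <- stats::setNames(rep(NA_character_, nrow(rows)), rows$variant_id)
  repeat {
    elig <- which(unassigned & rows$p <= spec$p1)
    if (!length(elig)) break
    i <- elig[1L]                       # rows already in greedy order
    unassigned[i] <- FALSE
    index_ids <- c(index_ids, rows$variant_id[i])
    assignment[rows$variant_id[i]] <- rows$variant_id[i]
    gi <- reference$dosages[, match(rows$variant_id[i], tv$variant_id)]
    for (j in which(unassigned)) {
      if (rows$p[j] > spec$p2) next
      if (rows$chromosome[j] != rows$chromosome[i]) next
      if (abs(rows$position[j] - rows$position[i]) > spec$window_kb * 1000) next
      gj <- reference$dosages[, match(rows$variant_id[j], tv$variant_id)]
      ok <- !is.na(gi) & !is.na(gj)
      if (sum(ok) < 2L) next
      if (stats::var(gi[ok]) == 0 || stats::var(gj[ok]) == 0) next
      if (stats::cor(gi[ok], gj[ok])^2 >= spec$r2_threshold) {
        unassigned[j] <- FALSE
        assignment[rows$variant_id[j]] <- rows$variant_id[i]
      }
    }
  }
  list(index_ids = index_ids, assignment = assignment)
}

# ---- Hudson-style FST oracle ------------------------------------------------
# Ratio-of-averages estimator: 1 - mean(Hw) / mean(Hb), with the within-
# population heterozygosity made unbiased for allele-count 2n.
hudson_fst <- function(p1, p2, n1, n2) {
  hw <- (2 * p1 * (1 - p1) * 2 * n1 / (2 * n1 - 1) +
           2 * p2 * (1 - p2) * 2 * n2 / (2 * n2 - 1)) / 2
  hb <- p1 * (1 - p2) + p2 * (1 - p1)
  1 - mean(hw) / mean(hb)
}

# One C+T score in a target subset, for the portability experiments.
ct_score_r2 <- function(gm_target, y_target, ss, reference, r2 = 0.2, p_T = 0.05) {
  cl <- clump(ss, reference, clump_spec(r2_threshold = r2))
  hw <- harmonize(cl$index, gm_target)
  wt <- threshold_weights(hw, p_T)
  s <- score(gm_target, wt)
  if (stats::sd(s) == 0) return(0)
  stats::cor(y_target, as.vector(s))^2
}
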