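#' Read genotypes from a VCF and apply the loading filters
#'
#' Loads a VCF 4.x file (plain or gzipped), keeps only biallelic single
#' nucleotide variants, converts GT calls to additive alt-allele dosages, and
#' removes variants whose minor-allele frequency -- computed from the
#' non-missing dosages of the loaded cohort -- is not greater than `maf_min`.
#' The default `maf_min = 0.001` reproduces the conventional "> 0.1% MAF"
#' cleaning step applied to reference panels before polygenic scoring.
#'
#' @param path VCF file path.
#' @param maf_min minor-allele-frequency floor in `[0, 0.5)`; variants with
#'   `MAF <= maf_min` are removed (so monomorphic variants never survive).
#' @return a [genotype_matrix()] with a [filter_log()] attribute recording
#'   `input`, `removed_not_biallelic_snp`, `removed_maf`, `retained`.
#' @export
read_genotypes <- function(path, maf_min = 0.001) {
  if (!is.numeric(maf_min) || maf_min < 0 || maf_min >= 0.5)
    stop("maf_min must be in [0, 0.5)")
  if (!file.exists(path)) stop("no such file: ", path)
  vcf <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(path)),
    error = function(e) stop("malformed VCF '", path, "': ", conditionMessage(e),
                             call. = FALSE)
  )
  rr <- SummarizedExperiment::rowRanges(vcf)
  n_in <- length(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  altl <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(altl)
  alt1 <- rep(NA_character_, n_in)
  alt1[n_alt == 1L] <- as.character(unlist(altl[n_alt == 1L]))
  nt <- c("A", "C", "G", "T")
  is_snp <- n_alt == 1L & ref %in% nt & alt1 %in% nt & !is.na(alt1) & ref != alt1

  ids <- names(rr)
  if (is.null(ids)) ids <- paste0(as.character(GenomicRanges::seqnames(rr)), ":",
                                  GenomicRanges::start(rr))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate variant_id in '", path, "': ", paste(dup, collapse = ", "))

  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF '", path, "' has no GT genotype field")
  dos <- gt_to_dosage(gt)           # variants x samples
  dos <- t(dos[is_snp, , drop = FALSE])

  variants <- data.table::data.table(
    variant_id = ids[is_snp],
    chromosome = as.character(GenomicRanges::seqnames(rr))[is_snp],
    position   = GenomicRanges::start(rr)[is_snp],
    ref_allele = ref[is_snp],
    alt_allele = alt1[is_snp]
  )
  gm <- genotype_matrix(dos, variants, colnames(gt))
  f <- maf(gm)
  keep <- !is.nan(f) & f > maf_min
  out <- subset_genotypes(gm, variants = keep)
  attr(out, "filter_log") <- list(
    input = n_in,
    removed_not_biallelic_snp = n_in - sum(is_snp),
    removed_maf = sum(!keep),
    retained = sum(keep)
  )
  out
}

# "0/1", "0|1", "./." ... -> alt-allele count; any non-ref allele index must
# be 1 (callers filter to biallelic first).
gt_to_dosage <- function(gt) {
  u <- unique(as.vector(gt))
  lut <- vapply(u, function(g) {
    al <- strsplit(gsub("\\|", "/", g), "/", fixed = TRUE)[[1]]
    if (any(al == "." | al == "")) return(NA_integer_)
    sum(as.integer(al) > 0L)
  }, integer(1))
  m <- matrix(lut[match(as.vector(gt), u)], nrow = nrow(gt),
              dimnames = dimnames(gt))
  m
}

#' Serialize a genotype matrix to a minimal VCF
#'
#' Writes a VCF 4.2 file with only the GT field, suitable for round-tripping a
#' [genotype_matrix()] through [read_genotypes()]. Missing dosages are written
#' as `./.`; dosage 1 is written as `0/1` (phase information is not retained).
#'
#' @param x a `genotype_matrix`
#' @param path output path (plain text)
#' @return `path`, invisibly
#' @export
write_genotypes_vcf <- function(x, path) {
  gtcode <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  d <- x$dosages
  gt <- matrix(gtcode[as.character(d)], nrow = nrow(d))
  gt[is.na(d)] <- "./."
  v <- x$variants
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", x$samples), collapse = "\t")
  )
  body <- paste(v$chromosome, v$position, v$variant_id, v$ref_allele,
                v$alt_allele, ".", "PASS", ".", "GT",
                apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

.default_sumstats_map <- function(effect_scale) {
  list(variant_id = "SNP", chromosome = "CHR", position = "BP",
       effect_allele = "A1", other_allele = "A2",
       effect = if (effect_scale == "odds_ratio") "OR" else "BETA",
       se = "SE", p = "P")
}

#' Read GWAS summary statistics
#'
#' Reads a delimited summary-statistics file into the standard per-variant
#' table (`variant_id`, `chromosome`, `position`, `effect_allele`,
#' `other_allele`, `beta`, `se`, `p`). Odds ratios are stored on the log
#' scale (`beta = log(OR)`). Rows with `p` outside `(0, 1]`, with missing
#' alleles, or (for the odds-ratio scale) with `OR <= 0` are dropped and
#' counted in the [filter_log()].
#'
#' @param path delimited text file (separator sniffed by `data.table::fread`).
#' @param column_map named list mapping the canonical field names
#'   (`variant_id`, `chromosome`, `position`, `effect_allele`, `other_allele`,
#'   `effect`, `se`, `p`) to column names in the file. Defaults follow the
#'   common `SNP/CHR/BP/A1/A2/BETA|OR/SE/P` layout.
#' @param effect_scale `"beta"` (linear-scale effect, stored as-is) or
#'   `"odds_ratio"` (stored as `log(OR)`).
#' @return `data.table` of summary statistics with a [filter_log()] attribute.
#' @export
read_sumstats <- function(path, column_map = NULL,
                          effect_scale = c("beta", "odds_ratio")) {
  effect_scale <- match.arg(effect_scale)
  map <- .default_sumstats_map(effect_scale)
  if (!is.null(column_map)) map[names(column_map)] <- column_map
  dt <- data.table::fread(path)
  missing_cols <- setdiff(unlist(map), names(dt))
  if (length(missing_cols))
    stop("summary-statistics file lacks mapped column(s): ",
         paste(missing_cols, collapse = ", "))
  ss <- data.table::data.table(
    variant_id    = as.character(dt[[map$variant_id]]),
    chromosome    = as.character(dt[[map$chromosome]]),
    position      = as.integer(dt[[map$position]]),
    effect_allele = toupper(as.character(dt[[map$effect_allele]])),
    other_allele  = toupper(as.character(dt[[map$other_allele]])),
    effect        = as.numeric(dt[[map$effect]]),
    se            = as.numeric(dt[[map$se]]),
    p             = as.numeric(dt[[map$p]])
  )
  n_in <- nrow(ss)
  bad_p <- is.na(ss$p) | ss$p <= 0 | ss$p > 1
  bad_allele <- is.na(ss$effect_allele) | is.na(ss$other_allele) |
    ss$effect_allele == "" | ss$other_allele == "" |
    ss$effect_allele == ss$other_allele
  bad_or <- if (effect_scale == "odds_ratio") (is.na(ss$effect) | ss$effect <= 0)
            else rep(FALSE, n_in)
  drop <- bad_p | bad_allele | bad_or
  ss <- ss[!drop]
  ss[, beta := if (effect_scale == "odds_ratio") log(effect) else effect]
  ss[, effect := NULL]
  data.table::setcolorder(ss, c("variant_id", "chromosome", "position",
                                "effect_allele", "other_allele", "beta", "se", "p"))
  dup <- unique(ss$variant_id[duplicated(ss$variant_id)])
  if (length(dup))
    stop("duplicate variant_id in summary statistics: ",
         paste(utils::head(dup, 10), collapse = ", "))
  attr(ss, "filter_log") <- list(
    input = n_in,
    removed_bad_p = sum(bad_p),
    removed_bad_allele = sum(bad_allele & !bad_p),
    removed_nonpositive_or = sum(bad_or & !bad_p & !bad_allele),
    retained = nrow(ss)
  )
  ss[]
}

#' Read a sample panel (1000Genomes `.panel` layout)
#'
#' Expects a whitespace- or tab-delimited file with a header containing at
#' least `sample`, `pop`, `super_pop` (extra columns such as `gender` are
#' ignored). Duplicate consistent lines are deduplicated with a warning;
#' a sample listed with two different populations is an error.
#'
#' @param path panel file path
#' @return `data.table` with columns `sample`, `pop`, `super_pop`
#' @export
read_panel <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  req <- c("sample", "pop", "super_pop")
  if (!all(req %in% names(dt)))
    stop("panel file must have header columns: ", paste(req, collapse = ", "))
  dt <- dt[, req, with = FALSE]
  dt[, (req) := lapply(.SD, as.character)]
  if (anyDuplicated(dt)) {
    warning("panel contains duplicate lines; deduplicating")
    dt <- unique(dt)
  }
  conf <- dt[, .N, by = sample][N > 1L, sample]
  if (length(conf))
    stop("sample(s) listed with conflicting populations: ",
         paste(conf, collapse = ", "))
  nest <- unique(dt[, .(pop, super_pop)])[, .N, by = pop][N > 1L, pop]
  if (length(nest))
    stop("population(s) assigned to multiple superpopulations: ",
         paste(nest, collapse = ", "))
  dt[]
}

.metric_types <- c("variance_explained", "beta", "odds_ratio", "auc")

#' Read a curated study-comparison table
#'
#' One row per matched (European, non-European) effect-size pair extracted
#' from a publication. `metric_type` must be one of `variance_explained`,
#' `beta`, `odds_ratio`, `auc` and applies to both effects of the row.
#'
#' @param path CSV with header `study_id, phenotype, ancestry_group,
#'   metric_type, effect_eur, effect_noneur, significant_noneur`.
#' @return `data.table` study-comparison table
#' @export
read_study_table <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  req <- c("study_id", "phenotype", "ancestry_group", "metric_type",
           "effect_eur", "effect_noneur", "significant_noneur")
  miss <- setdiff(req, names(dt))
  if (length(miss)) stop("study table lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(dt) == 0L) {
    warning("study table is empty")
    return(dt[])
  }
  bad <- which(!dt$metric_type %in% .metric_types)
  if (length(bad))
    stop("unknown metric_type in row(s) ", paste(bad, collapse = ", "), ": ",
         paste(unique(dt$metric_type[bad]), collapse = ", "))
  if (any(!is.finite(dt$effect_eur)) || any(!is.finite(dt$effect_noneur)))
    stop("non-finite effect values in study table")
  dt[, significant_noneur := as.logical(significant_noneur)]
  dt[]
}

#' Build or read a population-phenotype table
#'
#' `build_phenotype_table()` averages male and female country means into one
#' mean phenotype per population (the convention for country-height tables);
#' `read_phenotype_table()` reads an already-averaged CSV with columns
#' `pop, mean_phenotype`.
#'
#' @param pop population codes
#' @param male,female per-population male and female means (same units)
#' @return `data.table` with columns `pop`, `mean_phenotype`
#' @export
build_phenotype_table <- function(pop, male, female) {
  if (anyDuplicated(pop)) stop("duplicate population codes")
  if (any(!is.finite(male)) || any(!is.finite(female)))
    stop("non-finite phenotype values")
  data.table::data.table(pop = as.character(pop),
                         mean_phenotype = (male + female) / 2)
}

#' @rdname build_phenotype_table
#' @param path CSV file path
#' @export
read_phenotype_table <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  if (!all(c("pop", "mean_phenotype") %in% names(dt)))
    stop("phenotype table must have columns: pop, mean_phenotype")
  if (anyDuplicated(dt$pop)) stop("duplicate population codes in phenotype table")
  if (any(!is.finite(dt$mean_phenotype))) stop("non-finite phenotype values")
  dt[, .(pop = as.character(pop), mean_phenotype = as.numeric(mean_phenotype))]
}

#' Write / read a polygenic-score table
#'
#' Scores are written as CSV with one row per (sample, clump specification,
#' p-value threshold) cell. The write -> read round trip preserves scores to
#' full double precision.
#'
#' @param prs a score table from [score_grid()]
#' @param path output CSV path
#' @return `path` invisibly (writer); score `data.table` (reader)
#' @export
write_scores <- function(prs, path) {
  data.table::fwrite(data.table::as.data.table(prs), path)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  req <- c("sample", "clump_label", "p_T", "score", "n_variants")
  miss <- setdiff(req, names(dt))
  if (length(miss)) stop("score file lacks column(s): ", paste(miss, collapse = ", "))
  dt[]
}
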