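#' Additive-dosage genotype container
#'
#' A `genotype_matrix` holds a samples x variants matrix of alt-allele counts
#' (0, 1, 2, or `NA` for missing) together with the variant metadata needed for
#' harmonization, clumping and region masking. Sample order is preserved from
#' the source file and never reordered by any operation in this package.
#'
#' @param dosages integer matrix, samples in rows, variants in columns;
#'   entries in \{0, 1, 2, NA\}.
#' @param variants `data.table` with columns `variant_id`, `chromosome`,
#'   `position` (1-based), `ref_allele`, `alt_allele`.
#' @param samples character vector of sample identifiers, one per dosage row.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, variants, samples) {
  variants <- data.table::as.data.table(variants)
  req <- c("variant_id", "chromosome", "position", "ref_allele", "alt_allele")
  miss <- setdiff(req, names(variants))
  if (length(miss)) stop("variant metadata lacks column(s): ", paste(miss, collapse = ", "))
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  if (nrow(dosages) != length(samples))
    stop("dosage rows (", nrow(dosages), ") != number of samples (", length(samples), ")")
  if (ncol(dosages) != nrow(variants))
    stop("dosage columns (", ncol(dosages), ") != number of variants (", nrow(variants), ")")
  bad <- dosages[!is.na(dosages)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("dosages must be 0, 1, 2 or NA")
  if (anyDuplicated(variants$variant_id))
    stop("duplicate variant ids: ",
         paste(unique(variants$variant_id[duplicated(variants$variant_id)]), collapse = ", "))
  if (any(variants$position < 1L)) stop("positions must be >= 1 (1-based)")
  dimnames(dosages) <- list(samples, variants$variant_id)
  structure(list(dosages = dosages, variants = variants, samples = as.character(samples)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix: ", length(x$samples), " samples x ", nrow(x$variants),
      " variants\n", sep = "")
  nmiss <- sum(is.na(x$dosages))
  cat("  chromosomes: ", paste(unique(x$variants$chromosome), collapse = ", "),
      "; missing dosages: ", nmiss, "\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Number of samples / variants
#' @param x a `genotype_matrix`
#' @return integer count
#' @export
n_samples <- function(x) length(x$samples)

#' @rdname n_samples
#' @export
n_variants <- function(x) nrow(x$variants)

#' Subset a genotype matrix
#'
#' @param x a `genotype_matrix`
#' @param samples character vector of sample ids or logical/integer index;
#'   `NULL` keeps all. Order of `x` is preserved regardless of request order.
#' @param variants character vector of variant ids or logical/integer index;
#'   `NULL` keeps all.
#' @return a `genotype_matrix`
#' @export
subset_genotypes <- function(x, samples = NULL, variants = NULL) {
  si <- seq_along(x$samples)
  if (!is.null(samples)) {
    si <- if (is.character(samples)) which(x$samples %in% samples) else si[samples]
  }
  vi <- seq_len(nrow(x$variants))
  if (!is.null(variants)) {
    vi <- if (is.character(variants)) which(x$variants$variant_id %in% variants) else vi[variants]
  }
  genotype_matrix(x$dosages[si, vi, drop = FALSE], x$variants[vi], x$samples[si])
}

#' Alt-allele frequency per variant
#'
#' Computed from non-missing dosages of the loaded cohort (never from file
#' INFO fields).
#'
#' @param x a `genotype_matrix`
#' @return numeric vector, one frequency per variant (NaN if all missing)
#' @export
alt_freq <- function(x) {
  colMeans(x$dosages, na.rm = TRUE) / 2
}

#' Minor-allele frequency per variant
#' @param x a `genotype_matrix`
#' @return numeric vector in [0, 0.5]
#' @export
maf <- function(x) {
  f <- alt_freq(x)
  pmin(f, 1 - f)
}

#' Retrieve the filter log attached by a loading/filtering operation
#'
#' Every filtering operation records how many records it kept and removed;
#' `retained + removed` always equals the input count.
#'
#' @param x an object returned by a reader or filter
#' @return a list of counts, or `NULL` if none attached
#' @export
filter_log <- function(x) attr(x, "filter_log", exact = TRUE)
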