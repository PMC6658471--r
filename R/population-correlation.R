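#' Per-population score-distribution summaries and dispersion
#'
#' For every grid cell (clump specification x p_T) and population: the mean,
#' standard deviation and size of the population's score distribution; per
#' cell additionally a between-population dispersion statistic, the variance
#' of population means divided by the pooled within-population variance.
#' Dispersion 0 means identical population means; large values mean the
#' populations' score distributions have drifted apart relative to their
#' internal spread.
#'
#' @param prs a `prs_matrix` from [score_grid()]
#' @param panel sample panel covering every scored sample
#' @param standardize z-standardize scores against the pooled cohort within
#'   each grid cell before summarizing (default `FALSE`: raw scores)
#' @return list: `summaries` (`data.table` pop x cell with `mean`, `sd`, `n`;
#'   populations of size 1 have `sd = NA` and are flagged) and `dispersion`
#'   (`data.table` per cell)
#' @export
population_summaries <- function(prs, panel, standardize = FALSE) {
  prs <- data.table::as.data.table(prs)
  panel <- data.table::as.data.table(panel)
  missing_s <- setdiff(unique(prs$sample), panel$sample)
  if (length(missing_s))
    stop("scored sample(s) absent from panel: ",
         paste(utils::head(missing_s, 5), collapse = ", "))
  dt <- merge(prs, panel[, .(sample, pop)], by = "sample", sort = FALSE)
  if (standardize)
    dt[, score := if (stats::sd(score) > 0) (score - mean(score)) / stats::sd(score)
                  else score - mean(score),
       by = .(clump_label, p_T)]
  summ <- dt[, .(mean = mean(score),
                 sd = if (.N > 1L) stats::sd(score) else NA_real_,
                 n = .N,
                 sd_undefined = .N == 1L),
             by = .(pop, clump_label, r2_threshold, reference_population, p_T)]
  disp <- summ[, .(dispersion = {
    wv <- stats::weighted.mean(sd^2, w = n - 1L, na.rm = TRUE)
    if (!is.finite(wv) || wv == 0) if (stats::var(mean) == 0) 0 else Inf
    else stats::var(mean) / wv
  }, n_pops = .N),
  by = .(clump_label, r2_threshold, reference_population, p_T)]
  list(summaries = summ[], dispersion = disp[])
}

#' Dispersion along one axis of the construction grid
#'
#' Orders the between-population dispersion values along one methodological
#' axis (`p_T`, clumping `r2`, or LD reference population) with all other
#' grid factors held fixed, and flags whether the sequence is monotone.
#'
#' @param pop_summ output of [population_summaries()]
#' @param axis `"p_T"`, `"r2"`, or `"reference_pop"`
#' @return `data.table` of dispersion values ordered along the axis, one
#'   group per fixed combination of the other factors, with
#'   `monotone_increasing` / `monotone_decreasing` flags (`NA` when the axis
#'   has a single level)
#' @export
dispersion_trend <- function(pop_summ, axis = c("p_T", "r2", "reference_pop")) {
  axis <- match.arg(axis)
  disp <- data.table::copy(pop_summ$dispersion)
  axis_col <- switch(axis, p_T = "p_T", r2 = "r2_threshold",
                     reference_pop = "reference_population")
  fixed <- setdiff(c("p_T", "r2_threshold", "reference_population"), axis_col)
  data.table::setorderv(disp, c(fixed, axis_col))
  disp[, group := do.call(paste, c(.SD, sep = "|")), .SDcols = fixed]
  out <- disp[, .(
    axis_value = get(axis_col), dispersion = dispersion,
    monotone_increasing = if (.N < 2L) NA else all(diff(dispersion) >= 0),
    monotone_decreasing = if (.N < 2L) NA else all(diff(dispersion) <= 0)
  ), by = group]
  out[]
}

#' Default population exclusions for the phenotype-correlation analysis
#'
#' Seven 1000Genomes populations conventionally excluded before correlating
#' population score means with country phenotype means: four with no usable
#' country phenotype (PUR, BEB, PJL, MSL), two admixed cohorts of mixed
#' country origin (ASW, ACB), and one without a single country of origin
#' (CEU).
#'
#' @return `data.table` of `ExclusionRule`s: `pop`, `reason`
#' @export
default_exclusions <- function() {
  data.table::data.table(
    pop = c("PUR", "BEB", "PJL", "MSL", "ASW", "ACB", "CEU"),
    reason = c("no_phenotype", "no_phenotype", "no_phenotype", "no_phenotype",
               "admixed_mixed_origin", "admixed_mixed_origin",
               "no_single_country")
  )
}

#' Apply population exclusion rules to a sample panel
#'
#' Removes every sample of each excluded population and logs the removed
#' count per rule; excluded + retained always equals the input count.
#'
#' @param panel sample panel (`sample`, `pop`, `super_pop`)
#' @param rules `data.table` with columns `pop`, `reason`
#'   (default [default_exclusions()])
#' @return filtered panel with a [filter_log()] listing per-rule removals
#' @export
apply_population_exclusions <- function(panel, rules = default_exclusions()) {
  panel <- data.table::as.data.table(panel)
  rules <- data.table::as.data.table(rules)
  if (anyDuplicated(rules$pop)) stop("duplicate population codes in rules")
  unknown <- setdiff(rules$pop, unique(panel$pop))
  if (length(unknown))
    stop("unknown population code(s) in rules: ", paste(unknown, collapse = ", "))
  out <- panel[!pop %in% rules$pop]
  if (nrow(out) == 0L) warning("all populations excluded: empty panel")
  per_rule <- stats::setNames(
    lapply(rules$pop, function(p) sum(panel$pop == p)), rules$pop)
  attr(out, "filter_log") <- c(list(input = nrow(panel), retained = nrow(out),
                                    removed = nrow(panel) - nrow(out)),
                               per_rule)
  out[]
}

#' Correlation between population mean scores and population phenotypes
#'
#' Pearson correlation across populations between the mean polygenic score
#' of each population (one grid cell) and the population's mean phenotype,
#' with a two-sided p-value from the t-distribution on `n - 2` degrees of
#' freedom. Populations are weighted equally (one point per population).
#'
#' @param pop_means `data.table` with columns `pop`, `mean` -- e.g. one grid
#'   cell of `population_summaries()$summaries`
#' @param phenotype_table `data.table` with `pop`, `mean_phenotype`
#'   ([build_phenotype_table()])
#' @return list: `r`, `p`, `n_populations`
#' @export
phenotype_correlation <- function(pop_means, phenotype_table) {
  pop_means <- data.table::as.data.table(pop_means)
  dt <- merge(pop_means[, .(pop, mean)], phenotype_table, by = "pop")
  if (nrow(dt) < 3L)
    stop("need >= 3 populations after joining; got ", nrow(dt))
  if (stats::var(dt$mean) == 0 || stats::var(dt$mean_phenotype) == 0)
    stop("zero variance on one axis: correlation undefined")
  ct <- stats::cor.test(dt$mean, dt$mean_phenotype, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n_populations = nrow(dt))
}
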