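#' Within-study relative performance of a non-European polygenic score
#'
#' Expresses each non-European effect size as a percentage of the matched
#' European effect from the same study: `100 * noneur / eur` for variance
#' explained, regression betas and AUC, and `100 * log(OR_noneur) /
#' log(OR_eur)` for odds ratios (ratios of odds ratios are only meaningful on
#' the log scale). Parity with the European sample is 100; opposite-direction
#' effects yield negative percentages and are retained. With
#' `auc_above_chance = TRUE`, AUC rows are ratioed as `(AUC - 0.5)` excesses
#' instead of raw AUC values.
#'
#' @param comparisons a study-comparison `data.table`
#'   ([read_study_table()] / [simulate_study_table()])
#' @param auc_above_chance ratio AUC rows on the above-chance scale
#'   (default `FALSE`: raw AUC ratio)
#' @return `data.table`: `study_id`, `phenotype`, `ancestry_group`,
#'   `metric_type`, `relative_pct`
#' @export
relative_effect <- function(comparisons, auc_above_chance = FALSE) {
  dt <- data.table::as.data.table(comparisons)
  bad <- which(!dt$metric_type %in% .metric_types)
  if (length(bad)) stop("unknown metric_type in row(s) ", paste(bad, collapse = ", "))
  if (any(!is.finite(dt$effect_eur)) || any(!is.finite(dt$effect_noneur)))
    stop("non-finite effect values")
  eur <- dt$effect_eur; noneur <- dt$effect_noneur
  is_or <- dt$metric_type == "odds_ratio"
  if (any(is_or & (eur <= 0 | noneur <= 0)))
    stop("odds ratios must be > 0")
  if (any(is_or & eur == 1))
    stop("undefined baseline: European odds ratio of 1 (log OR = 0)")
  if (any(!is_or & eur == 0))
    stop("undefined baseline: European effect of 0")
  is_auc <- dt$metric_type == "auc"
  if (auc_above_chance) {
    if (any(is_auc & eur == 0.5))
      stop("undefined baseline: European AUC of 0.5 on the above-chance scale")
    eur[is_auc] <- eur[is_auc] - 0.5
    noneur[is_auc] <- noneur[is_auc] - 0.5
  }
  pct <- ifelse(is_or, 100 * log(noneur) / log(eur), 100 * noneur / eur)
  data.table::data.table(study_id = dt$study_id, phenotype = dt$phenotype,
                         ancestry_group = dt$ancestry_group,
                         metric_type = dt$metric_type,
                         relative_pct = pct)
}

#' Median relative performance of an ancestry group
#'
#' Sample median (even counts average the central pair) of the relative
#' percentages within one ancestry group.
#'
#' @param relative a table from [relative_effect()]
#' @param ancestry_group group label
#' @return median percentage
#' @export
group_median <- function(relative, ancestry_group) {
  x <- relative$relative_pct[relative$ancestry_group == ancestry_group]
  if (!length(x)) stop("no rows for ancestry group '", ancestry_group, "'")
  stats::median(x)
}

#' One-sample t-test of a group's relative performance against parity
#'
#' Two-sided one-sample t-test of the group's relative percentages against
#' `null_pct` (parity = 100 by default), with `df = n - 1`.
#'
#' @param relative a table from [relative_effect()]
#' @param ancestry_group group label
#' @param null_pct null value (default 100)
#' @return list: `t`, `df`, `p`, `n`, `mean`
#' @export
group_ttest <- function(relative, ancestry_group, null_pct = 100) {
  x <- relative$relative_pct[relative$ancestry_group == ancestry_group]
  if (length(x) < 2L) stop("need >= 2 rows for a t-test")
  if (stats::sd(x) == 0) stop("zero dispersion: t-test undefined")
  tt <- stats::t.test(x, mu = null_pct, alternative = "two.sided")
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, n = length(x), mean = mean(x))
}

#' Representation ratio of an ancestry group
#'
#' `100 * study_fraction / world_fraction`: 100 means a group's share of
#' polygenic-scoring studies equals its share of world population.
#'
#' @param study_fraction fraction of studies including the group
#' @param world_fraction the group's fraction of world population (> 0)
#' @return percentage
#' @export
representation_ratio <- function(study_fraction, world_fraction) {
  if (any(world_fraction <= 0)) stop("world_fraction must be > 0")
  100 * study_fraction / world_fraction
}

#' Full portability meta-analysis
#'
#' Normalizes every study comparison ([relative_effect()]), then reports per
#' ancestry group the number of comparisons, the median relative percentage,
#' and the one-sample t-test against parity (groups with fewer than two rows
#' or zero dispersion get `NA` test fields).
#'
#' @param comparisons study-comparison table
#' @param null_pct parity value for the t-test (default 100)
#' @param auc_above_chance passed to [relative_effect()]
#' @return `data.table`: `ancestry_group`, `n`, `median_pct`, `t`, `df`, `p`
#' @export
portability_meta <- function(comparisons, null_pct = 100, auc_above_chance = FALSE) {
  rel <- relative_effect(comparisons, auc_above_chance = auc_above_chance)
  groups <- unique(rel$ancestry_group)
  rows <- lapply(groups, function(g) {
    x <- rel$relative_pct[rel$ancestry_group == g]
    tt <- if (length(x) >= 2L && stats::sd(x) > 0)
      group_ttest(rel, g, null_pct) else list(t = NA_real_, df = NA_real_, p = NA_real_)
    data.table::data.table(ancestry_group = g, n = length(x),
                           median_pct = stats::median(x),
                           t = tt$t, df = tt$df, p = tt$p)
  })
  data.table::rbindlist(rows)[]
}
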