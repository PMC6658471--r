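#' @importFrom data.table := .N .SD data.table as.data.table fread fwrite
#' @importFrom methods is
#' @importFrom stats median
NULL

.datatable.aware <- TRUE

utils::globalVariables(c(
  ".", "pop", "super_pop", "sample", "score", "clump_label", "p_T",
  "r2_threshold", "reference_population", "n", "mean_phenotype", "beta",
  "effect", "p", "p_adj", "undefined", "component", "r", "N", "group",
  "dispersion", "sd", "significant_noneur", "variant_id", "index_id", "y",
  "mean"
))
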