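#' Synthetic 1000Genomes-layout sample panel
#'
#' Builds a SYNTHETIC sample panel with the 26 population codes and five
#' superpopulations of the 1000Genomes phase-3 release, totalling 2577
#' samples. The seven populations conventionally excluded from the
#' phenotype-correlation analysis carry their documented cohort sizes
#' (PUR 105, BEB 86, PJL 96, MSL 85, ASW 66, ACB 96, CEU 103); the remaining
#' nineteen population sizes are synthetic placeholders chosen only to make
#' the total come out to 2577. Sample identifiers are synthetic. Use this for
#' testing exclusion bookkeeping, not as a substitute for the real panel.
#'
#' @return `data.table` with columns `sample`, `pop`, `super_pop`
#' @export
synthetic_1kg_panel <- function() {
  pops <- c(
    # AFR
    YRI = "AFR", ESN = "AFR", GWD = "AFR", LWK = "AFR", MSL = "AFR",
    ACB = "AFR", ASW = "AFR",
    # EUR
    CEU = "EUR", TSI = "EUR", FIN = "EUR", GBR = "EUR", IBS = "EUR",
    # EAS
    CHB = "EAS", JPT = "EAS", CHS = "EAS", CDX = "EAS", KHV = "EAS",
    # SAS
    GIH = "SAS", PJL = "SAS", BEB = "SAS", STU = "SAS", ITU = "SAS",
    # AMR
    MXL = "AMR", PUR = "AMR", CLM = "AMR", PEL = "AMR"
  )
  fixed <- c(PUR = 105L, BEB = 86L, PJL = 96L, MSL = 85L, ASW = 66L,
             ACB = 96L, CEU = 103L)
  other <- setdiff(names(pops), names(fixed))       # 19 populations
  sizes <- stats::setNames(rep(102L, length(other)), other)
  sizes[seq_len(2577L - sum(fixed) - sum(sizes))] <- 103L  # top up to 2577
  sizes <- c(sizes, fixed)[names(pops)]
  data.table::data.table(
    sample = unlist(lapply(names(pops),
                           function(p) sprintf("%s_%04d", p, seq_len(sizes[[p]])))),
    pop = rep(names(pops), sizes),
    super_pop = rep(unname(pops), sizes)
  )
}
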