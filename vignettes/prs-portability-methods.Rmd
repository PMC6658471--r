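---
title: "Methods: cross-ancestry polygenic score portability and construction choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-ancestry polygenic score portability and construction choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical machinery it
implements: the models and their assumptions, the tunable parameters and why
their defaults are what they are, what the synthetic-data generator does and
does not emulate, and the numerical conventions that make results
reproducible. It states no empirical result that the test suite or the
acceptance script does not itself compute.

## 1. The two analyses

**Within-study portability meta-analysis.** Each row of a study-comparison
table carries one matched pair of effect sizes: a polygenic score evaluated
in a non-European-ancestry sample and in a European-ancestry sample from the
same publication, on the same metric (variance explained, regression beta,
odds ratio, or AUC). `relative_effect()` normalizes the non-European effect
to the European baseline, `100 × noneur/eur`, with odds ratios first moved
to the log scale (a ratio of odds ratios is not interpretable; a ratio of
log odds ratios is the standard within-study standardization). Parity is
100%; opposite-direction effects give negative percentages and are
deliberately retained rather than truncated, since truncation would bias
group summaries toward parity. Group summaries are the sample median and a
one-sample two-sided t-test of the percentages against 100 with df = n − 1.
The t-test structure is a design decision: the source analyses report t and
df but never name the test, and a one-sample test of the ratios against
parity is the only structure consistent with df = n − 1 for n comparisons.
Whether such ratios satisfy t-test assumptions (independence across rows
from the same study; approximate normality) is questionable — multiple
comparisons from one publication are treated as independent rows, a
documented limitation.

AUC rows are ratioed as raw AUC values by default. Because raw-AUC ratios
compress differences (an uninformative score still has AUC 0.5), an
`auc_above_chance` flag ratioes `AUC − 0.5` excesses instead; it is off by
default to match the primary convention.

**The construction grid.** Clumping + thresholding scores are computed over
a factorial grid: clumping r² ∈ {0.2, 0.05, 0.01} (500 kb window, p1 = p2 =
1), the LD reference population (a population, a superpopulation, or ALL),
and thirteen p-value thresholds from 5×10⁻⁸ to 1. Downstream readouts are
per-population distribution summaries with a dispersion statistic, a PRS
versus principal-component correlation scan, and a correlation between
population mean scores and population mean phenotypes.

## 2. Clumping, thresholding, scoring: exact conventions

* **Greedy clumping.** Variants are visited by ascending p-value; ties are
  broken by chromosome, then position, then variant id (lexicographic).
  The ordering is a determinism requirement, not a scientific claim. Each
  unassigned variant with p ≤ p1 becomes an index; unassigned variants with
  p ≤ p2 on the same chromosome within the window and with r² ≥ threshold
  to the index join its clump. The window is a closed interval in base
  pairs: |pos − pos_index| ≤ window_kb × 1000.
* **LD measure.** Squared Pearson correlation of unphased dosages over
  pairwise-complete samples (composite LD) — the quantity computable from
  dosage data without phasing. A variant monomorphic over the complete
  pairs has undefined LD and raises an error in `ld_r2()`; inside `clump()`
  such pairs simply cannot absorb each other.
* **Variants absent from the LD reference** are dropped from clumping and
  counted, mirroring the reference-panel behavior of the standard tooling;
  `keep_unmatched = TRUE` keeps them as singleton indices for users who
  prefer not to lose coverage.
* **Thresholding** retains p < p_T strictly, except p_T = 1 which is
  inclusive — taken from the source notation for the threshold ladder
  (strict inequalities up to "p ≤ 1" at the final rung).
* **Harmonization.** Weights are oriented to the target's alt allele:
  effect allele = alt keeps β, effect allele = ref stores −β, anything else
  is a mismatch. Strand-ambiguous pairs (A/T, C/G) are dropped by default
  because their orientation cannot be resolved from alleles alone. Every
  source row receives an action label; drops are counted, never raised.
  Join key is the variant id, falling back to
  chromosome:position:sorted-alleles when ids are missing.
* **Scoring.** Sum mode is Σ w·g with missing dosages imputed by the
  cohort mean dosage of the variant (configurable to zero). Average mode
  divides by 2 × (number of weighted variants). *Note:* the build contract
  contained a worked example implying division by four for a single
  variant; this contradicts its own definition and the per-allele-average
  convention, so the definition is followed (see the decisions ledger).
* **Orientation invariance holds up to a constant.** Flipping a target
  variant's ref/alt labels (with dosage complement 2 − d) flips the
  harmonized weight sign, so each sample's contribution changes from w·d
  to w·d − 2w: a shift common to all samples. Raw sums therefore move by a
  constant; centered scores, and every between-sample contrast, are exactly
  invariant, and that is what the invariance test asserts. Any analysis
  that depends on the raw intercept of a PRS is coding-convention-dependent
  and should not be trusted anyway.

## 3. Ancestry structure

PCA uses frequency-based standardization: dosages centered at 2f and
divided by √(2f(1−f)), the binomial standard deviation at the cohort
alt-allele frequency (mean-imputed missing values, monomorphic variants
excluded). This weighting is standard for ancestry PCA because drift moves
rare variants proportionally more; plain unit-variance scaling is available
by flag. Components come from the SVD; each is oriented so its
largest-magnitude sample coordinate is positive — an arbitrary but stable
convention that makes golden files and order-invariance tests possible.

Long-range LD regions are excluded before PCA with a closed-interval mask
defaulting to chr6 25–35 Mb (MHC) and chr8 7–13 Mb (the inversion
polymorphism); both regions carry enough internal LD to hijack leading
components. LD pruning defaults — window 50 variants, step 5, r² ≤ 0.2 —
are a design choice (the source pipeline names no parameters); they are the
common "indep-pairwise 50 5 0.2" idiom. Pruning passes repeat to a fixed
point so the operation is idempotent by construction; within a window the
lower-MAF member of the worst offending pair is removed (tie: later
position), because the lower-MAF variant carries less information.

The PRS–PC scan reports Pearson r and its two-sided t-distribution p-value
for every grid cell × component. Benjamini–Hochberg adjustment across the
whole scan is provided but off by default: the primary readout is the raw
correlation pattern, and the adjustment is this package's addition.
Constant score columns are flagged undefined and excluded from adjustment.

## 4. What the generator emulates — and what it does not

The synthetic cohort is a stated world chosen once:

* **Ancestral frequencies** i.i.d. Uniform(0.05, 0.95): a post-MAF-filter
  common-variant pool; no site-frequency-spectrum realism is attempted.
* **Drift** via Balding–Nichols: population frequency ~
  Beta(p(1−F)/F, (1−p)(1−F)/F), mean p, variance F·p(1−p); F = 0 returns p
  exactly. Default F ≈ 0.1 is continental-scale differentiation; the
  star-shaped population history (all populations drift independently from
  one ancestor) has no admixture, no migration, no serial bottlenecks.
* **LD** via a Gaussian copula: within each block of (default 10) variants
  a latent normal with exchangeable correlation r, thresholded at the
  (1 − f) quantile per variant; two haplotypes sum to a dosage. Blocks are
  laid out 2 Mb apart (250 per chromosome), so they are always far outside
  a 500 kb clumping window of each other. Real LD decays with distance and
  differs in extent between populations (notably shorter in African
  populations); exchangeable within-block correlation with a shared latent
  r is the simplest structure with a tunable target and is *less*
  population-differentiated in LD than reality — genotype-scale LD still
  drifts with frequency through the thresholds, but a green portability
  test here understates the LD mismatch of real cohorts.
* **Phenotype**: causal variants uniform at random, effects i.i.d. standard
  normal, environmental noise residualized against the genetic value and
  scaled so the in-sample Var(G)/Var(y) equals h² exactly — so recovery
  tests have a sharp target instead of a sampling-noisy one.
* **Discovery GWAS**: per-variant marginal OLS without covariates;
  monomorphic variants get β = 0, p = 1; p-values floored at the smallest
  positive double to stay in (0, 1]. Stratification confounding enters
  *only* through `inject_stratification()` (β' = β + δ(f_A − f_B)), keeping
  the bias controllable and its downstream signature (PRS–PC correlation)
  attributable.
* **Study tables**: per ancestry group, matched effect pairs whose true
  relative performance is a configured ratio plus Gaussian noise, metric
  types round-robin; odds-ratio rows impose the ratio on the log scale so
  the normalization recovers it. Case/control designs are emulated only at
  this meta-analysis level.

Seeds are threaded explicitly through every operation (Mersenne–Twister,
saved-and-restored global state, so package calls never disturb a user's
RNG stream). A green test therefore establishes correctness of the
machinery under this stated world — not calibration against real
1000Genomes/GWAS data, which involve imputation error, ascertainment,
admixture, and population-specific LD that this world omits.

**The portability-decay experiment** masks causal variants from the
summary statistics so the score must work through LD tags. This is the
mechanism the portability literature names (tag–causal coupling and
frequencies drift across populations); with causal variants directly
scored, drift has almost nothing to degrade and no decay should be — or is
— observed. The experiment's cohort sizes were chosen for Monte-Carlo
power and frozen; the assertion (Spearman trend of target R² in F negative
over 3 F levels × 20 replicates) is the build contract's.

## 5. Dispersion and the population-phenotype correlation

Between-population dispersion of a score column is the variance of
population means divided by the pooled within-population variance
(weights n − 1). The visual notion of distributions "drifting apart" has no
canonical numeric form; this ratio is unitless, zero iff population means
coincide, and invariant to affine rescaling of the score, which makes it
comparable across grid cells — the property the dispersion-trend analysis
needs. Populations with one sample have undefined SD and are flagged.

The population-level correlation takes one point per population — equal
weights, not n-weighted — matching the one-point-per-population scatterplot
convention, with p from the t-distribution on n − 2 df. It requires at
least three populations and errors on zero variance. The seven default
population exclusions (PUR, BEB, PJL, MSL for missing phenotype; ASW, ACB
for admixed/mixed country origin; CEU for no single origin country) ship as
packaged rules; the 2577-sample panel used in exclusion tests is a
synthetic layout (`synthetic_1kg_panel()`) whose seven excluded population
sizes are the documented ones and whose remaining sizes are placeholders.
Country phenotype tables average male and female means at construction
time (`build_phenotype_table()`).

## 6. Degenerate inputs and numerical choices

* Duplicate variant ids in genotypes or summary statistics are rejected,
  not resolved — the upstream sources mix rsID and chr:pos conventions, and
  guessing a resolution silently corrupts joins.
* p-values outside (0, 1], missing alleles, and non-positive odds ratios
  are dropped at load with counts; every filter satisfies retained +
  removed = input.
* MAF is computed from the loaded cohort's non-missing dosages, never from
  file INFO fields; the load filter keeps MAF strictly greater than the
  floor, so monomorphic variants never survive.
* Zero-dispersion groups make the meta-analysis t-test error; an empty
  European baseline (effect 0, or OR = 1 whose log is 0) is an undefined
  baseline, not an infinity.
* Score round-trips through CSV preserve doubles to full precision
  (`data.table::fwrite` shortest-round-trip formatting).

## 7. Known limitations

* No real-data adapters are bundled for the multi-gigabyte public
  resources; the readers accept their formats (VCF 4.x, panel files,
  delimited summary statistics with a column map), but reproduction on the
  real cohorts is out of scope.
* The meta-analysis treats rows as independent and has no standard errors
  to weight by (the curated sources do not provide them); no
  inverse-variance pooling is attempted.
* Case/control phenotypes are not simulated at the genotype level.
* The copula LD model cannot express distance-decaying or
  population-specific haplotype structure; conclusions about absolute
  portability magnitudes should not be read off the synthetic world.
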