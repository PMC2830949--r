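---
title: "Methods: the KDM5C expression fingerprint and the WAPDG statistic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the KDM5C expression fingerprint and the WAPDG statistic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wapdgkit)
```

## The scientific problem

Pathogenic mutations in *KDM5C*, an H3K4me2/me3 histone demethylase on the
X chromosome, are a comparatively frequent cause of non-syndromic X-linked
mental retardation. Because affected males have no consistent clinical
features beyond the cognitive phenotype, and because resequencing mostly
turns up missense variants of unclear relevance, a functional read-out is
needed: if KDM5C is a transcriptional repressor, its deficiency should
leave a reproducible trace in the transcriptome of accessible tissue.
`wapdgkit` implements the analysis chain that builds such an expression
fingerprint from lymphoblastoid cell lines and blood — marker discovery on
bead arrays, QRT-PCR validation, per-class effect estimates, and a
permutation statistic (WAPDG) that turns a small marker panel into a
patient/control discriminator and a blind-sample classifier.

All stages run on synthetic cohorts from the package's own generator, so
every number in this vignette and in the test suite is computed, not
transcribed.

## The synthetic cohorts

The generator (`sim_config()`, `simulate_array_experiment()`,
`simulate_qpcr_experiment()`) emulates the study design rather than any
particular dataset:

* **Discovery**: one patient array (a protein-truncating mutation carrier)
  against three control arrays; 10,000 background genes; 21 truly
  deregulated genes spiked at fold 4; 1,000 negative-control probes.
* **Validation**: a qPCR cohort of 8 missense + 4 truncating patients and
  5 controls, with the twelve marker genes spiked at the reported
  per-class LS-mean ratios (`kdm5c_marker_ratios()`, spanning 0.12× to
  8.57×).
* **Blind study**: four additional single samples — one at patient-level
  expression, one intermediate, two at control level.

Noise is multiplicative log-normal on intensities/quantities (a sample's
value is the group mean times a unit-mean log-normal multiplier with
coefficient of variation `cv_within`) and additive Gaussian on Ct values
(SD 0.15 cycles by default). Log-normal noise keeps values strictly
positive and right-skewed, which is what the WAPDG truncation step
presupposes. Two values of `cv_within` are used as study conditions:

* **0.25** for the validation qPCR cohort. The study does not report
  within-group variances; 25% is a realistic between-cell-line CV for
  lymphoblastoid expression and is demanding enough that single markers
  do *not* fully separate the groups (see the per-gene overlaps below).
* **0.10** for the discovery arrays. The pairwise differential-expression
  score is a *technical*-variance z-test (one array per sample, no
  biological replication in a pairwise comparison), so the within-array
  CV represents array-level technical variation, for which ~10% is
  typical of summarised bead intensities. The variance model used by the
  score is calibrated to the same value.

Dropout genes (`dropout_rate`) are placed below the quantification floor —
near the negative-control distribution on arrays, beyond the Ct ceiling on
plates — reproducing assays that fail to yield enough product to
quantify. Determinism is strict: one global seed with fixed per-stage
substreams (`stage_seed()`), so identical configurations are bit-identical
and any stage can be re-run in isolation.

What the generator does *not* emulate: bead-level error structure and
spatial artefacts, probe cross-hybridisation, batch and culture-handling
effects, correlated co-regulation between markers (genes are simulated
independently), and amplification-efficiency drift within a plate. Passing
tests therefore demonstrate the correctness and calibration of the
statistical machinery under the stated model, not robustness to every
failure mode of real arrays or plates.

## Marker discovery on arrays

**Normalisation.** The vendor's rank-invariant normalisation is
re-specified in documented form: per non-reference sample, probes whose
within-set rank differs from the reference by less than 5% of the current
set size are kept and the selection is iterated to a fixed point; the
sample is then scaled by the ratio of 10%-trimmed means over the invariant
set. The invariant set and scale factor are returned for audit. If the
set collapses below 100 probes the sample is refused rather than silently
scaled.

**Detection.** `detection_scores()` is the tie-aware empirical exceedance
of a probe's intensity over the sample's negative controls. A score of
"1" is only attainable by exceeding *all* controls, so the table
criterion "DT = 1" is read as `score >= 1 - 1/n_controls`; the looser
"DT > 0.99" is a plain threshold.

**Differential expression.** For one patient array vs one control array,
`diff_score()` returns `DS = 10 · sign(x_p − x_c) · (−log10 p)` with `p`
from a two-sided z-test under the technical variance model
`v(x) = σ₀² + (c·x)²` (`σ₀` estimated from negative-control spread, `c`
configurable). The published thresholds keep their meaning as p-value
bounds: DS > 50 ⇔ p < 10⁻⁵, DS > 100 ⇔ p < 10⁻¹⁰. Scores are computed on
the log scale of `p`, so they do not underflow.

**Tiered selection.** `select_candidates()` applies three tiers across
the patient-vs-each-control comparisons: *strict* (DS > 100, DT > 0.99,
fold ≥ 2, all comparisons, consistent direction), *standard* (DS > 50,
DT at the empirical maximum, fold ≥ 2, all comparisons), and *relaxed*
(standard criteria in exactly all-but-one comparison — the "two of three
controls" genes). Down-regulation qualifies through the reciprocal fold.
Whether the twofold exclusion is applied before or after normalisation is
not specified in the source description; it is applied to normalised
intensities here, since the comparison is only meaningful on a common
scale. Under null simulations the strict tier is expected to fire
essentially never (a p < 10⁻¹⁰ event in every comparison); the test suite
asserts ≤ 2 strict calls over 20 × 10,000 null genes.

## qPCR quantification

Each assay carries its own factor-2 serial dilution of reference cDNA.
`fit_standard_curve()` regresses Ct on `step · log2(factor)` by OLS; the
slope is cycles per log2 dilution and the efficiency `2^(1/slope)` fold
per cycle. `quantify()` aggregates triplicates by mean Ct — Ct noise is
approximately Gaussian whereas quantity noise is log-normal, so averaging
on the Ct scale is the lower-variance choice — and inverts the curve:
`quantity = 2^(−(mean Ct − intercept)/slope)`, on the dilution scale of
that assay's own standard. Quantities are therefore never compared across
genes, only within genes across samples, matching per-gene ratio
reporting.

Quantifiability is a QC call, not an error: mean Ct beyond a ceiling
(default 35 cycles; the exact cut-off used in the original assays is not
stated, so this is a configurable default) or triplicate SD above 0.5
cycles yields `not_quantifiable`. On noiseless synthetic plates the
quantification inverts the generator to ~10⁻¹² relative error, which the
suite asserts.

## Group contrasts

`fit_oneway()` is the one-factorial fixed-effect model: with a single
class factor the LS mean of a class is its arithmetic mean, the residual
variance is pooled within classes, and `df = n − k`. `contrast()` tests
`H0: LSM(i) = LSM(j)` by Student t with the pooled SE; with exactly two
classes this reduces to the classical pooled t-test, which the suite
verifies to machine precision against `t.test(var.equal = TRUE)`. Tests
run on linear-scale quantities (a log-scale option exists but is off by
default, matching a GLM on quantities), ratios are LS-mean ratios — the
only ratio the model produces directly — and no multiplicity adjustment
is applied, the one-factorial design being the stated reason; an optional
Benjamini–Hochberg column is available as clearly labelled extra output.
Significance codes use the conventional map (\*\*\* < 0.001,
\*\* < 0.01, \* < 0.05), a declared choice since the original footnote
defining the codes is not available in the text.

## WAPDG

The core statistic, Weighted Accumulative Permutation analysis for
Differentiation between Groups:

1. **Weighting** (`weight_expression()`): each gene's values are divided
   by the gene's grand mean over both groups combined, so every gene
   contributes on the same dimensionless scale (weighted values average
   exactly 1 per gene).
2. **Summaries** (`summarize_groups()`): per gene and group, the sample
   mean and SD (n − 1) of the weighted values.
3. **Permutation draws** (`permute_group()`): `N = 1000` draws per gene
   and group from Normal(mean, SD) restricted to values > 0 by
   *rejection* (redraw), not clipping — rejection produces the slight
   positive skew that mirrors strictly positive expression data, whereas
   clipping would pile mass at zero. `SD = 0` degenerates to copies of
   the mean. The original implementation used the Numerical Recipes
   `ran1`/`gasdev` generators; any high-quality seeded RNG is
   distributionally equivalent, so R's default generator is used and no
   result depends on the exact draw stream.
4. **Shared-value proportion** (`shared_proportion()`): the fraction of
   all draws (both groups pooled) inside the intersection of the two
   groups' empirical ranges, boundaries inclusive. This literal reading
   of "proportion of shared values" is brute-force checkable (the suite
   compares it against an exhaustive count) and hits exactly the `1/N`
   floor when the ranges are disjoint — so with `N = 1000` the strongest
   reportable claim is `P < 0.001`, and `p_bound = max(proportion, 1/N)`
   never goes below it. Alternative operationalisations (histogram
   overlap coefficients) would need binning choices the source does not
   provide; the range-intersection reading needs none.
5. **Combination** (`combine_genes()`): combined draw *i* of a group is
   the mean over the panel of that group's *i*-th per-gene draws. Genes
   are permuted independently, so the combined spread shrinks roughly as
   `1/√G` while the group means stay put — this is how a panel separates
   cleanly even when every single gene overlaps. Summing instead of
   averaging would only rescale both groups identically and is left as an
   extension point. Mixing up- and down-regulated genes would cancel;
   the down-regulated marker (TNFSF4) is excluded from the default
   11-gene panel, and an optional direction map lets it enter through
   reciprocal values for exploratory use.

`wapdg_analyze()` chains the steps deterministically under one seed and
returns per-gene and combined proportions plus the combined draw sets.

**Classification** (`classify_sample()`): an unknown sample is weighted
with the *training* grand means, averaged over the panel, and located
against the central `1 − 2α` empirical intervals of both groups' combined
draws (`α = 0.005` per side by default, chosen so verdict resolution
matches the `1/N` scale of the group statistic). Inside exactly one
interval → that group; inside both or neither → `unassigned`, the
expected verdict for genuinely intermediate signatures such as mild
missense effects. Quantile positions within each group's draws are
reported in place of error bars, whose original construction for single
samples is not described.

## Problem sizes and numerical choices

The test suite and the acceptance script use the study-scale designs
throughout: 17-sample validation cohorts with 1,000 draws per gene,
10,021-gene discovery arrays, 200-replicate Monte-Carlo runs for effect
recovery, 20 × 10,000 null genes for selection specificity, and 1,000
null genes for contrast calibration. These sizes give Monte-Carlo
standard errors comfortably inside the asserted tolerances (e.g. the
type-I rate check at 1,000 genes has binomial SE ≈ 0.7%, against a ±2%
band) while the whole suite runs in well under a minute.

Other numerical decisions: degenerate one-way models (zero residual
variance) and classes of fewer than two samples are errors, not silent
NAs; rejection sampling guards against vanishing positive support
(acceptance < 10⁻⁸ is an error rather than an endless loop); selection
ties are broken by gene id after sorting on the minimum |DS|; and all
RNG use is confined to `with_seed()` scopes so package calls never
disturb the caller's RNG state.

## Known limitations

* The marker effect sizes used as generator truth are point estimates
  from a small cohort; the generator treats them as exact.
* Genes are simulated independently; a real fingerprint's markers are
  likely co-regulated, which would slow the `1/√G` sharpening of the
  combined statistic. Combined-P claims on real data should therefore be
  read as conditional on approximate independence.
* The shared-value proportion is range-based and hence sensitive to the
  extreme draws; with `N = 1000` this is exactly the intended resolution,
  but much larger `N` would make the overlap criterion stricter for
  fixed group separation.
* The classifier is two-class with an abstention region; it does not
  model class priors or costs.

## Reproducing the analysis

The numbered scripts under `analysis/` run the whole chain on the
synthetic cohorts (simulate → select → quantify → contrast → WAPDG →
classify) and write their tables under `results/`;
`scripts/acceptance.R --seed <int> --out <path>` recomputes the headline
quantities from scratch. `run_pipeline()` drives the same stages from a
single configuration object for programmatic use.
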