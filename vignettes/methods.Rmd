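---
title: "Methods: dye-swap array analysis of developmental, sex-biased liver expression"
author: "tfsarray"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dye-swap array analysis of developmental, sex-biased liver expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfsarray)
```

# The experimental design and what the package computes

The package analyses a classic two-color microarray design for studying how
liver gene expression diverges between the sexes over postnatal development.
Male and female mouse liver RNA is collected at 3, 4 and 8 weeks of age and
compared in seven competitive hybridizations: male vs female at each age
(comparisons 1–3), and 8 wk vs 3 or 4 wk within each sex (comparisons 4–7).
Each comparison is run as a dye-swapped pair of arrays, so dye-specific bias
cancels when the pair is averaged.

From probe-level channel intensities the pipeline computes, per probe and
comparison, an error-weighted log2 ratio with a combined error and p-value;
flags each comparison up/down/unchanged; encodes the seven flags as a
*total flagging sum* (TFS) code; classifies genes by sex specificity, onset
age, and developmental change; clusters the 7-point ratio vectors against
predefined model profiles with a permutation test; and scores overlaps
between developmental gene sets and external regulator-response gene sets by
fold enrichment and an exact two-tail Fisher test.

## Ratio orientation

Each comparison carries an explicit numerator and denominator. The three sex
comparisons report male/female; the four developmental comparisons report
8 wk over the younger age. With this orientation flag 1 ("up") always means
male-biased or up-regulated with age, which is what makes the TFS digit
semantics coherent: in the worked pattern `(0,0,2,2,2,0,0)` → `28.0022200`,
digit 3 = 2 means female-biased at 8 wk and digits 4–5 = 2 mean
down-regulated from 3 and 4 wk to 8 wk in male liver.

# The error model

Channel noise is modelled in the additive + multiplicative (Rocke–Durbin)
form: an observed intensity is
`true * exp(N(0, sigma_mult^2)) + N(0, sigma_add^2)`, truncated at zero.
Propagated to a log2 ratio this gives the per-feature technology error

```
sigma_tech^2 = [ (sigma_add^2/red^2 + sigma_mult^2)
               + (sigma_add^2/green^2 + sigma_mult^2) ] / ln(2)^2
```

which decreases with intensity and approaches `sqrt(2)*sigma_mult/ln 2`
(≈ 0.204 log2 units at `sigma_mult = 0.1`) for bright features. The original
analysis system's error model is proprietary; this package fixes a concrete
published surrogate with the same structure: a technology error plus a
replicate-derived error, combined per replicate as

```
s_i^2 = max(sigma_tech_i^2, sigma_rep^2)
```

where `sigma_rep^2` is the between-replicate variance of the oriented log2
ratios *pooled across probes* (a single scalar per comparison). The `max`
prevents the under-estimation of error that plagues variance estimates from
two replicates; pooling across probes keeps the estimate stable, and — unlike
a per-probe two-replicate variance — preserves the uniformity of null
p-values, which the test suite checks by Kolmogorov–Smirnov on a self-self
simulation. Replicates are combined by inverse-variance weighting
(`weighted ratio = sum(r_i/s_i^2)/sum(1/s_i^2)`,
`combined sigma = (sum 1/s_i^2)^(-1/2)`), and the p-value is the two-sided
normal tail of the weighted ratio over its combined sigma — a z-type
statistic, with no small-sample t correction, as implied by an
error-weighted-averaging model. A numerical floor (`sigma_floor`, default
1e-6 log2 units) keeps the noise-free limit well defined.

# Normalization

Linear normalization rescales the green channel so both channels share their
median over well-above-background probes; LOWESS normalization then removes
intensity-dependent dye bias by subtracting a locally weighted fit of M on A
(tricube weights, 2 robustness iterations, span 0.3 by default — common
two-color practice, exposed in the configuration). "Well above background"
requires both raw channels to strictly exceed the 99th percentile
(nearest-rank) of the array's background population; a probe failing this on
any contributing array carries `wab = FALSE` in the comparison summary and
can never be flagged.

Intensity-dependent normalization assumes that at every intensity stratum
most probes are unregulated. Genes strongly down-regulated with age are
genuinely brighter at the young time point, so the bright end of the A axis
is always somewhat enriched for regulated genes; with realistic regulated
fractions (below ~10% per comparison) the local fit is essentially
unaffected, but a simulation that regulates a third of the genome at 2–4
fold would make the fit follow real signal at the intensity extremes. The
synthetic-data defaults are therefore set to study-scale regulated fractions
(see below).

# Thresholds and classification

Differential expression per comparison requires all of: linear |ratio| > 1.5
(strict), p < 1e-4 (strict), and well-above-background. The seven ternary
flags form the TFS code: the digits after the decimal point are the flags in
comparison order, and the whole number sums binary weights 1, 2, 4, 8, 16,
32, 64 over the flagged positions. Probes of one gene with identical TFS
patterns are redundant; the probe minimizing the sum of log10 p over its
flagged comparisons is retained (ties to the smallest probe id). Probes of
one gene with different TFS patterns are all retained.

Classification reads the flags: sex class from the 8 wk comparison only;
onset as the earliest sex comparison agreeing in direction with the 8 wk
flag (early bias in the opposite direction is recorded as *transient bias*,
not onset — both counting conventions for 3 wk onset are emitted, since
published count tables can differ on whether early bias must persist);
developmental change per sex from the two developmental comparisons, with
opposite directions in the two intervals reported as "mixed" rather than
silently coerced. "Signal intensity" means the mean of the two normalized
channel intensities, averaged over the arrays of the relevant comparison.
The stringent sex-independent call (8 wk sex ratio < 1.2, p > 0.01,
intensity ≥ 25) marks the conservative background population used for
enrichment of sex-independent sets. Candidate transcriptional regulators are
genes whose annotation descriptor contains "DNA binding" or "transcription"
(case-insensitive), with intensity ≥ 25 at 8 wk, |fold| > 2 on every
comparison with p < 1e-4, and > 2-fold sex bias if sex-specific.
Y-chromosome exclusion is available as a configuration flag when a
chromosome column is supplied, and is off by default.

# Profile clustering

The seven comparisons are treated as an ordered pseudo-series. Candidate
model profiles are all integer trajectories starting at 0 with steps of at
most `c` units (`c = 2` by default; `(2c+1)^6 − 1 = 15,624` candidates at
`T = 7`). A greedy max-min rule selects `m` mutually distinctive profiles
(`m` = 30 or 50 in the emulated study; demo runs use 10): the first pick
maximizes summed distance to all candidates, each later pick maximizes its
minimum distance to the already-selected set. Distance is 1 − Pearson
correlation throughout — for selection and for assigning each gene to its
closest profile. Constant vectors have undefined correlation: their distance
is defined as 1, and constant gene vectors are quarantined in a flat bucket,
excluded from significance testing. Ties break deterministically by
enumeration order (profiles) or lowest profile id (assignment).

Significance is by permutation: each gene's seven values are shuffled
independently (preserving the per-gene value multiset — the exchangeable
null), all genes are reassigned, and the expected count per profile is the
mean over `B` permutations (`B ≥ 100`; default 200). The observed count is
tested against the upper binomial tail with Bonferroni correction over the
number of profiles. The sex-specific and sex-independent gene universes are
always clustered separately and never mix.

A hierarchical-clustering utility (average linkage, 1 − Pearson distance)
orders genes and arrays for heat-map-style export, including optional Newick
output of the merge tree; no image rendering is done.

# Enrichment statistics

For sets of sizes `n` and `K` overlapping in `k` genes on a background of
`N`, fold enrichment is `k*N/(n*K)` and significance is the exact two-tail
Fisher test on `[[k, n−k], [K−k, N−n−K+k]]`, summing hypergeometric point
probabilities not exceeding the observed one. Point probabilities are
evaluated in log space, so p-values far below 1e-100 are exact rather than
underflowed; the implementation is cross-checked in the test suite against
brute-force summation for backgrounds up to 200 and against
`stats::fisher.test`. At the extreme deviations typical of these tables the
opposite tail is negligible, so the printed values are insensitive to the
two-sided convention. Backgrounds follow the harmonization rules: genes
common to both platforms for most comparisons, and the stringent
sex-independent subset when scoring sex-independent developmental sets.
External responder sets are plain gene-list inputs; symbols match
case-insensitively with no alias resolution.

# The synthetic-data generator

The generator exists so that every stage can be validated against known
truth. It emulates: a scaled-down probe complement with redundant probes per
gene; the 7-comparison dye-swap design (replicates in dye-swapped pairs);
log-normal expression spanning the dynamic range of a fluorescence array
(`base_meanlog = log(1000)`, `base_sdlog = 1.2`); additive + multiplicative
channel noise (`sigma_add = 3` linear units, `sigma_mult = 0.1`); a smooth
intensity-dependent dye bias (amplitude 0.3 log2 units) applied with
opposite half-signs to the two channels; a background population
(mean 20, SD 3) with a `frac_low_expressed = 0.05` fraction of probes at
background level; and genes with true sex effects (onset 3, 4 or 8 wk,
folds drawn log-uniformly from 2–4) and developmental trajectories.

Parameters a reader should know the reasoning for:

* **Class proportions** (5% male-specific, 5% female-specific, 90%
  sex-independent) concentrate signal enough for recovery statistics at
  desk scale while keeping sex-specific genes a clear minority, as on the
  real platform. Onset proportions (2/13/85% at 3/4/8 wk) mirror the
  strongly 8 wk-skewed onset distribution of the emulated study.
* **Developmental change probabilities** (12% of sex-independent genes per
  sex; 10% for the opposite-sex trajectory of sex-specific genes) keep the
  regulated fraction per comparison near 10%, the upper end of what the
  emulated arrays show. This is a modelling constraint, not a tuning knob:
  LOWESS normalization presumes a near-null majority at every intensity.
* **Trajectory coupling.** With six expression cells, a sex-specific gene's
  same-sex developmental fold is not free: it follows from the opposite-sex
  trajectory and the onset (e.g. a male-specific onset-8wk gene over an
  unchanged female trajectory is necessarily up-regulated in male liver —
  the same coupling the real data show). The generator samples the free
  parameters and records *realized* developmental calls derived from the
  exact expression matrix with the same 1.5-fold rule the classifier uses,
  so noiseless recovery is exact by construction.
* **Near-background probes** are drawn only from fully null genes: a
  transcript absent from liver cannot carry a liver expression difference,
  and this keeps the background filter from censoring planted effects.
* **Pooling of animals** into replicate RNA pools is modelled implicitly:
  biological variability enters only through the per-replicate noise, i.e.
  as the variance-reduced residual a pool of 5–6 animals would leave;
  individual animals are not simulated.
* **Sub-seeded RNG.** One master seed drives everything; each array draws
  from its own pre-split stream, so enlarging the design does not perturb
  existing arrays.

What the generator deliberately does **not** emulate: probe sequences and
cross-hybridization (a known artifact for close paralogs), spatial array
effects, print-tip structure, and inter-animal variance structure beyond the
pooled residual. Passing tests therefore validate the statistical pipeline,
not robustness to those artifacts.

## The noiseless configuration

`demoConfig(noiseless = TRUE)` demonstrates the zero-error limit: all noise
components and the dye bias are zero, the background is negligible, and the
LOWESS stage is disabled — with no dye bias there is nothing to remove, and
on noise-free structured data a local fit would absorb real signal. The
configuration also keeps every realized fold away from the 1.5 detection
boundary (a gene sitting exactly at an assay threshold has no well-defined
truth call for a thresholded assay). Under this configuration the
classification table must equal the truth table exactly, and the test suite
asserts that it does.

# Numerical choices

* Strict inequalities at every filter boundary (fold, p, background
  percentile); the background percentile is nearest-rank, not interpolated.
* Quartiles in box statistics use linear interpolation (type 7).
* `sigma_floor = 1e-6` log2 units bounds per-replicate errors away from
  zero so the noiseless limit produces p = 0 for true effects and p = 1 for
  exact nulls.
* Fisher tail summation uses the same relative tolerance (1e-7) as
  `stats::fisher.test` when comparing point probabilities.
* All tie-breaks are deterministic and documented at the function level
  (probe id, enumeration order, lowest profile id), so repeated runs are
  byte-identical.

# Problem sizes

Validation runs are scaled to desk size as the package's own choice: demo
pipelines use 2,000 probes, recovery checks 5,000 probes with 2 dye-swap
replicates per comparison, null calibrations 10,000 probes, and permutation
tests 100–200 permutations over 10 model profiles. The pipeline itself is
linear in probes × arrays and runs comfortably at full platform scale.

# Known limitations

* The error model is a published surrogate for a proprietary one; absolute
  p-values on real data from other feature-extraction software will differ
  in calibration.
* With two replicates the pooled between-replicate variance is a coarse,
  comparison-wide summary; genes with idiosyncratic replicate scatter are
  protected only through the technology component and the `max` rule.
* Gene-symbol matching in enrichment is exact (case-insensitive); no alias
  or ortholog resolution.
* The permutation null treats the seven comparisons as exchangeable within
  a gene; correlated comparisons (shared 8 wk samples) make this null
  conservative for profiles aligned with that correlation structure.
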