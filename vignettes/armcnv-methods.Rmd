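---
title: "Arm-level cfDNA copy-number analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Arm-level cfDNA copy-number analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the detection model and its assumptions, what the synthetic-data
generator does and does not emulate, the numerical choices, and the
places where the design was genuinely open.

## The detection model

Plasma cfDNA from a cancer patient is a mixture: a fraction `tf` (the
tumour fraction) of fragments derive from tumour cells, the rest from
normal cells. If the tumour carries `c` copies of a chromosome arm
instead of the normal 2, the expected sequencing coverage of that arm,
relative to a copy-neutral genome, is

```
r = 1 + tf * (c - 2) / 2
```

so a whole-arm gain (`c = 3`) at `tf = 0.1` shifts coverage by +5%, and a
loss (`c = 1`) by -5%. Detecting shifts of that size at ~1x coverage is
feasible only at large genomic scale, which is why the unit of analysis
is the chromosome arm.

The pipeline counts reads in fixed 100 kb windows, corrects GC bias,
sums windows per arm, and converts each sample's arm sums to *fractions*
of its total — so samples of different sequencing yield are directly
comparable. (The raw arm read count would confound copy number with
library size; working on fractions is an interpretive choice the package
makes explicit.) A panel of normal controls supplies per-arm means and
standard deviations, and each sample gets a per-arm z-score. `|z| > 2.96`
— strictly; the boundary is neutral — calls a gain or loss, and a sample
with at least one called arm is aneuploidy-positive.

Assumptions worth keeping in mind:

- events are whole-arm; focal amplifications/deletions dilute into the
  arm mean and are largely invisible (no segmentation is attempted);
- the control panel captures all non-tumour variability (sex chromosomes
  are excluded so donor sex does not enter);
- arm fractions are approximately normal across controls, which holds by
  aggregation (hundreds of bins per arm) at these depths.

## The arm grid

Arm boundaries for hg19 are embedded, derived from the cytoband table:
the p arm is `[0, centromere_start)`, the q arm `[centromere_end,
chrom_end)`, 0-based half-open. The acrocentric short arms (13p, 14p,
15p, 21p, 22p) are carried in the table but excluded from analysis, as is
standard — they are repetitive/rDNA and yield no usable unique coverage —
leaving 22 q arms + 17 p arms = 39 features. A user-supplied BED
overrides the embedded table (this is also the route for other
assemblies). Each arm is tiled left-to-right with full-width windows and
the sub-window remainder at the arm end is dropped rather than kept
short, so all bins are strictly comparable without length normalisation.

Reads are assigned to the bin containing the leftmost aligned base, each
read counted at most once; unmapped, secondary, supplementary and
duplicate-flagged reads are skipped, and a MAPQ threshold (default 30)
stands in for a unique-alignment filter. These are the standard low-pass
counting conventions.

## GC correction

Coverage depends smoothly and library-specifically on window GC content.
The package fits, per sample, a robust locally weighted regression
(`stats::lowess`, span 0.3 by default) of raw bin count on bin GC
fraction over usable bins, and rescales each bin by
`median(fitted) / fitted(gc_bin)`. A flat curve therefore leaves counts
untouched; corrected counts are kept as reals. Per-sample fitting (rather
than one pooled curve) is used because GC bias varies between libraries;
the span is exposed as a parameter. Bins where the fitted curve is
non-positive are masked with a warning; bins with >50% ambiguous
reference bases are unusable from the start. No mappability or
replication-timing covariates are modelled.

## The reference panel and its finite-size null

Per-arm mean and SD (denominator n-1) come from the control arm
fractions. For a control's own z-score the panel is refit without that
sample (leave-one-out, the default): self-inclusion deflates |z| and
would make the panel look cleaner than it is. Both modes are available.

A point that matters when interpreting control-cohort positivity: with a
panel of n controls, the leave-one-out z is not standard normal but a
scaled t — `z ~ sqrt(n/(n-1)) * t_{n-2}`. At n = 40 the per-arm tail
probability of |z| > 2.96 is ~0.006, roughly double the asymptotic
normal tail 2*(1-pnorm(2.96)) ~ 0.0031, and across 39 uncorrected arms
~20% of controls are expected to show at least one spurious call. The
test suite checks the empirical null against the exact t oracle at
n = 40 and against the normal tail for a large (n = 800) panel. The
per-arm threshold is deliberately *not* multiplicity-corrected — that
matches the method being reproduced — and the resulting per-sample false
positive rate is a property of that choice, not a bug.

## The synthetic cohort generator

No patient data accompany this package, so every downstream stage is
exercised on simulated cohorts with full ground truth. The generator
draws, per sample:

- **group and stage** — 41 cases / 40 controls by default, case stages
  I-IV as exact quotas 20/6/11/4 (so published cohort counts reproduce
  exactly; multinomial draws are available);
- **cfDNA concentration** — log-normal per group and stage, calibrated
  so cases average 0.12 ng/uL (stage IV highest, 0.14) and controls
  0.09, with spreads matching the reported ranges (~0.08-0.27 and
  0.06-0.17). The log-SDs (0.25 cases, 0.22 controls) are the package's
  calibration, chosen once from those ranges;
- **tumour fraction** — truncated normal per stage with means
  0.10/0.15/0.20/0.30 for I-IV and SD 0.05. These are declared
  assumptions: studies of this design report no tumour fractions;
- **arm profile** — controls are always copy-neutral; a case is entirely
  copy-neutral ("flat") with probability 20/41, matching the observed
  fraction of z-negative patients; otherwise each arm independently
  gains (c=3) or loses (c=1) with per-arm probabilities encoding the
  published per-arm prevalence among positive patients (e.g. 3q gain
  7/21, 22q loss 8/21; unreported arms get a 1/21 background);
- **bin counts** — expected count `reads * w_b * r(arm) * g(gc)` with
  `w_b` the bin's share of a flat genome, `r` the dilution formula above
  and `g` a quadratic GC-bias curve (default coefficients produce a
  realistic ±20% swing over the observed GC range, floored at 0.05 and
  normalised to mean 1), drawn negative-binomially with overdispersion
  `phi = 0.01` (variance `mu + phi mu^2`), i.e. ~10% extra-Poisson noise
  per bin — low-pass WGS counts are overdispersed. Default depth is 10^6
  counted reads per sample, which over ~27,000 bins puts per-arm
  fraction noise near 0.7% and makes a tf = 0.1 whole-arm event a ~7
  sigma excursion.

Everything is seeded; identical config + seed gives bit-identical
cohorts.

What the generator does *not* emulate: focal events, subclonal mixtures,
mappability artefacts, fragment-length effects, batch effects between
cases and controls, and the age imbalance of the real cohort. Passing
tests on synthetic cohorts therefore demonstrate correctness of the
*method* under its stated noise model, not clinical performance on real
plasma.

### The two presets

`paper_sim_config(separable = FALSE)` is the realistic cohort described
above. Its z-score operating characteristics land where the published
ones do qualitatively: roughly half of cases negative (the flat
fraction), specificity limited by the 39-arm uncorrected threshold.

`paper_sim_config(separable = TRUE)` is the idealised benchmark for the
classifier: no flat cases, tumour fraction floored at 0.1, and every
case carrying the complete five-arm signature — gains on 3q and 8q,
losses on 3p, 10q and 22q, the five arms reported (with concentration)
as the top classifier features. The full-signature choice is deliberate
and worth explaining. If instead each signature arm is drawn
independently at its published frequency, a case can carry events only
on arms that the gain-based top-6 feature selection happens to drop —
redundant features legitimately receive zero gain in a boosted ensemble
— and that case is invisible to the refit six-feature model; empirically
this caps held-out sensitivity below 95% at any frequency scaling. The
benchmark question is "does the pipeline recover perfect discrimination
when the cohort is perfectly discriminable?", and the full-signature
cohort is the construction that makes the premise true. Heterogeneous
event patterns are the default preset's job, not the benchmark's.

## The classifier

Features are the cfDNA concentration followed by the 39 arm z-scores in
fixed arm order. The model is binary-logistic gradient boosting with
`max_depth = 3` and L2 leaf regularisation `lambda = 1` — the two
constraints fixed by the reproduced design — with `nrounds = 100` and
`eta = 0.1` as conventional defaults (all four exposed). Training is
single-threaded, so results are bit-reproducible given the seed.

Two numerical choices matter at this sample size:

- `tree_method = "exact"`: the histogram-sketch split finder can place a
  threshold flush against an observed training value, so a test sample
  fractionally beyond the training range falls on the wrong side of the
  split. With 56 training samples the exact greedy enumerator is cheap
  and places thresholds mid-gap between observed values.
- feature selection runs on the training split only (refitting the model
  on the top six features by total gain, ties broken by fixed column
  order), to avoid leaking test information through the selection; a
  whole-cohort selection mode can be had by passing the full matrix.

Evaluation: random stratified 28-per-class training draw (the remaining
25 samples are the test group), ROC by threshold sweep with simultaneous
steps on ties and trapezoid AUC (equal to the normalised Mann-Whitney
pair count — the suite verifies this against exhaustive pair counting),
sensitivity/specificity at probability 0.5, and stratified five-fold
cross-validation (stratification is the safer reading of "five-fold" at
n = 81; fold class proportions are within one sample of exact).

Attributions are exact TreeSHAP values on the margin (log-odds) scale via
xgboost's `predcontrib`; additivity (base + rowSum = margin) is asserted
to 1e-6, and on models with up to three features the values are checked
against a brute-force Shapley enumeration over the feature power set
using the tree-path conditional expectation as the value function.

## Problem sizes used in the tests

The suite runs on a miniature grid that keeps the real 39-arm vocabulary
with 25 bins of 100 kb per arm — large enough for the normal-aggregation
assumptions to hold — and on the full hg19 grid (~27,000 bins) for the
end-to-end classifier benchmark. Monte-Carlo checks use 10^5+ arm-tests
for the null calibration, 150 cases per tumour-fraction point for power
curves, and 4,100 simulated patients for the concentration calibration;
all tolerances are 3 standard errors of the checked quantity.

## Known limitations

- No segmentation, focal CNV calling, or tumour-fraction estimation;
  arm-level z-scores are the entire signal.
- The embedded arm table is hg19-only (user BEDs cover other builds).
- The classifier benchmark demonstrates pipeline correctness on a
  separable cohort; it does not estimate real-world diagnostic accuracy,
  which the realistic preset suggests would be far below perfect at
  these tumour fractions.
- Leave-one-out z-scores at small panel sizes have a heavier-than-normal
  null; users comparing against a fixed 2.96 threshold should interpret
  control positivity accordingly (or enlarge the panel).
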