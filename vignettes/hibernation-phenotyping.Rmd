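---
title: "Hibernation phenotyping from body-temperature logger data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hibernation phenotyping: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hiberphen)
```

## The problem

Food-storing hibernators such as the common hamster (*Cricetus cricetus*)
overwinter on a continuum between staying euthermic on cached food and
expressing multiday deep torpor. Subcutaneous temperature loggers sampling
body temperature (Tb) every 90 minutes produce season-long traces in which
three bout morphologies are distinguishable:

* **deep torpor bouts** — Tb minimum below 20 °C sustained for more than
  24 h (typically ~10 °C for ~2.7 d);
* **short torpor bouts** — Tb minimum below 20 °C but total duration of at
  most 24 h (~18.5 °C, ~13 h);
* **short and shallow torpor bouts** — Tb depressed below the 30 °C
  euthermia threshold but never below 20 °C (~27 °C, a few hours).

`hiberphen` turns such traces into per-individual hibernation phenotypes,
couples them with food-store energy and white-adipose-tissue PUFA
accounting, and fits the mixed-model suite used to compare experimental
groups. A simulator generates traces and cohorts of known ground truth, so
every stage is validated by recovery tests rather than by eye.

## Segmentation model

A torpor bout is a maximal run of consecutive samples with Tb strictly
below the euthermia threshold (default 30 °C). The bout starts at the
first sub-threshold sample and ends at the first subsequent sample at or
above the threshold — the *recovery sample*. Duration is wall-clock time
between those two timestamps. Minimum Tb is taken over in-bout samples;
mean Tb includes the recovery sample by default, because at 90-minute
resolution the rewarming ramp is part of the bout's thermal signature.
Whether to include it is genuinely undecidable from bout phenomenology
alone, so the alternative convention is available via
`include_recovery_in_mean = FALSE`; durations are unaffected.

Thresholds are read strictly, which fixes the measure-zero ties: a bout
minimum of exactly 20.0 °C is short-shallow ("below 20 °C" is strict), and
a duration of exactly 24.0 h is short (deep requires *longer than* 24 h).
Classification is a total function of `(min_tb, duration)`; a property
test sweeps the plane to confirm the three classes are exhaustive and
mutually exclusive.

Records that end while the animal is still torpid yield a *truncated*
bout whose end is set one sampling interval after the last sample. It is
classified on the observed data and flagged, so reports can list it
separately instead of silently absorbing or dropping it.

### Sampling gaps

Loggers occasionally skip samples. Gaps (consecutive timestamps differing
from the nominal interval by more than one second) are annotated at read
time and never repaired. Segmentation applies one of three policies:

* `bridge` (default): the series is treated as continuous; a gap inside a
  bout contributes its wall-clock time to the duration (duration is clock
  time) but no samples to the minimum or mean;
* `split`: a gap terminates any open bout as truncated and detection
  restarts after it — the conservative choice when gaps are long;
* `error`: refuse to segment gapped windows.

## Phenotypes

Short and short-shallow bouts are pooled into a single *shallow* category
for statistics; short bouts are too rare to support their own category.
Per category (deep, shallow, both) the phenotype holds the bout count,
total and mean duration (internally hours, reported as days), the mean
over bouts of the per-bout minimum Tb, and the mean bout Tb. An individual
is a *hibernator* if it expressed at least one deep bout. Phenology is
defined by deep bouts only: the pre-hibernation period runs from
experiment onset to the first deep bout onset, hibernation duration to the
end of the last deep bout, and the post-hibernation period to the
experiment end. Shallow bouts before the first deep bout do not start
"hibernation". Non-hibernators get missing phenology, not zeros, and
categories without bouts get `n = 0`, zero totals, and missing means.
Group summaries report mean ± SE with `n` equal to the individuals
actually contributing a value, so bout-temperature summaries average over
the animals that expressed the bout type while counts cover everyone.
Per-individual values are averaged unrounded; rounding to one decimal is
left to report formatting.

## Food budgets

Diet composition constants (metabolizable energy MJ/100 g, fat, PUFA, LA,
ALA g/100 g) live in a versioned JSON config shipped with the package
(pellets at 1.32 MJ/100 g with 1.97 g PUFA/100 g = 1.64 LA + 0.33 ALA;
sunflower seeds at 2.45 MJ/100 g with 23.14 g PUFA/100 g, almost entirely
LA), so other diets can be modelled by pointing at a different file.
Intake is provided minus remaining mass per item; energy and PUFA scale
exactly linearly in mass, and totals are additive over items. Component
sums are validated with a 0.1 g/100 g slack for unlisted minor PUFAs. By
these constants a 2000 g pellet provision carries 26.40 MJ and a
1500 g + 500 g pellet/seed provision 32.05 MJ.

## Statistical models

The suite mirrors standard practice for repeated-measures ecophysiology:

* **Bout-level responses** (duration, minimum Tb, mean Tb) are compared
  between groups with linear mixed models (`nlme::lme`, REML) with a
  random intercept per individual to correct for repeated measurements.
* **Individual-level responses** (counts, totals, phenology, PUFA change)
  use ordinary linear models, with pre-hibernation body mass as the
  default covariate; intake models regress hibernation parameters on
  pellet (and, in the high-fat group, seed) intake.
* **PUFA proportions** are modelled with sampling time (pre/post), group,
  and their interaction as fixed effects plus a random intercept; the
  interaction is dissected into four cell-mean contrasts (group gap at
  pre, within-group change in each group, group gap at post) tested as
  Wald χ² with 1 df.
* **Model reduction** for the hibernators-only PUFA-change model uses
  backward AICc (`AICc = AIC + 2k(k+1)/(n−k−1)`); the duration terms,
  deep minimum Tb, and group are design variables exempt from removal, so
  in practice the reduction decides the fate of the shallow minimum-Tb
  term. AICc is undefined when `n − k − 1 ≤ 0`; the reduction scores such
  over-rich candidates as infinitely poor rather than fitting them.

Design choices worth stating explicitly:

* **Type III tests under sum-to-zero coding.** Type III marginal tests
  are ill-defined under treatment coding, so all fits locally force
  `contr.sum`; results are invariant to factor level order (tested).
* **F rather than Wald χ² for mixed-model terms.** For between-individual
  factors the marginal F-test with group-level denominator degrees of
  freedom is well calibrated at 11 + 11 individuals, whereas Wald χ²
  tests are anti-conservative at this size. The null-calibration suite
  (below) checks the realized type-I error.
* **Post-hoc contrasts are reported raw** (`adjust = "none"`), matching
  the convention of reporting unadjusted interaction contrasts; any
  `p.adjust` method can be switched on.
* **Differing n is intentional.** Individuals lacking a bout category are
  excluded from that category's bout-level model but kept (with zero) in
  count/total models; individuals missing a PUFA measurement are excluded
  from the paired PUFA model.
* **Singular mixed fits are flagged, not dropped.** A between-individual
  variance collapsing to ~0 is reported on the result object.
* Student's t is the equal-variance version, deliberately not Welch.
* Significance is read at α = 0.05 throughout.

## The simulator

`simulation_config()` encodes the emulated study design: two groups of 11
females over a 137-day winter sampled every 90 minutes; euthermic
baseline 36.5 °C with AR(1) fluctuation (sd 0.3 °C) and 0.2 °C
measurement noise; bout plateaus/durations drawn per type around
10.1 °C / 2.7 d (deep), 18.5 °C / 12.9 h (short), 27.3 °C / 4.7 h
(short-shallow); about half the individuals hibernate; seed intake in the
high-fat group uniform on 154–455 g of 500 g provided. Where the emulated
quantities are published as mean ± SE, the sd defaults are back-converted
with the corresponding n (body mass sd 33 g from SE 10, n = 11; deep
plateau sd 0.7 °C from SE 0.2, n = 13, and so on). Deep bouts are packed
late in the season — expressed hibernation is compressed against the end
of winter after a long pre-hibernation period — separated by euthermic
gaps of 0.5–1 d and followed by a post-hibernation period of ~13 d.

Two effect sizes couple the cohort: expected deep-torpor days decrease
linearly in seed intake (−0.02 d/g by default), and the winter PUFA
change is `base + β_deep · deep_days + β_seed · seeds_g + noise` with
defaults −5 points, −0.5 points/d, +0.02 points/g, residual sd 1.5. The
defaults were fixed once from the emulated study's reported ranges and
are not tuned thereafter.

Traces are rendered as a piecewise process: AR(1) baseline; within each
bout an exponential relaxation from just below the euthermia threshold
toward the plateau (cooling time constant 4 h) and back (rewarming 2 h,
faster, as in heterotherm physiology), both shortened to duration/8 for
bouts too brief to complete the relaxation. In-bout values are capped at
29.4 °C so that, at zero noise, segmentation recovers every scheduled
bout's onset and end within one sampling interval — the round-trip
invariant the recovery tests rely on.

What the simulator deliberately does **not** model: ambient-temperature
or photoperiod coupling, within-individual correlation of bout durations
(bout draws are independent given the per-individual plateau offset),
overdispersion of bout counts (Poisson), drift or failure of loggers, and
seasonal trends in euthermic Tb. Passing recovery tests therefore show
that the pipeline is correct for data of this structure, not that real
traces are this clean; gap handling and truncation are exercised by
dedicated fixtures instead.

## Verification design and problem sizes

* **Oracle equivalence**: 1000 random-walk traces (100–3000 samples) are
  segmented both by the package and by an independently written one-pass
  reference scan; agreement must be exact.
* **Round trip**: a full cohort is rendered noiselessly and segmented —
  every scheduled bout must be recovered with the right type and an onset
  within one sampling interval; at default noise the bout-type confusion
  rate must stay below 5 %.
* **Effect recovery**: 200 replicate cohorts at the design size. The
  seed-intake slope on deep-torpor days is estimated among high-fat
  hibernators, and the deep-days slope on PUFA change from the
  all-individuals change model; each true value must fall inside the
  fitted 95 % CI in at least 90 % of replicates. Recovery replicates set
  the *direct* seed-on-PUFA path to zero so the deep-days slope is
  identified — the standard isolation design for parameter-recovery
  studies; with a nonzero direct path the change model (which does not
  carry seed intake) would estimate a compound effect, not β_deep.
* **Null calibration**: 1000 cohorts with all coupling effects zeroed;
  the group F-test of the individual-level linear model, the group
  F-test of the bout-level mixed model, and the interaction F-test of
  the paired PUFA model must reject at a rate within [0.03, 0.07] at
  α = 0.05.

These sizes keep the whole verification suite in the minutes range on a
single core while leaving the binomial noise of the calibration rates
well inside the accepted bands.

## Numerical conventions and degenerate inputs

* Timestamps are serialized ISO-8601 UTC; internally time is seconds
  since experiment onset, so duration arithmetic never crosses a
  timezone. The regular-sampling check uses a 1-second tolerance.
* Logger range is enforced at [−40, 85] °C; raw values are analysed as
  logged — no calibration or quantization is applied on input (the
  simulator can optionally quantize to the 0.5 °C logger step).
* A trace with fewer than two samples in the window, a bout outside the
  experiment window, non-monotone timestamps, or remaining food mass
  exceeding provided mass are contract errors, named per individual.
* Constant responses fit (the mixed model is flagged singular, the group
  effect is exactly zero); identically-zero residual variance in linear
  models is rejected by the Type III machinery rather than reported as a
  spurious certainty.
* The hibernators-only PUFA-change model requires enough deep-torpor
  animals in both groups to carry five predictors; when a cohort cannot
  support it the result records the reason instead of erroring, since
  small cohorts legitimately produce too few hibernators.

## Known limitations

* Phenology assumes the experiment window brackets the hibernation
  season; bouts truncated by the window bias hibernation duration low by
  up to one sampling interval per truncated end.
* The energy budget is provision accounting, not energetics: no
  digestibility, body-composition conversion, or metabolic-rate
  inference.
* The AICc reduction searches backward over single-term removals; with
  the design variables exempted this is exhaustive here, but it is not a
  general all-subsets search.
* Wald χ² interaction contrasts and marginal F-tests can differ in the
  third decimal from other Type III implementations when designs are
  unbalanced; the calibration suite bounds the practical consequence.
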