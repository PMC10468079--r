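---
title: "Methods: accelerometer reduction, PAQ scoring and fitness-stratified validity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: accelerometer reduction, PAQ scoring and fitness-stratified validity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fitpaq)
```

`fitpaq` implements the analysis chain of a questionnaire-validation study
in which three physical activity questionnaires (IPAQ-SF, GPAQ, EHIS-PAQ)
are compared against a hip-worn triaxial accelerometer, with participants
stratified into cardiorespiratory fitness terciles from their 6-minute-walk
(6MWT) distance. This vignette documents the models, the parameters that
matter, the numerical conventions, and what the synthetic cohort does and
does not emulate.

## Accelerometer model

Raw acceleration (nominally 100 Hz, ±16 g) is reduced in half-open 6-s
epochs `[t, t + 6 s)` aligned to recording start; a trailing partial epoch
is dropped.

* **MAD** (`compute_mad()`): per epoch, the mean absolute deviation of the
  resultant `r = sqrt(x² + y² + z²)` from its epoch mean. MAD is gravity-
  and orientation-insensitive for fixed device placement and tracks oxygen
  cost during ambulation.
* **MET conversion** (`mad_to_met()`): METs = VO₂/3.5 (mL·kg⁻¹·min⁻¹),
  floored at 1.0 (resting). The MAD→VO₂ regression is device- and
  site-specific and is *not* hard-coded: `met_calibration()` is a pluggable
  piecewise-linear map. The default is anchored at widely used hip MAD
  intensity cut-points — 0 g → 3.5 (1 MET), 0.091 g → 10.5 (3 MET),
  0.414 g → 21 (6 MET) — and extrapolates with the last slope. Every
  property the package's tests rely on (resting floor, monotonicity,
  threshold classification) is calibration-agnostic.
* **Smoothing** (`smooth_ema()`): first-order EMA,
  `y_t = α x_t + (1 − α) y_{t−1}`, `y_1 = x_1`, with
  `α = 1 − exp(−Δt/τ)` for epoch length Δt = 6 s. The MET time constant
  defaults to τ = 20 s (a few epochs: enough to suppress single-epoch
  spikes without erasing 10-min bouts); the posture-angle EMA is fixed at
  τ = 60 s, a one-minute smoother. Constant series are fixed points and
  output stays inside the input range.
* **Posture** (`compute_ape()`, `classify_posture()`): the angle between
  the epoch-mean acceleration vector and a gravity reference estimated from
  the stillest (lowest-MAD) epochs (`estimate_reference_vector()`, default
  k = 10). Epochs with smoothed MET < 1.5 are standing below 11.6°, sitting
  from 11.6° to 72.0° inclusive, lying above 72.0°; the 72.0° boundary is
  assigned to sitting because the band is stated inclusively. A zero
  epoch-mean vector yields posture `unknown`, which counts as neither
  sedentary nor standing time.
* **Intensity** (`classify_intensity()`): VPA at MET ≥ 6.0,
  MPA at 3.0 ≤ MET < 6.0, SB at MET < 1.5 with sitting/lying posture,
  light otherwise. Together with posture this partitions every wear epoch
  into exactly one class.
* **Non-wear** (`detect_nonwear()`): runs of ≥ 60 min below 0.0067 g MAD
  (both configurable). The wear protocol itself (hip waking / wrist sleep)
  provides the awake segmentation; when only epoch tables are available the
  `awake` flag is taken from the table (the generator uses a 07:00–23:00
  waking window).
* **Summaries** (`summarise_day()`, `summarise_week()`): minutes are epoch
  counts × 6 s / 60 over awake-wear epochs. A valid day needs ≥ 600 such
  minutes; an included participant needs ≥ 4 valid days of which one is a
  Saturday or Sunday. Weekly minutes are `7 × (5/7 × weekday mean + 2/7 ×
  weekend mean)` over valid days — the weighting preserves the weekend
  representation the inclusion rule demands — falling back to the
  unweighted mean × 7 when a stratum is empty. Daily SB is the unweighted
  mean over valid days, in min/day.

## Questionnaire scoring

All instruments report days/week × minutes/day per domain; weekly minutes
are their product after cleaning. `cleaning_rules()` defaults to the
official IPAQ conventions: per-domain daily minutes truncate at 180, and a
summed daily total above 960 min invalidates the record; both rules are
configurable and every action is logged in `cleaning_codes`. Cleaning can
only reduce weekly totals.

* IPAQ-SF: MPA = moderate, VPA = vigorous, walking kept separate. MVPA
  defaults to moderate + vigorous (walking excluded; a flag includes it).
* GPAQ: VPA = work + leisure vigorous; MPA = work + leisure moderate +
  transport, transport being moderate by the analysis-guide convention
  (configurable).
* EHIS-PAQ deliberately measures activity types, not intensities, so its
  MVPA composite is aerobic sports/fitness/recreation + walking + cycling,
  weekly. Sitting arrives either in minutes or as an ordered category;
  `sitting_codebook()` scores categories at interval midpoints, with the
  open-ended top band at its lower bound plus half the preceding width
  (default bands < 4 h, 4–6 h, 6–8 h, 8–10 h, ≥ 10 h → 120, 300, 420, 540,
  660 min).

`harmonise_paq()` produces one wide row per participant and flags
completeness; the analysis restricts itself to participants with all three
instruments, an included accelerometer week and a fitness group.

## Fitness grouping

Participants are split by sex into age bands 18–34.99, 35–49.99, 50–64.99,
65+ (left-closed at 35/50/65), then into 6MWT terciles within each cell:
ascending distance, ties broken by participant id, cut at ranks ⌈n/3⌉ and
⌈2n/3⌉, so cell group sizes differ by at most one. Because cuts are
cell-wise, group-wise 6MWT ranges may overlap across cells — that is a
property of the stratified design, not an error. Cells smaller than 3 fall
back to sex-pooled cuts with a warning. Descriptives are median and IQR
with type-7 (linear-interpolation) quantiles, stated so that differences
from other software's quantile conventions are attributable.

## Validity, agreement and equivalence

`validity_analysis()` fixes the difference direction as PAQ − accelerometer
(configurable and logged; under-reported sitting then gives negative paired
t statistics). Per instrument × measure:

* **Spearman validity** per group and total, average-tie ranks, two-sided
  p; bands on |ρ|: ≤ 0.29 very low, 0.30–0.49 low, 0.50–0.69 moderate,
  0.70–0.89 high, ≥ 0.90 very high (0.90 itself is assigned to "very
  high"). Groups with < 3 complete pairs are withheld. Missingness is
  handled by pairwise deletion per instrument × measure.
* **Bland–Altman**: bias = mean difference, limits of agreement
  bias ± 1.96 × SD (n − 1), with per-pair rows for plotting.
* **Equivalence**: paired TOST via the confidence-interval method at
  α = 0.05 one-sided, i.e. a 90% CI — the standard level for this method.
  Bounds are ± 15% of the pooled accelerometer mean of the measure (SB in
  min/day, MVPA in min/week), overridable with raw bounds. The CI-inside-
  bounds criterion and the two-one-sided-p criterion are algebraically
  identical; the tests assert they never disagree. Zero-variance
  differences get an exact verdict (|mean| vs bound) with the df flagged
  degenerate.
* **Group differences**: per-group normality screening (Lilliefors-
  corrected Kolmogorov–Smirnov by default, since location and scale are
  estimated; the uncorrected variant is a toggle; groups under 5 are
  treated as non-normal), then Kruskal–Wallis if any group departs at 0.05,
  else one-way ANOVA; pairwise post-hoc tests with Bonferroni adjustment
  over the number of pairs.

## The synthetic cohort

The generator (`cohort_config()` defaults) defines the study conditions:
179 participants, 42% male, age ≈ N(47, 10) truncated to 18–80; a latent
fitness z-score; 6MWT = 650 + 80 z + N(0, 30) m (tercile medians near
570/660/750 m); true MVPA lognormal with group means 300/360/420 min/week
(CV 0.5) and vigorous shares of 1/2/4%; true awake sedentary time
N(500, 110) min/day truncated to [60, 900]. The fitness-group label used by
the reporting model is the tercile of *latent* fitness — deliberately
independent of the analysis-side 6MWT grouping, so the grouping stage can
be validated against generation (the resulting label mismatch attenuates
group contrasts downstream, which the defaults anticipate).

Reporting error has three components:

1. **Group multipliers**: reported activity = true × 2.5/1.8/1.3
   (low/intermediate/high); reported sitting = true × 0.6/0.55/0.7.
2. **Mean-one lognormal noise**, CV 0.25.
3. **Uninformed recall**: with probability 0.85/0.45/0.10 by fitness group
   a report is generated from the group's behaviour distribution instead of
   the participant's own true value.

The third component exists because a purely multiplicative model cannot
express the phenomenon under study: multiplicative mean-one noise that is
strong enough to push rank validity to the published low-fitness regime
(ρ ≈ 0.1–0.2) has so heavy a tail that group means become practically
unrecoverable, while uninformed recall erodes rank validity without
touching group means. The over-reporting multipliers are therefore
recoverable as ratios of group means (reported/true), and group-wise
Spearman validity is expected around 0.2/0.4/0.6 from low to high fitness —
the regime published for these instruments. With unit multipliers, zero CV
and zero recall probability the reporting model is the identity up to the
days × 5-minute-grid decomposition of weekly minutes (error below
2.5 min × days per domain). Reported weekly minutes are capped at
7 × 960 min only as a physical plausibility ceiling; with the default CV it
is essentially never active.

Synthesis is two-tier for desk-scale runtime: epoch-level weeks
(`generate_epoch_series()`: sleep 23:00–07:00, awake days assembled from
sedentary/light/MPA/VPA blocks whose totals match the profile, activity
blocks buffered by light blocks, weekly activity allocated multinomially
across days) for pipeline testing, and raw 100 Hz signals only for short
bouts (`generate_raw_bout()`) for MAD/APE unit tests. Cohort-scale runs use
`simulate_device_summaries()`, which perturbs the true weekly summaries
with small lognormal device noise (CV 0.08 activity, 0.05 SB) instead of
synthesising ~100k epochs per participant.

What the generator does **not** emulate: seasonality, item non-response
patterns, activity-type mismatch between self-report and device (cycling,
swimming), day-of-week behaviour differences, and the published finding
that the EHIS-PAQ MVPA composite is equivalent to the accelerometer — the
generator applies the same over-reporting multipliers to the EHIS composite
as to the other instruments, so synthetic EHIS MVPA is *not* equivalent.
Passing tests on this cohort demonstrate the correctness and calibration of
the analysis chain, not empirical claims about real populations.

## Numerical conventions and edge cases

* Epochs are half-open, aligned to recording start; 1 min = 10 epochs.
* EMA initialisation `y_1 = x_1`; α from the time constant as above.
* Posture band edges: 11.6° → sitting, 72.0° → sitting.
* Tercile ties: participant-id order; exact tie handling of any original
  study is not reproducible from published information, so it is fixed and
  documented here.
* Degenerate inputs: empty day → invalid zero-minute day; < 3 pairs →
  withheld correlation; < 2 pairs → Bland–Altman error; zero-variance
  TOST → exact verdict; missing 6MWT → excluded with reason code.
* Problem sizes in the test suite are chosen for a desk-scale run: oracle
  equivalence on signals of up to ~3000 samples, 100 replicate cohorts of
  n = 500 for the ordering property, n = 2000 for multiplier recovery, and
  8 participant-weeks (~800k epochs) for pipeline closure, with closure
  tolerances of ±5% weekly MVPA and ±2% daily SB at 7 complete wear days
  (the residual error is EMA edge-blurring at block boundaries plus
  rounding to whole epochs).

## Known limitations

* The MAD→MET default calibration is a documented stand-in anchored at
  published cut-points, not a device-fitted regression; studies with their
  own calibration should supply it via `met_calibration()`.
* Awake/sleep segmentation relies on the wear protocol or a fixed nocturnal
  window, not a sleep algorithm.
* `read_sav()` wraps `foreign::read.spss()`; value-label quirks of specific
  SPSS exports may need a column mapping (`map_study_columns()`) and manual
  type checks.
* The analysis treats the accelerometer as the criterion; it is itself an
  imperfect reference (device placement, non-ambulatory activities), so
  "validity" here is criterion validity against that reference, not truth.
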