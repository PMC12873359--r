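---
title: "Models and methods in restact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in restact}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`restact` analyzes minute-epoch actigraphy: non-negative activity counts
accumulated over fixed 1-min bins by a wearable accelerometer logger,
recorded continuously for weeks from diurnal subjects housed under a
12:12 light–dark schedule with lights on at 07:00. This vignette is the
package's own account of the statistical models it fits, the tunable
parameters and their defaults, what the synthetic-data generator does and
does not emulate, and the numerical and design choices made where the
methodology leaves room.

## 1. The data model

An `epoch_series` stores counts at a fixed epoch length (default 1 min)
with a start timestamp and the light schedule. Counts are required to be
non-negative integers and equally spaced; gaps are an error at read time
and are never imputed. All day-level operations (hourly profiles, daily
means, per-day model fits, per-day entropy) use *complete calendar days*,
midnight to midnight: incomplete first and last days are excluded rather
than extrapolated, which avoids edge bias at the cost of discarding up to
two partial days.

Descriptive statistics use the sample (n−1) standard deviation, the
moment estimator of skewness `m3/m2^1.5`, and *excess* kurtosis
`m4/m2² − 3` (normal = 0); the convention is recorded in the output
because kurtosis conventions differ across software. "Average daily
activity" defaults to the per-epoch mean over complete days (so its units
match the basic-statistics mean); the per-day-total convention is exposed
alongside because the literature uses both.

## 2. Cosinor rhythm analysis

The single-component model is

y(t) = M + A·cos(ω₂₄ t + φ), ω₂₄ = 2π/1440 rad/min,

with mesor M (rhythm-adjusted mean), amplitude A and acrophase φ. Because
diurnal activity commonly carries a strong 12 h (semi-circadian)
harmonic, the double model adds A₁₂·cos(ω₁₂ t + φ₁₂), ω₁₂ = 2π/720.
Periods are fixed; no period estimation is attempted.

Estimation linearizes each component as
`a·cos(ωt) + b·sin(ωt)` and solves by ordinary least squares, then maps
back: `A = √(a²+b²)`, `φ = atan2(−b, a)` folded into [0, 2π). On
noiseless model input this equals direct nonlinear least squares exactly
(tested against `optim`). Time is measured in minutes from local
midnight, so φ is directly interpretable against clock time; the 24 h
peak time `t_peak = (2π − φ)/ω₂₄ mod 1440` is exposed separately.

Choices worth knowing:

- **10-min aggregation.** Counts are summed into clock-aligned 10-min
  bins before fitting (the conventional preprocessing for this model
  class); a leading partial bin is trimmed, a trailing one dropped.
- **Per-day fits, averaged (default).** The model is fitted to each
  complete day separately and the parameters averaged — linear parameters
  arithmetically, acrophases by the circular (resultant-vector) mean,
  which is the only correct average near the 0/2π wrap. A whole-series
  mode exists (`aggregate = TRUE`, `fit_cosinor` on the full series)
  because "fit per individual on a daily basis" admits both readings;
  per-day-averaged is the default as the stricter reading.
- **Degenerate input.** Amplitudes at numerical-noise level are reported
  as exactly 0 with an undefined (NA) acrophase; days whose fit fails a
  precondition are skipped and counted, never imputed.

## 3. Behavioral organization (bout distributions)

Epochs are dichotomized at a threshold equal to the **mean of the nonzero
counts**, computed once over the whole recording. The per-day variant is
available behind a flag; the whole-recording default is simpler, fully
reproducible, and serves the same purpose (robustness to day-to-day
differences in device mounting). Rest epochs are strictly below the
threshold ("remained below"); ties count as active. Maximal runs of
same-state epochs become bouts; the first and last runs are censored by
the recording window and are dropped by default (`keep_all` retains
them, in which case bout durations always sum to the recording length).

The empirical survival function `P(x ≥ a)` is evaluated at every distinct
observed duration. Two functional forms are fitted by OLS in transformed
coordinates, matching the fit-a-functional-form methodology (an MLE
Hill-type estimator is included only as a cross-check):

- rests: `P(x ≥ a) = A·a^(−γ)`, regression of log P on log a, default
  range 3–30 min. The lower bound follows the stated fitting rule
  (a ≥ 3 min); the upper bound confines the fit to the region where
  power-law scaling is described (about one decade). Both bounds are
  configurable, including the 2-min variant.
- active bouts: `P(x ≥ a) = exp(−α·a^β)`, regression of log(−log P) on
  log a, default range 10–100 min. In-range points with P = 1 are
  excluded (their double logarithm is undefined).

No Clauset-style x_min selection or KS hypothesis testing is performed;
the ranges are fixed, as in the source methodology.

## 4. Sample Entropy

SampEn(m, r) = −ln(A/B), where B counts pairs of distinct m-point
templates within Chebyshev tolerance r and A counts those whose (m+1)-th
points also match. The package uses the Richman–Moorman convention: both
counts run over the N − m templates that have a defined extension, so
A/B is a proper conditional probability, A ≤ B, and SampEn ≥ 0 whenever
defined. Self-matches are excluded; the tolerance comparison is
inclusive (≤ r). When no pair matches (B = 0) or no extension matches
(A = 0), the value is undefined and propagated as NA — never as
infinity — and excluded from averages with a logged count.

Defaults m = 2, r = 0.2 in SD units: each day's lights-on (07:00–19:00)
counts are z-normalized (sample SD) to mean 0, SD 1, so r = 0.2 is exact
per day. Computation is per day with averaging, mirroring the per-day
cosinor treatment and avoiding spurious template matches across the
overnight gap; a concatenated mode exists behind a flag. The compiled
kernel is verified against an O(N²) brute-force oracle on hundreds of
short sequences and against the analytic i.i.d. Gaussian limit
−ln(2Φ(r/√2) − 1) at N = 5000.

## 5. Group statistics

- **t tests** are pooled-variance Student by default (matching the named
  test in the source methodology), Welch by flag. Zero pooled variance
  with equal means gives t = 0, p = 1; with unequal means the result is
  flagged degenerate rather than fabricating a statistic.
- **Correlations** are reported as (r, F, p) with `F = r²(n−2)/(1−r²)`
  on (1, n−2) df — identical to the two-tailed slope test. The report
  always derives df₂ = n − 2 from the sample actually used; subjects
  with missing cortisol are dropped before computing n.
- **Hourly profiles** (per-clock-hour totals averaged over complete
  days) are compared by a balanced split-plot ANOVA: group
  between-subject, hour within-subject, subject-within-group as the
  between error stratum. No sphericity correction is applied by default
  (none is part of the emulated analysis); Greenhouse–Geisser is
  available by flag and the epsilon is always reported. Post hoc:
  per-hour pooled t tests, Bonferroni-corrected over the 24 hourly
  comparisons (the raw p is also reported so a p < 0.1 "tendency" tier
  can be read off).
- **Three-chamber trials** reduce to per-subject means of the social
  preference index SPI = (%stranger − %empty)/100 ∈ [−1, 1], dwell
  percentages and transition counts, with group t tests and the
  transitions-vs-%stranger correlation.

Type-I error of both the t test and all three ANOVA effects is verified
by null simulation at the cohort scale (n = 5 per group, 10⁴ replicates,
rejection rate 0.05 ± 0.01) in the acceptance suite.

## 6. The synthetic-data generator

The generator is a stated world, fixed once, against which every
estimator is tested by parameter recovery:

- **Bout process.** Each subject is an alternating renewal process.
  Rest durations follow a truncated power law with survival exponent γ
  on [2, 480] min (defaults γ = 1.10 control-like, 1.38 exposure-like);
  active durations follow the stretched-exponential law with
  (α, β) = (0.86, 0.60) / (0.67, 0.67). Sampling is inverse-CDF from the
  continuous law, then **floored** to whole minutes. Flooring — rather
  than rounding up — is deliberate: for integer k,
  P(⌊X⌋ ≥ k) = P(X ≥ k), so the discrete durations inherit the survival
  function exactly at integers and log-log recovery of γ is unbiased
  apart from upper truncation. Ceiling would shift the integer survival
  curve to S(a−1) and inflate the fitted exponent by roughly 10–20% over
  the 3–30 min window.
- **Diurnal envelope.** Within active bouts, counts are
  negative-binomial (overdispersed, size 2 — actigraphy counts are far
  from Poisson) around a double-cosinor envelope clipped at 0. The
  mesor/24 h truth is the group parameter table on the per-minute scale.
  The default 12 h harmonic is A₁₂ = 120/140 at φ₁₂ = 2.50: the fitted
  table amplitude (≈55 counts/min) sits just below the bimodality
  threshold A₂₄/4 and yields a unimodal envelope, while the world being
  emulated is explicitly bimodal (morning rise, dip near 13:00, evening
  peak). With these defaults the envelope's hourly argmin is T13 and a
  5-subject × 22-day cohort reproduces the dip within the 1 h bin width.
  Users can pass the table values verbatim through `cosinor_truth`.
- **Rest counts and night.** Rest epochs draw low-rate Poisson counts
  (mean 5, far below any realistic threshold); lights-off intensities
  are multiplied by `night_suppression` (default 0.2 — the envelope is
  already near zero at night, so nights are near-silent, matching the
  day/night contrast of the emulated recordings).
- **Between-subject heterogeneity.** A log-normal subject multiplier
  (CV 0.2, matching the observed between-subject CV of mean activity of
  about 0.19) scales each subject's intensities. This is what gives the
  cortisol coupling something to correlate with.
- **Cortisol.** Subject cortisol = intercept + slope × mean hourly
  activity + Gaussian noise. When no explicit noise SD is given, it is
  calibrated from the realized between-subject activity SD so the
  population correlation equals `cortisol_target_r` (default 0.72). Each
  subject's three monthly samples are jittered to average exactly to the
  subject value, so the per-sample CSV round-trips losslessly into the
  correlation analysis.
- **Determinism.** Every subject derives one RNG substream from
  (seed, subject_seed), so cohorts are reproducible byte-for-byte and
  extensible without perturbing existing subjects.

What the generator does *not* emulate: device physics and calibration,
behavioral categories (feeding, grooming), sleep staging,
autocorrelation within bouts beyond the envelope, and seasonal or
developmental drift. A green recovery test therefore establishes that the
estimators recover the parameters of *this* generative family at the
cohort's scale — not that real recordings follow these laws.

Two known, quantified gaps: (1) recovering γ by running the full
threshold pipeline on generated cohorts is biased low by ≈0.1–0.15,
because the diurnal envelope pushes low-envelope active epochs below the
threshold and merges runs; the duration law itself is recovered
unbiasedly, and the end-to-end check relies on the group *ordering*,
which is robust. (2) Realized daytime SampEn levels (≈0.3–0.5) sit below
the published group means; the ordering (exposure-like > control-like)
follows from the rest-fragmentation difference and is what the
end-to-end criterion asserts.

## 7. Numerical choices and degenerate inputs

- Acrophases are reported in radians in [0, 2π), as fitted; averaging is
  circular. An amplitude below 1e−10 × the response scale is treated as
  zero with NA acrophase.
- Survival curves use exact tie counting (no epsilon comparisons).
- log-space fits require ≥ 3 distinct in-range durations, else error;
  R² is computed directly from residuals so perfect fits do not warn.
- Constant sequences make z-scoring (and hence entropy) an error at the
  sequence level; at the day level the day is marked undefined and
  excluded from the subject mean with a count.
- All randomness in tests and the acceptance script is seeded; derived
  seeds stay below 2³¹.

## 8. Decisions on genuinely open points

- *Whole-series vs per-day cosinor*: both implemented; per-day averaged
  is the default.
- *Threshold scope*: whole-recording default, per-day behind a flag.
- *Rest-fit lower bound 2 vs 3 min*: both reachable; 3 min is the
  default, matching the stated fitting rule.
- *Entropy scope*: per-day default, concatenated behind a flag; the
  per-day daytime record at 1-min epochs gives N = 720, comfortably
  above the ~10^m–20^m guideline for m = 2.
- *"Average daily activity"*: per-epoch mean default, per-day total
  exposed.
- *Within-bout count law*: negative binomial, a modeling convenience;
  nothing downstream depends on it beyond overdispersion stressing the
  threshold rule realistically.
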