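---
title: "Flight activity and effort from songbird accelerometry: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flight activity and effort from songbird accelerometry: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(accelflight)
```

## The problem

Small forest songbirds provisioning nestlings move through their territory in
hundreds of short flights a day, almost all of them too brief and too hidden
to time by eye. A body-mounted tri-axial accelerometer records the bird's
movement directly: a miniature MEMS logger on the synsacrum samples the
acceleration vector **A** = (a~x~, a~y~, a~z~) in g-units at a fixed rate
(23 Hz in a typical field configuration, 100 Hz in an aviary configuration),
over a ±8 g range with 8-bit output — 256 levels, a 0.0625 g step. From such
a trace this package recovers:

* a per-window **behaviour classification** over six classes (flying,
  inactive/perching, food shaking, preening, swallowing, bill wiping),
* **flight bouts** with start times and durations,
* per-bird **activity metrics** — the flight proportion R~flight~ (total
  flight time over recording time) and mean flight duration T~flight~ —
* per-flight and per-bird **effort** as VeDBA, the vectorial dynamic body
  acceleration,
* a **Weibull distributional regression** describing how the per-flight
  effort distribution changes with flight duration,
* **wing morphometrics** (wing loading N = mg/S, aspect ratio AR = b²/S,
  weight-normalized wing area S\* = 1/N) and their association with effort,
* and back-of-the-envelope **ecological extrapolations** (daily flight time
  and distance, foraging radius).

Because raw field recordings of this kind are rarely published, the package
also contains a first-class synthetic-data generator that emulates the
logger and the bird, with exact ground truth, so that every downstream stage
is testable end to end.

## Signal model: VeDBA

The static (gravitational + postural) component of each axis is estimated by
a centered running mean; the default window is 5 samples, i.e. 0.22 s at
23 Hz. The dynamic body acceleration is the residual, DBA = A − A~static~,
and

$$\mathrm{VeDBA} = \sqrt{\mathrm{DBA}_x^2 + \mathrm{DBA}_y^2 + \mathrm{DBA}_z^2}.$$

Numerical conventions (the literature leaves them open, so they are fixed
here explicitly):

* **Edge handling.** Near the trace boundaries the running-mean window is
  clipped to the available samples (at position *i* the mean runs over
  `[max(1, i−2), min(n, i+2)]` for the 5-sample window). The output keeps
  the input length and no fabricated padding value ever enters an average.
  Interior values — everything further than half a window from an edge —
  are unaffected by this choice, and per-segment VeDBA means are dominated
  by interior samples.
* **Window in samples, not seconds.** The smoothing parameter is "5
  samples" at any rate, matching how the field configuration defines it;
  at 100 Hz this is a 0.05 s window, which slightly widens the passband of
  the dynamic component rather than silently changing the sample count.
* **Quantization.** Values map to the nearest level of the grid
  `−range + k·step`, `k = 0..2^bits − 1`; ties round half away from zero
  (symmetric treatment of positive and negative accelerations); values
  beyond the range clip to the extreme levels, as a saturating MEMS output
  does. The operation is idempotent and never moves an in-range value by
  more than `step/2`.
* **Timestamps** are `(i − 1)/rate` (0-based sample index over rate), and
  every segment operation uses half-open intervals `[start, start + dur)`,
  so abutting segments never share a sample.

## Behaviour classification

The trace is cut into consecutive non-overlapping windows of 16 samples
(≈0.7 s at 23 Hz — about 14 wingbeat cycles of a 20 Hz flapper, and short
enough that few windows straddle two behaviours); a trailing partial window
is dropped. Per window the features are: per-axis mean, SD, min, max,
skewness and excess kurtosis (population moments; defined as 0 for constant
windows); the three pairwise axis correlations (0 for constant axes); mean
and max of a window-local VeDBA; and the dominant non-DC bin of the z-axis
discrete Fourier spectrum with its power. An XGBoost multi-class model (200
trees, depth 4, learning rate 0.1, single thread, fixed seed) is trained on
windows labelled by majority ground truth, with per-row weights inversely
proportional to class frequency because maintenance behaviours are far rarer
than perching and flight. An "other" class is excluded by construction.

The intended workflow mirrors the two-stage field protocol: train on an
annotated higher-rate session subsampled to a comparable rate (100 Hz →
every 4th sample → 25 Hz), then predict on 23 Hz field traces. The 25/23 Hz
mismatch is deliberately retained: the wingbeat carrier aliases to 5 Hz in
training data but 3 Hz in field data, so the model must rely on the
amplitude-type features that transfer across rates. On default synthetic
data this still yields window-level flight recall and precision above 0.9,
which is the package's acceptance property (the confusion matrix of any
real aviary dataset is not reproducible without that data).

## Flight segmentation

Window labels collapse to flying/non-flying. Every single non-flying window
flanked by two flying ones — judged on the *original* sequence, in one left
to right pass — flips to flying (a sub-second pause inside a bout is part of
the same flight); runs of two or more non-flying windows are never touched,
and a leading or trailing window has only one flank, so it never flips. In
the overlapping pattern F,N,F,N,F both single gaps flip. The rule is
idempotent, never reduces flight, and the added flight time is exactly the
filled-window count times the window duration. There is deliberately no
symmetric rule for a lone flying window: a single-window (~0.7 s) flight is
a real, common event for this kind of bird. Maximal flying runs then become
segments with `start = first_window_index × window_duration` and
`duration = run_length × window_duration`.

## Per-bird metrics

R~flight~ is total segment time over recording time; T~flight~ is total
segment time over segment count; per-segment effort VeDBA~mean~ is the mean
VeDBA over the segment's half-open interval, and the per-bird effort
VeDBA~mean,bird~ is the **unweighted** mean over segments — each flight
counts once regardless of duration (a duration-weighted variant is
available as an option). The tagging time of a bird is the midpoint of its
recording. Recordings under 10 min and birds with zero detected flights are
flagged, not excluded.

Window quantization has two visible structural effects worth knowing about
when comparing against continuous-time truth: detected bout durations are
rounded up to multiples of ~0.7 s (so detected T~flight~ runs ~0.4–0.6 s
above the true mean bout), and the shortest detected segments include a few
boundary samples of non-flight, which dilutes their measured VeDBA. Both
effects are bounded by the window duration per bout boundary, which is the
bound the tests assert for R~flight~.

## The effort–duration model

Short flights (take-offs, aerial sallies, descents) show highly variable
per-flight mean VeDBA; long commuting flights converge to a stable level.
This is modelled as VeDBA~mean~ ~ Weibull with both parameters depending on
log duration through log links:

$$k(T) = e^{\alpha_0 + \alpha_1 \ln T}, \qquad
  \lambda(T) = e^{\beta_0 + \beta_1 \ln T},$$

fitted by maximizing the analytic log-likelihood with BFGS. Log links
guarantee positivity for every duration; log duration is the single
covariate. Starting values are moment-based (shape from the coefficient of
variation via the standard k ≈ CV^−1.086 approximation, scale from the
mean), with a small deterministic multi-start fallback; the linear
predictors are clamped to ±15 inside the likelihood so the optimizer can
probe extreme parameters without overflow. Non-convergence is reported in
the fitted object, never silently. Quantile curves are the closed form
Q(p;T) = λ(T)(−ln(1−p))^{1/k(T)}; the median curve (p = 0.5) at long
durations is the long-flight effort plateau.

Because no fitted coefficients for real data are published, the model is
validated by parameter recovery: simulating from known coefficients and
refitting recovers the duration slopes to within ±0.05 at n = 5000, with
bias shrinking as n grows (tested at n = 10³ and 10⁴). A
constant-parameter Weibull fit from `fitdistrplus` serves as an independent
cross-check in the no-covariate case.

## Morphometrics

Wing photos give single-wing area and semi-span; doubling yields S and b
(no body-root correction is applied — none is assumed in the source
procedure). Derived: mean chord S/b, AR = b²/S, N = mg/S with g = 9.81
m s⁻², S\* = 1/N. Internally everything is SI; the population table I/O is
in field units (g, mm², mm) with conversion at the boundary. Note that a
ratio computed from group means (e.g. AR from mean mass and mean area) is
close to, but not the same as, the group mean of per-bird ratios; the
package computes per-bird ratios and exposes both, and a test documents the
discrepancy.

## Group comparisons

Sex comparisons use Welch's unequal-variance t-test (fractional df) —
chosen because that is the form consistent with fractional degrees of
freedom in this literature — with the pooled-variance test as an option,
and the arcsine square-root transform available for proportions. Pair
comparisons are one-sample t-tests on within-pair differences (df = pairs −
1), with zero-variance differences flagged as degenerate rather than
returning a fabricated p-value. Brood-size effects use classical one-way
ANOVA on brood size as a categorical factor (with two levels, F is exactly
the squared pooled t, which a test checks). The morphology–effort
association is a Pearson correlation plus the least-squares line (R² = r²).
The time-of-day trend is a loess smooth (tricube-weighted local *linear*
regression, span 0.75) evaluated on an hour grid with a ±1.96 SE pointwise
band; a generalized additive model would serve the same role, but the
exposed contract is the smooth curve, not a basis choice. No
multiple-testing correction is applied by default, matching single-study
reporting practice.

## What the synthetic generator emulates — and what it does not

The generator is the package's study system. Its defaults encode the field
conditions the analysis assumes, chosen once from the published summary
structure:

| parameter | default | why |
|---|---|---|
| sample rate | 23 Hz (field), 100 Hz (aviary) | the two logger configurations |
| sensor | ±8 g, 8 bit, quantized | 0.0625 g step |
| session | 7200 s | ~2 h of memory-limited recording |
| wingbeat carrier | 20 Hz, + half-amplitude 1st harmonic | small-passerine flap rate; gives a learnable spectral peak |
| flight bout law | log-normal, median 1.9 s, log-SD 0.68, truncated 60 s | mean ≈ 2.4 s, ~99.3% of bouts < 10 s, occasional 30–50 s bouts |
| behaviour chain | no-self-transition Markov, flying weight 3.2 | ~13.8% of time in flight, ~190 bouts/h |
| long-flight effort | 0.76 g | the per-bout mean-VeDBA plateau |
| short-flight spread | 0.35 g at zero duration, decaying with τ = 5 s | high variance for short bouts, convergence for long ones |
| bounding mix / pause | 30% of bouts; 20% pause fraction, 0.7 s cycle | intermittent flight style; ballistic pauses read ~0 g |

Design notes:

* Bout classes follow a first-order Markov chain **without
  self-transitions**, so realized bout durations follow each class's
  duration law exactly and two flight bouts never silently merge. The
  stationary visit distribution is closed-form (π~i~ ∝ w~i~(W − w~i~), by
  detailed balance), so the time budget is exactly controllable and
  `stationary_fractions()` exposes it.
* Signals are defined in continuous time and evaluated at the requested
  sample instants, so the 20 Hz carrier aliases at 23 or 25 Hz exactly as
  physical sampling aliases it (3 Hz and 5 Hz respectively). The harmonic is
  phase-locked to the fundamental; a bout's random phase shifts the
  waveform in time without changing its shape.
* Flap amplitude per bout is calibrated against the package's own VeDBA
  pipeline: the gain of the unit flapping waveform is computed numerically
  at the target rate, and for bounding bouts — where the flap/pause gravity
  transitions add an amplitude-independent VeDBA contribution — a secant
  (affine) calibration on a long synthetic bout is inverted instead.
  Generator and pipeline therefore agree by construction, and the per-bout
  mean VeDBA of long bouts lands within a few hundredths of a g of the
  configured target.
* During ballistic pauses all axes are near 0 g (free fall), with noise
  clamped so the vector magnitude stays below 0.2 g.
* One root seed; the schedule and the signal synthesis use fixed seed
  offsets, so stages are independently reproducible and identical
  config + seed reproduces the trace bit for bit.
* Maintenance behaviours differ only in carrier-frequency and amplitude
  tiers (8 Hz/0.5 g shaking, 3 Hz/0.25 g preening, 5 Hz/0.35 g swallowing,
  11 Hz/0.45 g bill wiping): no kinematic realism is claimed for them; they
  only need to be separable and to occupy realistic slices of the budget.

What it does **not** emulate: flight biomechanics (no speed, no position,
no aerodynamics), postural changes within a behaviour, sensor drift or
calibration error, temperature effects, or battery/memory behaviour beyond
the sample count. Passing tests on synthetic data therefore demonstrate
that the pipeline's inference machinery is correct and well calibrated —
not that a classifier trained on synthetic data would transfer to a real
bird.

The bird-population generator samples per-sex morphology from normal laws
(defaults: male mass 13.0 ± 0.49 g, wing area 8712 ± 418 mm², span 211 ± 7
mm; female 13.2 ± 0.63 g, 8196 ± 625 mm², 202 ± 12 mm; non-positive draws
are redrawn), brood sizes 3–8 concentrated on 5–7, and tagging hours
uniform over the foraging day.

## Ecological extrapolations

Explicit, unit-checked arithmetic with an overridable assumptions object
(17 h foraging day; 9.74 m s⁻¹ flight speed — a migratory estimate used as
a rough foraging stand-in, flagged as such; out-and-back trips of two main
flights):

* daily flight time = R~flight~ × 17 h (13% → 132.6 min ≈ 2 h 13 min);
* daily flight distance = that time × speed (per-bird application is the
  intended use);
* foraging radius = bout duration × speed, one leg of the out-and-back
  pair (2.38 s → ~23 m; 10 s → ≤ 100 m);
* the total:flight time ratio 1/R~flight~ (0.1366 → 7.3, i.e. "1:7.3").
  This is *total* over flight time: the non-flying:flying ratio would be
  1/R − 1 ≈ 6.3 and does not reproduce the conventional figure, so the
  definition is fixed here deliberately;
* a sex difference in proportions converts to seconds per hour via × 3600
  (0.14 vs 0.13 → 36 s h⁻¹).

## Problem sizes and tolerances used by the test suite

Chosen so the whole suite runs in well under a minute on one CPU while
leaving the statistical checks decisive: classifier end-to-end uses one
30-min aviary session (≈2 800 windows) and one 30-min field session;
gap-fill/segmentation equivalence runs 10⁴ random sequences against
brute-force oracles; type-I error checks use 1 000 replicates (bands ±0.02
around 0.05); Weibull recovery uses n = 5 000 (slope tolerance ±0.05) with
the shrinking-bias check at 10³ vs 10⁴; duration-law structure uses 2 500
bouts (≥98% under 10 s); long-bout effort convergence uses fixed 15 s bouts
over a 25-min session (tolerance ±0.05 g).

## Known limitations

* The classifier transfers across a 25 → 23 Hz rate change by relying on
  amplitude-type features; a larger rate mismatch would need rate-invariant
  features or retraining.
* Detected bout durations are quantized to ~0.7 s windows; sub-window
  flights are either absorbed or rounded up, and per-segment VeDBA of very
  short segments is diluted by boundary samples (≈0.05–0.08 g at the
  default configuration).
* The Weibull model's log-link shape cannot decay faster than a power of
  duration, so if the true effort spread decays exponentially with
  duration, the fitted envelope at very long durations is conservative.
* VeDBA is a movement-intensity proxy, not energy expenditure; no
  energetic conversion is provided by design.
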