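---
title: "Quantifying pulse depth: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying pulse depth: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsedepth)
```

## The problem

In pulse palpation the *depth* of the radial pulse — floating, sunken, or
middle-depth — is judged by how pulse strength changes as the examiner's
finger presses harder.  A floating pulse is strongest under light contact
pressure and fades when pressed; a sunken pulse is the opposite.  A
pulse-taking device makes this operational: it records the pressure
waveform at a fixed palpation site under five stepped hold-down pressures
(about 37, 73, 108, 143 and 181 mmHg, each held for five seconds), at the
three classical palpation positions (Chon, Gwan, Cheok).  The curve of
pulse strength H against hold-down pressure P — the P-H curve — is the
primary object: its argmax encodes the depth.

`pulsedepth` implements the full chain from raw waveforms to a depth
label, plus the statistics used to validate such an algorithm against
human raters, and a synthetic generator so everything is testable without
a device.

## From raw waveform to pulse strengths

Each recording is reduced to five numbers H1..H5 in four steps
(`build_profile()`):

1. **Segmentation** (`segment_steps()`).  Plateaus of the hold-down
   pressure trace are found by thresholding the local slope (0.25 s
   central difference of a ~0.5 s median-filtered trace) at 20 mmHg/s;
   runs of quasi-constant pressure at least 2 s long count as steps.
   Exactly five are required; anything else is an error, because a
   missing plateau invalidates the P-H curve.  Explicit step boundaries,
   when a file provides them, always win.  The first and last 0.25 s of
   each plateau are discarded before beat analysis (actuator settle
   time).

2. **Baseline alignment** (`detrend_baseline()`).  The baseline within a
   step is modelled as a 5th-order polynomial.  Fitting that polynomial
   to the raw samples by ordinary least squares is tempting but subtly
   wrong: a 1–2 Hz beat train over a 5 s window has a non-negligible
   projection onto low-order polynomials, so the fit absorbs a slice of
   the pulse itself and biases every downstream strength estimate by
   several percent.  We therefore fit the polynomial by *asymmetric*
   least squares: samples above the current baseline get weight 0.01,
   samples below it weight 1, iterated to a fixed point, followed by a
   hard refit through the deepest 30% of residuals (again iterated).
   The pulse spends a substantial fraction of each cycle on its
   diastolic foot, so the fit settles on the foot and the polynomial
   remains a pure baseline model; on a flat or exactly polynomial foot
   the procedure is exact to machine precision.  The symmetric form
   stays available (`robust = FALSE`) for comparison.  The fit is done
   per pressure step, not over the whole recording: the stepped
   hold-down pressure introduces baseline discontinuities at every
   actuator move that no single smooth polynomial can follow.

3. **Ensemble averaging** (`average_beat()`).  Beat peaks are detected
   as local maxima with local prominence at least 25% of the segment
   peak-to-trough, constrained to a heart-rate band (default 40–180
   beats/min, which sets the minimum peak distance).  Beats are aligned
   on their peaks and averaged point-wise over a fixed window (0.35
   median periods before to 0.65 after); partial edge beats are
   discarded.  Averaging 5–10 beats suppresses residual noise roughly
   like σ/√n, with a small floor from per-beat alignment jitter.

4. **Strength** (`pulse_strength()`).  H is the peak-to-trough amplitude
   of the averaged beat.  Devices report strength in arbitrary units and
   the choice of amplitude measure is not standardized; peak-to-trough
   is scale-linear, agrees with how P-H curves are drawn, and is
   insensitive to the baseline convention of the previous step.  Units
   are treated as abstract non-negative amplitudes throughout and never
   converted.

For simultaneous-palpation analysis the three locations are averaged
element-wise first (`location_average()`): H_i is the mean of the three
locations' strengths at step i.

## Depth coefficients

Two scalar summaries of the P-H curve are provided, both in [0, 1] with
0 = floating-like and 1 = sunken-like.

**Interpolated-curve coefficient** (`cfs_lee()`):
C = (P_opt − P0) / (P_max − P0), where P_opt is the argmax of an
interpolant through the five (P, H) points.  The interpolant is the
monotone Fritsch–Carlson piecewise cubic (`splinefun(method =
"monoH.FC")`): an unconstrained spline can overshoot between points and
park a spurious maximum far from any datum — precisely the known failure
mode of this coefficient on non-unimodal data.  The argmax is located on
a 10^4-point grid and polished by golden-section search in the
bracketing cell; on plateaus of equal maxima the smallest pressure wins
(deterministic, biased toward floating).

**Strength-ratio coefficient** (`cfs_new()`):
C = H_deep / (H_shallow + H_deep).  Two selections of the shallow/deep
strengths are implemented: variant v1 uses ((H1+H2)/2, (H4+H5)/2) and
variant v2 uses (H1, H4) — i.e. pulse strengths at roughly 37 and
143 mmHg.  The coefficient needs no interpolation, is scale-invariant,
antisymmetric under swapping its arguments, and equals 1/2 exactly for
equal strengths.  If both strengths are zero the function raises an
error rather than returning 1/2: "no pulse detected" is a data problem,
not a middle-depth pulse.  Only v1 and v2 are implemented; other
selections have been used in the field but lack published definitions.
`cfs_subject()` applies either coefficient after location averaging (the
same averaging convention for both methods, for comparability).

## Decision rules and threshold fitting

`classify_single(cfs, c*)` labels a pulse floating iff C ≤ c* (the
boundary belongs to floating).  `classify_dual(cfs, c_f, c_s)` with
c_f ≤ c_s labels C ≤ c_f floating, C > c_s sunken, and the band between
middle-depth — a reject option that trades selection rate
(`selection_rate()`, the decided fraction) for accuracy, or, read
positively, the third depth class.  With c_f = c_s the dual rule reduces
exactly to the single rule.

Thresholds are estimated by exhaustive sweep (`sweep_single()`,
`sweep_dual()`) on a 0.01 grid — thresholds in this literature are
quoted to two decimals, and a finer grid cannot be resolved by ~100
subjects.  The dual sweep also extracts the selection-rate frontier: for
each achievable number of decisions, the maximum concordant count.  MCC
is computed for single-rule sweeps only; with a reject option the 2×2
table is conditioned on an outcome-dependent subset and the MCC loses
its meaning.  Accuracy anomalies at extreme thresholds (tiny decided
sets) are left visible; they are small-sample artifacts, not bugs.

`cfs_classifier()` wraps the sweep as a model-style fit: `coef()` returns
the threshold(s), `predict()` classifies new coefficients, `plot()`
draws the sweep curves or the frontier.  Ties in the single rule go to
the smallest threshold.  For the dual rule the fit maximizes accuracy
among frontier points deciding at least `min_selection_rate` of the
cohort (default 0.7 — the regime where the reject option buys accuracy
without discarding most subjects); ties go to the higher selection rate.

## Agreement and group statistics

`agreement_table()` cross-tabulates two binary ratings in a fixed
orientation; `accuracy()` is the concordant fraction and `mcc()` the
Matthews correlation coefficient, with a zero marginal giving MCC = 0 by
the usual convention.  `welch_ttest()` compares a covariate between
groups; Welch's unequal-variance form is the default because the
floating and sunken groups' spreads differ visibly in practice (the
pooled form is behind `var_equal = TRUE`).  P-values are two-sided, and
no multiple-testing correction is applied across covariates — the
package reports the same raw quantities a clinical table would.

## The synthetic generator

`simulate_cohort()` and `simulate_record()` generate ground-truthed data
emulating a five-step pulse acquisition.

*Strength model.*  Each subject carries a Gaussian P-H envelope
H(P) = A·exp(−(P − μ)²/2w²).  The peak pressure μ encodes the true
depth, the width w (60 ± 10 mmHg) how sharply the pulse damps away from
its optimum, and A (≈150–160 ± 35–40 device units, per group) the
maximal strength.  A Gaussian bell is the simplest shape matching the
unimodal rise-then-fall of observed P-H curves with interpretable knobs.

*Group structure and calibration.*  Group-conditional μ distributions
are calibrated so that the cohort group means of the v2 coefficient land
near the published clinical anchors 0.54 (floating) and 0.63 (sunken):
frozen defaults μ ~ N(95.8, 18²) mmHg for floating and N(109.9, 19²) for
sunken, which also reproduce the published within-group SD of ≈ 0.14.
A point worth recording: because the floating group's *mean* coefficient
sits above 1/2, a Gaussian envelope forces the mean peak pressure of
both groups above the midpoint of the P1/P4 pressures (~90 mmHg) — the
groups are separated by ~14 mmHg of peak pressure, not by a
floating-below/sunken-above split around arterial pressure.  Covariates
(BMI, blood pressures, heart rate) are co-generated with group-shifted
means matching the published cohort table, for t-test demonstrations
only; no causal model is implied.

*Acquisition model.*  Step pressures are drawn around (37, 73, 108, 143,
181) mmHg with SDs (6, 10, 13, 17, 21).  Most of that between-subject
variance is modelled as a common factor (loading 0.9) — the device
adapts its pressure protocol to the wrist as a whole — with independent
jitter making up the remainder, and a 12 mmHg minimum inter-step gap; a
real protocol never holds two steps at nearly the same pressure, and
fully independent draws would collide often enough to merge plateaus.
Per-location jitter (5 mmHg on μ, 10% on amplitude) and a 10%
multiplicative per-step strength scatter mirror the repeatability
reported for array-sensor devices.  Waveforms (only generated on
request) tile a two-Gaussian beat template — systolic peak plus smaller
dicrotic bump, period rounded to an integer number of samples at
100 Hz — scaled to the injected strength, riding on baseline wander (a
respiration sinusoid at 0.25 Hz plus a slow spline-interpolated random
walk, both scaled by `drift_amplitude`) and white noise.  The template's
values below 2% of its peak are clamped to zero: late diastole sits on
an exactly flat foot, which is both physiologically reasonable (the
runoff has returned to baseline) and what makes the foot-based baseline
fit exact on clean data.

*Randomness.*  One integer master seed drives a hierarchical stream
(cohort → subject → location → waveform), so any subject subset is
reproducible independently of cohort size, and a record is bit-identical
under the same seed.

*What the generator does not emulate* — and hence what green tests do
not certify about real data: arterial hemodynamics (no Windkessel, no
wave reflection), sensor-array spatial structure, realistic beat
morphology beyond peak-to-trough amplitude, arrhythmia and motion
artifacts, and any dependence of the envelope shape on pressure-step
order (no hysteresis).  The generator constrains only the P-H envelope
behavior and cohort-level summary statistics; waveform-level choices are
stand-ins.

## Numerical conventions and degenerate inputs

* Threshold grid 0.01 over [0, 1]; sweep ties resolved deterministically
  (smallest threshold / widest reject band).
* Argmax ties in `cfs_lee()` take the smallest pressure.
* Both strengths zero in `cfs_new()` is an error, as is a segmentation
  that does not find exactly five plateaus, or fewer than two complete
  beats in a step.
* Waveform CSVs must have a monotone time base whose step deviates from
  the median by at most 5%; the sampling rate is inferred from the
  median step.
* Labels serialize as lowercase `floating` / `sunken` / `middle_depth`;
  unknown strings are rejected.

## Problem sizes used by the test suite

The suite validates cohort-level statistics on simulated cohorts of
49/72 subjects (the canonical concordant group sizes), calibration on
500 per group, the Welch separation property over 100 seeded cohorts,
and waveform-level recovery on a handful of full records — sizes chosen
so the whole suite exercises every code path in about a minute while
keeping Monte Carlo margins comfortable.

## Known limitations

* The pulse-strength definition (peak-to-trough of the averaged beat) is
  one of several defensible choices (peak above foot, mean pulse
  pressure); results are scale-linear in any of them but thresholds are
  not interchangeable across definitions.
* `cfs_lee()` on fewer than ~4 informative points inherits all the known
  fragility of interpolated argmax estimates; the strength-ratio
  coefficient is the recommended default.
* The dual-rule threshold choice depends on the selection-rate floor the
  analyst is willing to accept; there is no data-driven default for that
  trade-off.
* Agreement statistics assume the reference diagnoses are themselves
  reliable; with rater accuracy near 70%, an algorithm cannot be
  expected to exceed that ceiling against such a reference.
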