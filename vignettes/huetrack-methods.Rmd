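---
title: "Models and methods behind huetrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind huetrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`huetrack` implements the full analysis chain for continuous two-stream
color tracking experiments: stimulus simulation, a synthetic observer,
target–response pairing, a constrained von Mises mixture of report
precision, simulation-based validation, and spectral phase analysis of
precision time-courses. This vignette explains each model, the tunable
parameters, and the numerical and design choices, so that users know
exactly what is being computed and where the package's own decisions
enter.

## Stimuli: constrained random walks on the hue circle

Each color stream follows a walk on the 360° hue circle at a fixed speed
of 1°/frame at 60 frames/s (480 frames = 8 s by default). Candidate
reversal points are spaced by independent uniform integer draws between
30 and 100 frames; at each candidate the walk's direction reverts with
probability `reversal_prob`.

`reversal_prob` defaults to 1 (every candidate reverses). With certain
reversal the expected candidate spacing of 65 frames implies roughly
480/65 ≈ 7.4 reversals per stream per trial and a merged two-stream
reversal interval of about 0.54 s. Descriptions of comparable stimulus
sets report fewer reversals and longer, more variable intervals than this
deterministic-reversal arithmetic yields, which is why the reversal
mechanism is exposed as an explicit probability parameter rather than
hard-coded: the published interval statistics are not guaranteed to be
reproducible from the verbal description of the generative process, and
`reversal_prob` lets users explore the family. All stimulus statistics
(`stimulus_statistics()`) are computed from whatever set is actually
generated.

Two streams form an admissible pair when their circular distance is at
least `min_dist = 60°` at *every* frame, checked exhaustively over the
trajectory length. Pairing scans randomly ordered candidate pairs from a
precomputed pool and looks only at the constraint, never at the
trajectory content, so the histories of paired streams remain
independent. With frequent reversals the walks are local (they typically
visit a third of the circle), and pairs that stay 60° apart for 8 s tend
to occupy nearly disjoint hue ranges; the per-trial hue intersection
fraction reported by `stimulus_statistics()` is therefore sensitive to
`reversal_prob`, and is computed on integer-degree-binned visited hues (a
binning choice of this package).

Hues map to iso-luminant colors on a circle of chromaticity radius
0.0576 centered on the white point (u′ = 0.1978, v′ = 0.4683) in a
14.5 cd/m² luminance plane; hue 0° lies on the +u′ axis and angles grow
counter-clockwise. Dot-level rendering (dot clouds, dot identity
flipping, display calibration) is out of scope.

## The synthetic observer

The observer is the generative counterpart of the analysis assumptions:
at probe time one stream is *favored* and reported with von Mises error
of SD `sd_high`, the other with `sd_low` (degrees; `0 < sd_high ≤
sd_low`). Under `fixed` allocation the favored stream is drawn once per
trial with probability ½. Under `alternating` allocation favor follows
the sign of `cos(2π f (t − t_cue) + φ)`: a deterministic phase function,
not a stochastic switching process, because the claim being exercised
downstream is an antiphase relation between streams, not a
switching-time distribution. When a trial has no cue (or
`cue_resets_phase = FALSE`) the phase is drawn uniformly per trial, so
cue-absent trials carry no SOA-locked structure. This observer is a
stand-in sufficient to exercise the analyses, not a cognitive model: it
has no generative account of *why* precision alternates, no reaction
times, no learning, and by default no guessing or swapping (an optional
`swap_rate` exists purely to stress-test the pairing rule).

Double-report trials report the favored stream first with probability
`first_confidence = 0.9`, operationalizing the assumption that the first
dial report is usually the more confident one. Trial lengths for the
free-length designs are drawn uniformly from 6–8 s (360–480 frames) and
the probe-time targets are the trajectory hues at the truncation frame;
SOA designs probe at fixed times on six-point grids (3.0–4.0 s in 200 ms
steps, 3.0–3.5 s in 100 ms steps, or 3.0–3.2 s in 40 ms steps), with a
cue 200 ms after hue onset on half the trials and per SOA 36 cued-stream
probes, 36 uncued-stream probes, and 72 cue-absent trials.

What passing tests on this observer do **not** show about real data:
real reports contain lapses, swaps, motor noise from the dial, and
serial dependencies that the generator deliberately omits; the mixture
model downstream likewise has no guess component, so the recovery
results characterize the estimator under its own assumptions.

## Pairing the two reports

With two targets (Ta, Tb) and two ordered reports (R1, R2) there are two
possible assignments. The primary rule pairs R1 with the target at the
smaller circular distance and R2 with the remaining target; the control
rule picks the assignment containing the overall smallest of the four
distances. Exact distance ties (possible on rounded data, measure-zero
on continuous data) are broken deterministically toward Ta. Errors are
stored signed, response minus target, in (−180°, 180°]; the mixture
consumes signed errors while the half-normal time-course estimator
consumes absolute errors.

## The constrained mixture and its EM fit

The mixture has density `½·VM(μ₁, κ₁) + ½·VM(μ₂, κ₂)` with both means
box-constrained to ±10° (allowing small response biases only) and the
weights fixed exactly at ½, since half of the pooled errors belong to
each stream by design. Precision is reported as `sqrt(1/κ)`. Because κ
is defined for radian-scaled angles, the fit runs on radians and
converts SDs to degrees (×180/π); the ratio of the two SDs is invariant
to this unit choice, so ratio-based conclusions do not depend on it.

Numerical choices:

* **E/M steps.** Responsibilities from the current components; means
  updated by the weighted circular mean, clipped to the box constraint;
  concentrations by inverting the mean-resultant-length relation
  A₁(κ) = R with the Best–Fisher piecewise approximation refined by
  Newton steps on the exponentially scaled Bessel ratio.
* **Initialization and restarts.** Moment estimates of κ from the
  small-|error| and large-|error| halves of the sample seed the first
  start; `n_restarts = 10` total, the rest with jittered concentrations
  and uniform means in the box, keeping the best final log-likelihood.
* **Bounds and stopping.** κ clamped to [10⁻³, 10⁴]; convergence when
  the log-likelihood improves by less than 10⁻⁶ nats (monotonicity is
  asserted in the tests); at most 500 iterations. An all-identical
  input is flagged as degenerate and returns the capped κ.

The fitted pair is always reported ordered (`sd_precise ≤
sd_imprecise`), which is also why the fitted ratio is biased upward when
the true components are equal: ordering plus sampling noise guarantees
ratio ≥ 1. This bias is *measured*, not assumed, by
`equal_deviation_ratio_null()`, which draws datasets from a single von
Mises, refits the mixture, and reports the median ratio and the tail
beyond a reference ratio. The default representative SD is 15° with a
documented sweep over 10–25°, since the per-subject means this null
would ideally use are dataset-specific.

## Monte-Carlo validation of a fitted pair

`monte_carlo_null()` rebuilds the estimation pipeline under the
hypothesis that the fitted pair is the truth: responses are re-drawn
around the subject's actual targets, double-report designs are routed
back through the pairing rule (the default, mirroring what is applied
to real data; a flag disables re-pairing), single-report designs draw
exactly half the trials from each precision distribution, and the
mixture is refitted each time. The resulting cloud of pairs is
summarized by a 4-parameter Gaussian — two means and two axis SDs, no
covariance term. The position of the observed pair is converted to a p
value by the axis-standardized squared radius referred to a chi-square
distribution with 2 degrees of freedom; because the Gaussian has no
covariance parameter this mapping is the natural "position within the
null" measure, and the empirical tail proportion of the simulated cloud
is reported alongside for transparency. The package's calibration test
confirms that pairs generated from the null process yield uniform p
values under this mapping.

The permutation consistency test sums per-subject Euclidean distances
between precision pairs of two conditions and compares the sum against
random permutations of the subject assignment; the identity permutation
is included in the null count (add-one rule) so p can never be exactly
zero. Regression through the origin (`y = a·x`, `a = Σxy/Σx²`, F on
(1, n−1) df) quantifies the across-subject precision relation without an
intercept term.

## Precision time-courses and spectral phase analysis

For SOA designs the probed stream is unambiguous, so no mixture is
needed: per subject × condition × SOA cell, precision is the
maximum-likelihood half-normal scale of the absolute errors,
`sqrt(mean(e²))`, which ignores small clockwise/counter-clockwise
biases. Each subject's cells are then z-normalized (mean 0, SD 1 across
all of that subject's cells) to remove large overall performance
differences; the spectral step operates on the z-normalized series, as
normalization is part of the pipeline immediately preceding it.

Each six-point time-course is mean-removed, zero-padded to 16 points,
and discrete-Fourier-transformed, putting bin k at k/(16·dt) Hz. The
choice of 16 is deliberate: with SOA spacings of 0.2, 0.1, and 0.04 s
the resulting bins land exactly on 0.9375/1.25 Hz, 3.75 Hz, and
4.6875 Hz — the frequencies at which results in this paradigm are
conventionally reported — and it is exposed as `pad_to` for users who
prefer another estimator. Mean removal prevents DC leakage into the
lowest bins of such a short padded series. The SOA spacing is snapped
to 10 decimal digits before use so that the frequency axis is exact
even when the grid was built by floating-point increments.

Phase differences (cued minus uncued, wrapped to (−180°, 180°]) are
combined across subjects by the phase-locking value (modulus of the mean
unit phasor). The peak bin is selected by maximal PLV within the
resolvable band, which defaults to [1/(n·dt), 1/(2·dt)] — from the
period of the sampled window up to the Nyquist frequency. At the peak
bin, v-tests (modified Rayleigh tests with specified direction,
`V = n·R·cos(m − θ₀)`, normal approximation `u = V·√(2/n)`, one-sided)
are run against 0° (in-phase) and 180° (antiphase). Phase locking is
computed across subjects, not across within-subject data splits, since
one phase difference per subject per bin is what the six-point design
supports.

## Reproducibility and problem sizes

Every stochastic function takes an optional integer `seed` and leaves
the caller's RNG state untouched; `run_pipeline()` derives per-stage
seeds from a single top-level seed so sub-analyses are independently
reproducible, and writes all outputs as delimited text with
17-significant-digit numerics so files round-trip exactly.

The packaged test-scale runs use: 1000 simulations of 300 errors for the
equal-deviation null (with a 200-simulation sweep at other SDs), 200
seeds of 150 double-report trials for parameter recovery, 20 replications
of a 15-subject × 864-trial SOA experiment for the end-to-end alternation
analysis, and 500 replications for the p-value calibrations. These sizes
were chosen to make medians and calibration tests stable at desk scale
while keeping a full run in the minutes range.

## Known limitations

* The observer and the mixture share the same error family; recovery
  results certify the estimator under its own assumptions, not
  robustness to guessing, swapping, or non-von-Mises noise.
* The equal-deviation null's representative SD is a global stand-in for
  unavailable per-subject precisions; its median bias varies mildly over
  the 10–25° sweep.
* The 4-parameter Gaussian null ignores the (mild, measured) correlation
  between the two fitted SDs; the empirical tail p is reported for
  cases where this matters.
* The alternation band and peak-bin selection assume equally spaced SOA
  grids; unequal grids are rejected rather than resampled.
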