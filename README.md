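# huetrack

Simulation and analysis of report precision when human observers track two
continuously changing color streams at once.

## The problem

In continuous feature-value tracking experiments, two superimposed dot
clouds change hue independently along random trajectories on an
iso-luminant hue circle. After several seconds of tracking, observers dial
in the last perceived hue of one or both streams on a color wheel. The
scientific question is how a limited attentional resource is shared between
the two streams: is report precision balanced, imbalanced at a stable
ratio, or alternating between streams over time?

`huetrack` is aimed at researchers in visual psychophysics who want a
tested, reusable implementation of this analysis pipeline — for planning
such experiments through simulation, validating the estimator's biases, or
re-analyzing trial tables of targets and responses.

## What the package computes

The core model decomposes the pooled signed report errors
`e = R − T ∈ (−180°, 180°]` of one subject into a constrained two-component
von Mises mixture,

    f(e) = ½ · VM(e; μ₁, κ₁) + ½ · VM(e; μ₂, κ₂),   |μⱼ| ≤ 10°,

fitted by expectation maximization with the weights fixed at exactly ½
(each stream contributes half of the reports). Tracking precision per
stream is summarized as `sd = sqrt(1/κ)` (converted from radians to
degrees), giving an ordered precision pair (high, low) and their ratio —
the quantity of interest for resource allocation.

Around that core the package provides:

* **Stimuli** — paired constrained random-walk hue trajectories
  (1°/frame, random direction reversals, a minimum 60° inter-stream
  distance at every frame), hue-to-CIELUV color mapping, and stimulus
  audit statistics.
* **Synthetic observer** — trial-table simulation with stream-specific
  von Mises error under fixed or time-alternating resource allocation,
  standing in for behavioral data.
* **Pairing** — resolution of the two-report/two-target ambiguity of
  double-report trials by the order-based minimum-distance rule, with the
  order-free global rule as a control.
* **Validation** — Monte-Carlo null distributions of the fitted precision
  pair (4-parameter bivariate Gaussian summary, chi-square position
  p-value), the equal-deviation simulation quantifying the fitted ratio's
  upward bias, a 10,000-permutation Euclidean-distance consistency test
  across conditions, zero-intercept regression, and KS uniformity checks.
* **Time-courses** — per-SOA half-normal precision estimation, per-subject
  z-normalization, zero-padded Fourier phase differences between cued and
  uncued streams, phase-locking values, and v-tests against 0°/180°.

## Worked example

Simulate one subject who tracks one stream at 8° and the other at 16°
error SD, resolve the report pairing, fit the constrained mixture, and
validate the estimate against its Monte-Carlo null:

```r
library(huetrack)

pool    <- generate_trajectory_pool(40, seed = 1)
pairs   <- make_trajectory_pairs(pool, 60, min_dist = 60, seed = 2)
model   <- observer_model(sd_high = 8, sd_low = 16)
design  <- experiment_design("exp1", n_trials = 150)
records <- simulate_experiment(model, design, pairs, seed = 3)

errors <- compute_errors(records, strategy = "first_min")
fit    <- fit_constrained_mixture(errors$error, seed = 4)
fit
#> <vm_mixture_fit> n=300, loglik=15.708, converged in 38 iterations
#>   precise:   mu=+2.70 deg, kappa=41.367, sd=8.908 deg
#>   imprecise: mu=-1.23 deg, kappa=12.963, sd=15.913 deg
#>   ratio sd_imprecise/sd_precise = 1.786
```

The 300 pooled errors (2 per trial) split into a precise component near
8.9° and an imprecise one near 15.9° — close to the generating 8°/16°
observer, with a fitted ratio of 1.79 against the true 2.0. The
Monte-Carlo check then asks whether an observer who truly responds with
these two SDs would yield such an estimate:

```r
null <- monte_carlo_null(records[, c("target_a", "target_b")], fit$precision,
                         n_sim = 200, design = "exp1", seed = 5)
null_p_value(fit$precision, null)$p
#> [1] 0.966
```

A p near 1 means the observed pair sits in the center of its own null
cloud: the estimate is consistent with two independent precision
distributions. Finally, an observer whose resource alternates between
streams at 1 Hz (phase-reset by a cue) is recovered by the time-course
pipeline on the 200-ms SOA grid:

```r
mod3 <- observer_model(8, 16, allocation = "alternating", alternation_freq = 1)
rec3 <- simulate_subjects(mod3, experiment_design("exp3a"), pairs,
                          n_subjects = 15, seed = 6)
alternation_analysis(build_timecourses(rec3))
#> <alternation_result> peak PLV 0.971 at 0.9375 Hz (band 0.833-2.500 Hz)
#>   v-test vs   0 deg: v(14) = -14.57, p = 1.0000, m = 179.29 deg
#>   v-test vs 180 deg: v(14) = 14.57, p = 0.0000, m = 179.29 deg
```

The phase difference between the cued- and uncued-stream precision
time-courses locks near 180° at the ~1 Hz bins: the streams are tracked in
antiphase.

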