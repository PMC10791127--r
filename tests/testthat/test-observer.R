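test_that("experiment simulation is deterministic given a seed", {
  mod <- observer_model(8, 16)
  des <- experiment_design("exp1", n_trials = 40)
  a <- simulate_experiment(mod, des, test_pairs(20), seed = 31)
  b <- simulate_experiment(mod, des, test_pairs(20), seed = 31)
  expect_identical(a, b)
  expect_error(simulate_experiment(mod, des, list(), seed = 31), "non-empty")
})

test_that("trial records satisfy their structural invariants", {
  mod <- observer_model(8, 16)
  r1 <- simulate_experiment(mod, experiment_design("exp1", n_trials = 50),
                            test_pairs(20), seed = 32)
  expect_true(all(circular_distance(r1$target_a, r1$target_b) >= 60))
  expect_true(all(!is.na(r1$response_2)))
  expect_true(all(r1$probed_stream == "both"))
  expect_true(all(r1$probe_time_s >= 6 & r1$probe_time_s <= 8))

  r2 <- simulate_experiment(mod, experiment_design("exp2", n_trials = 50),
                            test_pairs(20), seed = 33)
  expect_true(all(is.na(r2$response_2)))
  expect_true(all(r2$probed_stream %in% c("a", "b")))
})

test_that("equal resource allocation collapses to a single error population", {
  mod <- observer_model(12, 12)
  rec <- simulate_experiment(mod, experiment_design("exp2", n_trials = 800),
                             test_pairs(30), seed = 34)
  err <- compute_errors(rec)$error
  expect_lt(abs(sd(err) - 12), 1.2)
})

test_that("a near-perfect high-precision resource shows up in half the single reports", {
  mod <- observer_model(0.1, 20)
  rec <- simulate_experiment(mod, experiment_design("exp2", n_trials = 600),
                             test_pairs(30), seed = 35)
  err <- compute_errors(rec)$error
  frac_tiny <- mean(abs(err) < 1)
  expect_gt(frac_tiny, 0.38)
  expect_lt(frac_tiny, 0.62)
})

test_that("alternating allocation follows the sign of the cosine phase function", {
  mod <- observer_model(8, 16, allocation = "alternating", alternation_freq = 1,
                        alternation_phase = 0, cue_resets_phase = TRUE)
  des <- experiment_design("exp3a")
  rec <- simulate_experiment(mod, des, test_pairs(30), seed = 36)
  cued <- rec[rec$cue_present, ]
  # independent oracle: cued stream favored iff cos(2*pi*f*(t - t_cue)) > 0
  want <- ifelse(cos(2 * pi * 1 * (cued$soa - 0.2)) > 0,
                 cued$cued_stream,
                 ifelse(cued$cued_stream == "a", "b", "a"))
  expect_identical(cued$favored_stream, want)
  expect_setequal(unique(rec$soa), seq(3, 4, by = 0.2))
})

test_that("favored-stream errors pass a von Mises fit at the configured SDs", {
  mod <- observer_model(8, 16)
  rec <- simulate_experiment(mod, experiment_design("exp2", n_trials = 1200),
                             test_pairs(30), seed = 37)
  err <- compute_errors(rec)
  favored <- rec$favored_stream[match(err$trial_id, rec$trial_id)]
  fav <- err$error[err$assigned_target == favored]
  oth <- err$error[err$assigned_target != favored]
  # moment-based concentration estimate, independent of the EM path
  sd_fav <- vm_sd_from_kappa(huetrack:::a1_inv(mean(cos(fav * pi / 180))))
  sd_oth <- vm_sd_from_kappa(huetrack:::a1_inv(mean(cos(oth * pi / 180))))
  expect_lt(abs(sd_fav - 8), 0.8)
  expect_lt(abs(sd_oth - 16), 1.6)
})

test_that("uniformity checks flag degenerate target sets and accept uniform ones", {
  res <- withr::with_seed(38, {
    u <- data.frame(target_a = runif(200, 0, 360))
    u$target_b <- wrap_positive(u$target_a + runif(200, 60, 180))
    targets_uniformity_check(u)
  })
  expect_named(res, c("check", "D", "p", "n"))

  same <- data.frame(target_a = rep(100, 50), target_b = rep(200, 50))
  res_same <- targets_uniformity_check(same)
  expect_lt(res_same$p[res_same$check == "target_a"], 1e-6)

  clamped <- data.frame(target_a = runif(50, 0, 360))
  clamped$target_b <- wrap_positive(clamped$target_a + 60)
  res_cl <- targets_uniformity_check(clamped)
  expect_lt(res_cl$p[res_cl$check == "distance"], 1e-6)

  expect_error(targets_uniformity_check(same[1:10, ]), "at least 20")
})

test_that("uniformity p-values are calibrated under truly uniform targets", {
  ps <- withr::with_seed(39, replicate(400, {
    u <- data.frame(target_a = runif(60, 0, 360))
    u$target_b <- wrap_positive(u$target_a + runif(60, 60, 180))
    targets_uniformity_check(u)$p[1]
  }))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})
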