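test_that("half-normal scale estimation has its closed form and matches a numeric MLE", {
  expect_equal(fit_halfnormal_sd(rep(7, 20)), 7)
  x <- withr::with_seed(71, abs(rnorm(10000, 0, 12)))
  expect_lt(abs(fit_halfnormal_sd(x) - 12), 0.5)

  # generic numeric maximum-likelihood oracle for the half-normal scale
  nll <- function(s) -sum(log(2) + dnorm(x, 0, s, log = TRUE))
  opt <- optimize(nll, c(1, 50), tol = 1e-10)
  expect_lt(abs(fit_halfnormal_sd(x) - opt$minimum), 1e-4)

  expect_error(fit_halfnormal_sd(numeric(0)), "empty")
  expect_error(fit_halfnormal_sd(c(3, 200)), "180")
})

test_that("z-normalization standardizes each subject and ignores location/scale", {
  v <- array(0, c(2, 3, 6), dimnames = list(subject = 1:2,
                                            condition = c("cue_absent", "cued_stream", "uncued_stream"),
                                            soa = seq(3, 4, 0.2)))
  v[1, , ] <- matrix(1:18, 3, 6)
  v[2, , ] <- matrix(rnorm(18, 50, 5), 3, 6)
  tc <- structure(list(values = v, cell_counts = v * 0 + 10,
                       soa_grid = seq(3, 4, 0.2),
                       conditions = dimnames(v)$condition, normalized = FALSE),
                  class = "timecourse_matrix")
  z <- znormalize_subject(tc)
  for (s in 1:2) {
    expect_equal(mean(z$values[s, , ]), 0, tolerance = 1e-12)
    expect_equal(sd(as.numeric(z$values[s, , ])), 1, tolerance = 1e-12)
  }
  shifted <- tc
  shifted$values[1, , ] <- shifted$values[1, , ] + 100
  scaled <- tc
  scaled$values[2, , ] <- scaled$values[2, , ] * 3.7
  expect_equal(znormalize_subject(shifted)$values, z$values)
  expect_equal(znormalize_subject(scaled)$values, z$values)

  flat <- tc
  flat$values[1, , ] <- 5
  expect_error(znormalize_subject(flat), "degenerate subject")
  expect_error(znormalize_subject(z), "already normalized")
})

test_that("the zero-padded frequency axis contains the resolvable peak frequencies", {
  a <- rnorm(6); b <- rnorm(6)
  f200 <- spectral_phase(a, b, dt = 0.2, pad_to = 16)$freq
  expect_true(all(c(0.9375, 1.25) %in% f200))
  f100 <- spectral_phase(a, b, dt = 0.1, pad_to = 16)$freq
  expect_true(3.75 %in% f100)
  f40 <- spectral_phase(a, b, dt = 0.04, pad_to = 16)$freq
  expect_true(4.6875 %in% f40)
  expect_equal(f200, (1:8) / (16 * 0.2))
})

test_that("identical series have zero phase difference wherever there is power", {
  x <- withr::with_seed(72, rnorm(6))
  sp <- spectral_phase(x, x, dt = 0.2)
  nz <- sp$amp_a > 1e-9
  expect_true(all(abs(sp$phase_diff[nz]) < 1e-9))
  expect_error(spectral_phase(x, x, dt = -1), "dt")
  expect_error(spectral_phase(x, rnorm(5), dt = 0.2), "equal length")
})

test_that("phase-locking value matches brute-force trigonometry and its extremes", {
  expect_equal(plv_across_subjects(rep(37, 15)), 1)
  expect_lt(plv_across_subjects(seq(0, 360, length.out = 13)[-13]), 1e-12)
  set.seed(73)
  for (i in 1:100) {
    ph <- runif(sample(3:20, 1), -180, 180)
    expect_lt(abs(plv_across_subjects(ph) - bf_plv(ph)), 1e-10)
  }
})

test_that("plv of uniform phases follows the Rayleigh null from direct simulation", {
  set.seed(74)
  pkg <- replicate(2000, plv_across_subjects(runif(15, -180, 180)))
  ref <- replicate(2000, bf_plv(runif(15, 0, 360)))
  expect_gt(suppressWarnings(ks.test(pkg, ref))$p.value, 0.01)
})

test_that("v-test matches brute force and its degenerate cases", {
  conc <- v_test(rep(90, 15), 90)
  expect_equal(conc$V, 15)
  expect_equal(conc$R, 1)
  expect_lt(conc$p, 1e-7)

  sym <- v_test(c(rep(130, 5), rep(50, 5)), 0)  # symmetric about 90
  expect_lt(abs(sym$V), 1e-9)
  expect_equal(sym$p, 0.5, tolerance = 1e-9)

  set.seed(75)
  for (i in 1:100) {
    ang <- runif(sample(5:20, 1), -180, 180)
    th0 <- runif(1, 0, 360)
    got <- v_test(ang, th0)
    want <- bf_v_test(ang, th0)
    expect_lt(abs(got$V - want$V), 1e-10)
    expect_lt(abs(got$p - want$p), 1e-10)
  }
  expect_error(v_test(1:3, 0), "at least 5")
})

test_that("time-course construction reproduces the design cell counts and flags empty cells", {
  mod <- observer_model(8, 16, allocation = "alternating", alternation_freq = 1)
  rec <- simulate_subjects(mod, experiment_design("exp3a"), test_pairs(30),
                           n_subjects = 2, seed = 76)
  tc <- build_timecourses(rec)
  expect_true(tc$normalized)
  expect_equal(dim(tc$values), c(2, 3, 6))
  expect_true(all(tc$cell_counts[, "cue_absent", ] == 72))
  expect_true(all(tc$cell_counts[, c("cued_stream", "uncued_stream"), ] == 36))

  broken <- rec[!(rec$subject == 1 & rec$soa == 3.2 & rec$cue_present &
                    rec$probed_stream == rec$cued_stream), ]
  expect_error(build_timecourses(broken), "empty cell: subject 1, condition cued_stream, SOA 3.2")
})

test_that("an antiphase alternating observer is recovered end to end", {
  mod <- observer_model(8, 16, allocation = "alternating", alternation_freq = 1)
  des <- experiment_design("exp3a")
  peak_ok <- logical(5); p_ok <- logical(5); angle_ok <- logical(5)
  for (i in 1:5) {
    rec <- simulate_subjects(mod, des, test_pairs(30), n_subjects = 15, seed = 120 + i)
    alt <- alternation_analysis(build_timecourses(rec))
    peak_ok[i] <- alt$peak_freq %in% c(0.9375, 1.25)
    p_ok[i] <- alt$v180$p < 0.05
    angle_ok[i] <- abs(circular_difference(alt$v180$mean_angle, 180)) < 45
  }
  # the peak may wander to a neighboring bin on a given seed; the majority
  # of seeds must land on the ~1 Hz bins, and antiphase must always show
  expect_gte(sum(peak_ok), 3)
  expect_true(all(p_ok))
  expect_true(all(angle_ok))
})
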