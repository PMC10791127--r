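test_that("regression through the origin matches its closed form and the linear-model oracle", {
  x <- c(1, 2, 3, 4.5)
  exact <- regression_through_origin(x, 2 * x)
  expect_equal(exact$slope, 2)
  expect_equal(exact$F, Inf)

  set.seed(61)
  for (i in 1:100) {
    n <- sample(5:30, 1)
    x <- runif(n, 0.5, 30)
    y <- 1.7 * x + rnorm(n, 0, 3)
    got <- regression_through_origin(x, y)
    fit <- lm(y ~ 0 + x)
    expect_lt(abs(got$slope - coef(fit)[["x"]]), 1e-10)
    fs <- summary(fit)$fstatistic
    expect_lt(abs(got$F - fs[["value"]]), 1e-7 * got$F)
    expect_equal(got$df, c(1, n - 1))
  }
  expect_error(regression_through_origin(c(0, 0, 0), 1:3), "zero")
  expect_error(regression_through_origin(1:2, 1:2), "at least 3")
})

test_that("circular KS uniformity test behaves at its extremes", {
  equi <- seq(0.5, 359.5, length.out = 100)
  expect_gt(ks_uniform_circular(equi)$p, 0.99)
  expect_lt(ks_uniform_circular(rep(123, 50))$p, 1e-10)
  expect_error(ks_uniform_circular(1:5), "at least 10")
})

test_that("permutation consistency finds identical pairs maximally consistent", {
  set.seed(62)
  X <- cbind(runif(10, 5, 15), runif(10, 10, 30))
  res <- permutation_consistency(X, X, n_perm = 999)
  expect_equal(res$sum_distance, 0)
  expect_lte(res$p, 5 / 1000)

  # invariant under joint relabeling of subjects
  perm <- sample(10)
  res2 <- permutation_consistency(X[perm, ], X[perm, ], n_perm = 99)
  expect_equal(res2$sum_distance, 0)

  expect_error(permutation_consistency(X[1:4, ], X[1:4, ], 99), "at least 5")
  expect_error(permutation_consistency(X, X[1:9, ], 99), "equal subject")
})

test_that("Monte-Carlo permutation p matches the exhaustive null at n = 5", {
  set.seed(63)
  X <- cbind(runif(5, 5, 15), runif(5, 10, 30))
  Y <- X + matrix(rnorm(10, 0, 3), 5, 2)
  D <- sqrt(outer(X[, 1], Y[, 1], "-")^2 + outer(X[, 2], Y[, 2], "-")^2)
  obs <- sum(diag(D))
  perms <- as.matrix(expand.grid(rep(list(1:5), 5)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 5), , drop = FALSE]
  sums <- apply(perms, 1, function(p) sum(D[cbind(1:5, p)]))
  p_exact <- mean(sums <= obs)
  res <- permutation_consistency(X, Y, n_perm = 20000, seed = 64)
  expect_lt(abs(res$p - p_exact), 0.02)
})

test_that("the chi-square position measure has its closed-form values", {
  null <- structure(list(
    samples = data.frame(sd_precise = rnorm(200, 10, 1.5),
                         sd_imprecise = rnorm(200, 18, 2)),
    mean_precise = 10, mean_imprecise = 18,
    sd_precise_axis = 1.5, sd_imprecise_axis = 2,
    n_sim = 200, design = "exp2"), class = "mc_null")
  at_mean <- null_p_value(c(10, 18), null)
  expect_equal(at_mean$p, 1)
  out3 <- null_p_value(c(10 + 3 * 1.5, 18 + 3 * 2), null)
  expect_equal(out3$p, exp(-9), tolerance = 1e-12)
  bad <- null
  bad$sd_precise_axis <- 0
  expect_error(null_p_value(c(10, 18), bad), "degenerate")
})

test_that("parametric and empirical tail probabilities of the simulated cloud agree", {
  tg <- withr::with_seed(65, runif(80, 0, 360))
  null <- monte_carlo_null(tg, c(9, 17), n_sim = 120, design = "exp2",
                           n_restarts = 3, seed = 66)
  obs <- c(null$mean_precise + null$sd_precise_axis,
           null$mean_imprecise - null$sd_imprecise_axis)
  res <- null_p_value(obs, null)
  expect_lt(abs(res$p - res$p_empirical), 4 * sqrt(res$p * (1 - res$p) / 120) + 0.02)
})

test_that("Monte-Carlo null generation is seeded and warns on tiny simulation counts", {
  tg <- cbind(runif(30, 0, 360), runif(30, 0, 360))
  tg[, 2] <- wrap_positive(tg[, 1] + runif(30, 60, 300))
  a <- suppressWarnings(monte_carlo_null(tg, c(8, 16), n_sim = 20, design = "exp1",
                                         n_restarts = 2, seed = 67))
  b <- suppressWarnings(monte_carlo_null(tg, c(8, 16), n_sim = 20, design = "exp1",
                                         n_restarts = 2, seed = 67))
  expect_identical(a$samples, b$samples)
  expect_warning(monte_carlo_null(tg, c(8, 16), n_sim = 20, design = "exp1",
                                  n_restarts = 2, seed = 67), "n_sim")
})

test_that("the equal-deviation ratio bias shrinks with sample size and never drops below 1", {
  r100 <- equal_deviation_ratio_null(sd = 15, n_errors = 100, n_sim = 40,
                                     n_restarts = 4, seed = 68)
  r1000 <- equal_deviation_ratio_null(sd = 15, n_errors = 1000, n_sim = 40,
                                      n_restarts = 4, seed = 69)
  expect_true(all(r100$ratios >= 1))
  expect_gte(r100$median_ratio, 1)
  expect_lt(r1000$median_ratio, r100$median_ratio)
})
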