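#' Monte-Carlo null distribution of a precision pair
#'
#' Simulates the full estimation pipeline under the hypothesis that
#' responses really are drawn from two independent von Mises precision
#' distributions with the fitted SDs: for each simulation, synthetic
#' responses are attached to the subject's actual targets, errors are
#' extracted exactly as for real data (double-report designs are routed
#' through the pairing rule), the constrained mixture is refitted, and the
#' resulting precision pair is recorded. The cloud of simulated pairs is
#' then summarized by a 4-parameter bivariate Gaussian (two means, two
#' axis SDs, no covariance term).
#'
#' @param targets For `design = "exp1"`: a two-column matrix or data frame
#'   of per-trial target hues (degrees). For `design = "exp2"`: a vector
#'   of per-trial probed target hues (one report per trial).
#' @param sd_pair A [precision_pair()] (or length-2 numeric of SDs in
#'   degrees) taken as ground truth.
#' @param n_sim Number of simulated response distributions.
#' @param design `"exp1"` (two reports per trial) or `"exp2"` (one report
#'   per trial; exactly half the trials draw from each precision
#'   distribution).
#' @param re_pair For exp1: route simulated response pairs through the
#'   order-based pairing rule before refitting (mirrors the pipeline
#'   applied to real data). If `FALSE`, the generating assignment is used
#'   directly.
#' @param n_restarts EM restarts used for the refits.
#' @param mu_bound Mean constraint passed to the mixture fit.
#' @param seed Optional integer seed.
#' @return Object of class `mc_null`: the simulated `samples` (data frame
#'   with `sd_precise`, `sd_imprecise`), Gaussian summary (`mean_precise`,
#'   `mean_imprecise`, `sd_precise_axis`, `sd_imprecise_axis`), `n_sim`,
#'   and `design`.
#' @export
monte_carlo_null <- function(targets, sd_pair, n_sim = 1000,
                             design = c("exp1", "exp2"),
                             re_pair = TRUE, n_restarts = 5, mu_bound = 10,
                             seed = NULL) {
  design <- match.arg(design)
  if (!is.null(seed)) {
    return(withr::with_seed(
      seed,
      monte_carlo_null(targets, sd_pair, n_sim, design, re_pair, n_restarts, mu_bound)
    ))
  }
  sds <- as_sd_pair(sd_pair)
  if (n_sim < 100) {
    warning("n_sim < 100 gives an unstable null distribution", call. = FALSE)
  }
  k_hi <- vm_kappa_from_sd(sds[1])
  k_lo <- vm_kappa_from_sd(sds[2])

  sims <- matrix(NA_real_, n_sim, 2)
  for (s in seq_len(n_sim)) {
    err <- simulate_null_errors(targets, k_hi, k_lo, design, re_pair)
    fit <- fit_constrained_mixture(err, mu_bound = mu_bound, n_restarts = n_restarts)
    sims[s, ] <- c(fit$precision$sd_precise, fit$precision$sd_imprecise)
  }
  samples <- data.frame(sd_precise = sims[, 1], sd_imprecise = sims[, 2])
  structure(
    list(samples = samples,
         mean_precise = mean(samples$sd_precise),
         mean_imprecise = mean(samples$sd_imprecise),
         sd_precise_axis = stats::sd(samples$sd_precise),
         sd_imprecise_axis = stats::sd(samples$sd_imprecise),
         n_sim = n_sim, design = design),
    class = "mc_null"
  )
}

simulate_null_errors <- function(targets, k_hi, k_lo, design, re_pair) {
  if (design == "exp1") {
    tg <- as.matrix(targets)
    stopifnot(ncol(tg) == 2)
    n <- nrow(tg)
    hi_is_a <- stats::runif(n) < 0.5
    e_hi <- rvonmises(n, 0, k_hi)
    e_lo <- rvonmises(n, 0, k_lo)
    if (!re_pair) return(c(e_hi, e_lo))
    err_a <- ifelse(hi_is_a, e_hi, e_lo)
    err_b <- ifelse(hi_is_a, e_lo, e_hi)
    rep_a <- wrap_positive(tg[, 1] + err_a)
    rep_b <- wrap_positive(tg[, 2] + err_b)
    a_first <- stats::runif(n) < 0.5
    rec <- data.frame(trial_id = seq_len(n), probed_stream = "both",
                      target_a = tg[, 1], target_b = tg[, 2],
                      response_1 = ifelse(a_first, rep_a, rep_b),
                      response_2 = ifelse(a_first, rep_b, rep_a))
    compute_errors(rec, "first_min")$error
  } else {
    n <- length(targets)
    n_hi <- floor(n / 2)
    c(rvonmises(n_hi, 0, k_hi), rvonmises(n - n_hi, 0, k_lo))
  }
}

as_sd_pair <- function(sd_pair) {
  if (inherits(sd_pair, "precision_pair")) {
    c(sd_pair$sd_precise, sd_pair$sd_imprecise)
  } else {
    sort(as.numeric(sd_pair))
  }
}

#' @export
print.mc_null <- function(x, ...) {
  cat(sprintf("<mc_null> %s, %d simulations\n", x$design, x$n_sim))
  cat(sprintf("  precise axis:   %.3f deg (SD %.3f)\n", x$mean_precise, x$sd_precise_axis))
  cat(sprintf("  imprecise axis: %.3f deg (SD %.3f)\n", x$mean_imprecise, x$sd_imprecise_axis))
  invisible(x)
}

#' Position of an observed precision pair within a Monte-Carlo null
#'
#' Standardizes the observed pair on the two Gaussian axes and refers the
#' squared radius to its chi-square reference with 2 degrees of freedom
#' (the fitted Gaussian has no covariance term). The empirical tail
#' proportion of the simulated cloud is reported alongside.
#'
#' @param observed A [precision_pair()] or length-2 numeric (precise,
#'   imprecise SD in degrees).
#' @param null An `mc_null` from [monte_carlo_null()].
#' @return List with `p` (parametric, in (0, 1\]), `p_empirical`
#'   (add-one-corrected tail proportion of the simulated cloud), and
#'   `mahalanobis_sq`.
#' @export
null_p_value <- function(observed, null) {
  stopifnot(inherits(null, "mc_null"))
  obs <- as_sd_pair(observed)
  if (null$sd_precise_axis <= 0 || null$sd_imprecise_axis <= 0) {
    stop("degenerate null: zero axis SD", call. = FALSE)
  }
  q <- ((obs[1] - null$mean_precise) / null$sd_precise_axis)^2 +
    ((obs[2] - null$mean_imprecise) / null$sd_imprecise_axis)^2
  q_sim <- ((null$samples$sd_precise - null$mean_precise) / null$sd_precise_axis)^2 +
    ((null$samples$sd_imprecise - null$mean_imprecise) / null$sd_imprecise_axis)^2
  list(p = stats::pchisq(q, df = 2, lower.tail = FALSE),
       p_empirical = (1 + sum(q_sim >= q)) / (null$n_sim + 1),
       mahalanobis_sq = q)
}

#' Ratio bias of the constrained mixture under equal true deviations
#'
#' Simulates datasets in which every error shares one common SD (so the
#' true precision ratio is 1), refits the constrained two-component
#' mixture, and collects the distribution of estimated
#' high/low-precision-SD ratios. This quantifies the upward bias of the
#' fitted ratio under the null of perfectly balanced resources.
#'
#' @param sd Common true SD, degrees.
#' @param n_errors Errors per simulated dataset.
#' @param n_sim Number of simulated datasets.
#' @param reference_ratio Reference value; the fraction of fitted ratios
#'   strictly exceeding it is reported.
#' @param n_restarts,mu_bound Passed to [fit_constrained_mixture()].
#' @param seed Optional integer seed.
#' @return Object of class `ratio_null`: `ratios`, `median_ratio`,
#'   `frac_exceeding`, plus the simulation settings.
#' @export
equal_deviation_ratio_null <- function(sd = 15, n_errors = 300, n_sim = 1000,
                                       reference_ratio = 1.928,
                                       n_restarts = 10, mu_bound = 10,
                                       seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(
      seed,
      equal_deviation_ratio_null(sd, n_errors, n_sim, reference_ratio,
                                 n_restarts, mu_bound)
    ))
  }
  stopifnot(sd > 0, n_errors >= 20, n_sim >= 1)
  kappa <- vm_kappa_from_sd(sd)
  ratios <- numeric(n_sim)
  for (s in seq_len(n_sim)) {
    err <- rvonmises(n_errors, 0, kappa)
    fit <- fit_constrained_mixture(err, mu_bound = mu_bound, n_restarts = n_restarts)
    ratios[s] <- fit$precision$ratio
  }
  structure(
    list(ratios = ratios,
         median_ratio = stats::median(ratios),
         frac_exceeding = mean(ratios > reference_ratio),
         reference_ratio = reference_ratio,
         sd = sd, n_errors = n_errors, n_sim = n_sim),
    class = "ratio_null"
  )
}

#' @export
print.ratio_null <- function(x, ...) {
  cat(sprintf("<ratio_null> sd=%g deg, %d x %d errors\n", x$sd, x$n_sim, x$n_errors))
  cat(sprintf("  median ratio = %.3f; %.1f%% of ratios > %.3f\n",
              x$median_ratio, 100 * x$frac_exceeding, x$reference_ratio))
  invisible(x)
}

#' Permutation test of cross-condition consistency of precision pairs
#'
#' The observed statistic is the sum over subjects of the Euclidean
#' distance between a subject's precision pair in condition x and in
#' condition y. The null is built by permuting the subject assignment of
#' the y pairs; small p means the pairs are more consistent within
#' subjects than between. Following the add-one rule, the identity
#' permutation is included in the null count, so the smallest attainable p
#' is 1/(n_perm + 1).
#'
#' @param pairs_x,pairs_y Per-subject precision pairs in matched order: a
#'   two-column matrix/data frame (precise, imprecise) or a list of
#'   [precision_pair()] objects.
#' @param n_perm Number of random permutations.
#' @param seed Optional integer seed.
#' @return List with `sum_distance`, `p`, `n_subjects`, `n_perm`, and the
#'   permuted sums `perm_sums`.
#' @export
permutation_consistency <- function(pairs_x, pairs_y, n_perm = 10000, seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, permutation_consistency(pairs_x, pairs_y, n_perm)))
  }
  X <- as_pair_matrix(pairs_x)
  Y <- as_pair_matrix(pairs_y)
  n <- nrow(X)
  if (nrow(Y) != n) stop("pairs_x and pairs_y must have equal subject counts", call. = FALSE)
  if (n < 5) stop("need at least 5 subjects", call. = FALSE)

  # D[i, j] = distance between subject i's x pair and subject j's y pair
  D <- sqrt(outer(X[, 1], Y[, 1], "-")^2 + outer(X[, 2], Y[, 2], "-")^2)
  obs <- sum(diag(D))
  perm_sums <- vapply(seq_len(n_perm), function(k) {
    p <- sample.int(n)
    sum(D[cbind(seq_len(n), p)])
  }, numeric(1))
  list(sum_distance = obs,
       p = (1 + sum(perm_sums <= obs)) / (n_perm + 1),
       n_subjects = n, n_perm = n_perm, perm_sums = perm_sums)
}

as_pair_matrix <- function(pairs) {
  if (is.list(pairs) && length(pairs) && inherits(pairs[[1]], "precision_pair")) {
    pairs <- t(vapply(pairs, function(p) c(p$sd_precise, p$sd_imprecise), numeric(2)))
  }
  m <- as.matrix(pairs)
  stopifnot(ncol(m) == 2)
  m
}

#' Linear regression through the origin
#'
#' Fits y = a * x with zero intercept: a = sum(xy) / sum(x^2), with the
#' F-test of the regression sum of squares against the residual on
#' (1, n - 1) degrees of freedom.
#'
#' @param x,y Numeric vectors (e.g. per-subject precision estimates).
#' @return List with `slope`, `F`, `p`, `df` (length 2), and `n`.
#' @export
regression_through_origin <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  if (all(x == 0)) stop("x must not be all zero", call. = FALSE)
  a <- sum(x * y) / sum(x^2)
  fitted <- a * x
  ssr <- sum(fitted^2)
  sse <- sum((y - fitted)^2)
  Fst <- if (sse == 0) Inf else ssr / (sse / (n - 1))
  list(slope = a, F = Fst,
       p = stats::pf(Fst, 1, n - 1, lower.tail = FALSE),
       df = c(1, n - 1), n = n)
}

#' Kolmogorov-Smirnov test of circular uniformity
#'
#' Tests angles (degrees) against the uniform distribution on the full
#' circle by referring angle/360 to uniform \[0, 1\] (asymptotic p).
#'
#' @param angles Angles in degrees (at least 10).
#' @return List with `D` and `p`.
#' @export
ks_uniform_circular <- function(angles) {
  if (length(angles) < 10) stop("need at least 10 angles", call. = FALSE)
  ks_unif01(wrap_positive(angles) / 360)
}
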