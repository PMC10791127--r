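#' Convert von Mises concentration to a precision SD in degrees
#'
#' The report precision of a stream is summarized as sqrt(1/kappa), the
#' large-concentration standard deviation of a von Mises distribution.
#' Kappa is defined on the radian scale, so sqrt(1/kappa) is a radian SD
#' and is converted to degrees here.
#'
#' @param kappa Concentration (> 0).
#' @return SD in degrees.
#' @export
vm_sd_from_kappa <- function(kappa) {
  if (any(kappa <= 0)) stop("kappa must be > 0", call. = FALSE)
  rad2deg(sqrt(1 / kappa))
}

#' @rdname vm_sd_from_kappa
#' @param sd_deg Precision SD in degrees.
#' @export
vm_kappa_from_sd <- function(sd_deg) {
  if (any(sd_deg <= 0)) stop("sd must be > 0", call. = FALSE)
  1 / deg2rad(sd_deg)^2
}

#' Ordered pair of precision estimates
#'
#' @param sd1,sd2 Two precision SDs in degrees (any order).
#' @return Object of class `precision_pair` with fields `sd_precise`
#'   (smaller SD), `sd_imprecise`, and `ratio = sd_imprecise / sd_precise`.
#' @export
precision_pair <- function(sd1, sd2) {
  lo <- min(sd1, sd2); hi <- max(sd1, sd2)
  structure(list(sd_precise = lo, sd_imprecise = hi, ratio = hi / lo),
            class = "precision_pair")
}

#' @export
print.precision_pair <- function(x, ...) {
  cat(sprintf("<precision_pair> sd_precise=%.3f deg, sd_imprecise=%.3f deg, ratio=%.3f\n",
              x$sd_precise, x$sd_imprecise, x$ratio))
  invisible(x)
}

#' Log-likelihood of an equal-weight two-component von Mises mixture
#'
#' @param errors Signed errors in degrees, |error| <= 180.
#' @param mu Length-2 vector of component means (degrees).
#' @param kappa Length-2 vector of concentrations.
#' @param weights Component weights (fixed at 0.5/0.5 in the constrained
#'   model).
#' @return Log-likelihood in nats (densities per radian).
#' @export
mixture_loglik <- function(errors, mu, kappa, weights = c(0.5, 0.5)) {
  stopifnot(length(mu) == 2, length(kappa) == 2, length(weights) == 2)
  f1 <- dvonmises(errors, mu[1], kappa[1])
  f2 <- dvonmises(errors, mu[2], kappa[2])
  sum(log(weights[1] * f1 + weights[2] * f2))
}

#' Fit the constrained two-component von Mises mixture by EM
#'
#' Fits the model used to decompose pooled signed report errors into a
#' high-precision and a low-precision component: a mixture of two von
#' Mises distributions with weights fixed at exactly 0.5 each and both
#' means constrained to lie within `mu_bound` degrees of zero (allowing
#' only small response biases). The E-step computes component
#' responsibilities; the M-step updates each mean by the weighted circular
#' mean clipped to the box constraint and each concentration by inverting
#' the mean-resultant-length relation A1(kappa) = R (Best-Fisher
#' approximation refined by Newton steps). The best of `n_restarts`
#' jittered starts by final log-likelihood is returned.
#'
#' @param errors Signed errors in degrees (at least 20, all |error| <=
#'   180).
#' @param mu_bound Box constraint on the component means, degrees.
#' @param n_restarts Number of jittered EM starts.
#' @param tol Convergence tolerance on the log-likelihood change, nats.
#' @param max_iter Maximum EM iterations per start.
#' @param seed Optional integer seed controlling the restart jitter.
#' @param kappa_range Concentrations are clamped to this range to avoid
#'   degenerate fits.
#' @return Object of class `vm_mixture_fit`: component parameters (`mu`,
#'   `kappa`, degrees / radian-scale concentration, ordered precise
#'   component first), `weights`, `loglik`, `loglik_path`, `n`, `n_iter`,
#'   `converged`, per-sample `responsibilities` (n x 2), and `precision`
#'   (a [precision_pair()]).
#' @export
fit_constrained_mixture <- function(errors, mu_bound = 10, n_restarts = 10,
                                    tol = 1e-6, max_iter = 500, seed = NULL,
                                    kappa_range = c(1e-3, 1e4)) {
  if (!is.null(seed)) {
    return(withr::with_seed(
      seed,
      fit_constrained_mixture(errors, mu_bound, n_restarts, tol, max_iter,
                              kappa_range = kappa_range)
    ))
  }
  errors <- as.numeric(errors)
  if (length(errors) < 20) stop("need at least 20 error samples", call. = FALSE)
  if (any(!is.finite(errors)) || any(abs(errors) > 180)) {
    stop("errors must be finite signed degrees with |error| <= 180", call. = FALSE)
  }
  if (max(abs(wrap_signed(errors - errors[1]))) < 1e-12) {
    warning("degenerate input: all errors identical; kappa capped", call. = FALSE)
  }

  x <- deg2rad(errors)
  cx <- cos(x); sx <- sin(x)
  mu_bound_rad <- deg2rad(mu_bound)
  n <- length(x)

  # moment starts from the small-|error| and large-|error| halves
  ae <- abs(errors)
  med <- stats::median(ae)
  lo_half <- errors[ae <= med]; hi_half <- errors[ae >= med]
  k_start <- function(e) {
    R <- mean(cos(deg2rad(e)))
    clamp(a1_inv(max(R, 1e-6)), kappa_range)
  }
  k_hi0 <- k_start(lo_half)  # tight component from the small errors
  k_lo0 <- k_start(hi_half)
  if (k_hi0 / k_lo0 < 1.5) k_hi0 <- k_lo0 * 2  # ensure distinct starts

  best <- NULL
  for (r in seq_len(n_restarts)) {
    if (r == 1L) {
      mu0 <- c(0, 0)
      k0 <- c(k_hi0, k_lo0)
    } else {
      mu0 <- clamp(stats::runif(2, -mu_bound_rad, mu_bound_rad), c(-mu_bound_rad, mu_bound_rad))
      k0 <- clamp(c(k_hi0, k_lo0) * exp(stats::runif(2, -0.8, 0.8)), kappa_range)
    }
    fit <- em_vm_mixture(x, cx, sx, mu0, k0, mu_bound_rad, tol, max_iter, kappa_range)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }

  ord <- order(best$kappa, decreasing = TRUE)  # precise (large kappa) first
  sds <- vm_sd_from_kappa(best$kappa[ord])
  structure(
    list(mu = rad2deg(best$mu[ord]),
         kappa = best$kappa[ord],
         weights = c(0.5, 0.5),
         loglik = best$loglik,
         loglik_path = best$loglik_path,
         n = n,
         n_iter = best$n_iter,
         converged = best$converged,
         responsibilities = best$resp[, ord, drop = FALSE],
         precision = precision_pair(sds[1], sds[2]),
         mu_bound = mu_bound),
    class = "vm_mixture_fit"
  )
}

clamp <- function(x, range) pmin(pmax(x, range[1]), range[2])

# core EM on radian angles; cx, sx precomputed cos/sin
em_vm_mixture <- function(x, cx, sx, mu, kappa, mu_bound_rad, tol, max_iter,
                          kappa_range) {
  n <- length(x)
  dens <- function(mu_j, k_j) {
    exp(k_j * (cx * cos(mu_j) + sx * sin(mu_j) - 1)) /
      (2 * pi * besselI(k_j, 0, expon.scaled = TRUE))
  }
  ll_old <- -Inf
  ll_path <- numeric(0)
  converged <- FALSE
  g1 <- rep(0.5, n)
  for (it in seq_len(max_iter)) {
    f1 <- dens(mu[1], kappa[1])
    f2 <- dens(mu[2], kappa[2])
    mix <- 0.5 * f1 + 0.5 * f2
    ll <- sum(log(mix))
    ll_path <- c(ll_path, ll)
    g1 <- f1 / (f1 + f2)
    g2 <- 1 - g1
    if (is.finite(ll) && ll - ll_old < tol && it > 1L) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    for (j in 1:2) {
      g <- if (j == 1) g1 else g2
      S <- sum(g * sx); C <- sum(g * cx)
      mu_j <- clamp(atan2(S, C), c(-mu_bound_rad, mu_bound_rad))
      R_j <- (C * cos(mu_j) + S * sin(mu_j)) / sum(g)
      k_j <- if (R_j <= 0) kappa_range[1] else clamp(a1_inv(R_j), kappa_range)
      mu[j] <- mu_j; kappa[j] <- k_j
    }
  }
  list(mu = mu, kappa = kappa, loglik = ll_path[length(ll_path)],
       loglik_path = ll_path, n_iter = length(ll_path),
       converged = converged, resp = cbind(g1, 1 - g1))
}

#' @export
print.vm_mixture_fit <- function(x, ...) {
  cat(sprintf("<vm_mixture_fit> n=%d, loglik=%.3f, %s in %d iterations\n",
              x$n, x$loglik, if (x$converged) "converged" else "NOT converged",
              x$n_iter))
  cat(sprintf("  precise:   mu=%+.2f deg, kappa=%.3f, sd=%.3f deg\n",
              x$mu[1], x$kappa[1], x$precision$sd_precise))
  cat(sprintf("  imprecise: mu=%+.2f deg, kappa=%.3f, sd=%.3f deg\n",
              x$mu[2], x$kappa[2], x$precision$sd_imprecise))
  cat(sprintf("  ratio sd_imprecise/sd_precise = %.3f\n", x$precision$ratio))
  invisible(x)
}
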