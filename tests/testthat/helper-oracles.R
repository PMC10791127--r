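# Brute-force reference implementations, kept deliberately independent of
# the package's own code paths.

# signed shortest arc by exhaustive search over integer wraps
bf_circ_diff <- function(a, b) {
  cand <- a - b + 360 * (-5:5)
  best <- cand[which.min(abs(cand))]
  if (best == -180) 180 else best
}

bf_circ_dist <- function(a, b) abs(bf_circ_diff(a, b))

# modified Bessel I0 by power series (accurate for moderate kappa)
bf_i0 <- function(k) {
  term <- 1; total <- 1; m <- 0
  while (TRUE) {
    m <- m + 1
    term <- term * (k / 2)^2 / m^2
    total <- total + term
    if (term < 1e-18 * total || m > 500) break
  }
  total
}

bf_vm_density <- function(x_deg, mu_deg, kappa) {
  th <- (x_deg - mu_deg) * pi / 180
  exp(kappa * cos(th)) / (2 * pi * bf_i0(kappa))
}

bf_mixture_loglik <- function(errors, mu, kappa, w = c(0.5, 0.5)) {
  total <- 0
  for (e in errors) {
    total <- total + log(w[1] * bf_vm_density(e, mu[1], kappa[1]) +
                           w[2] * bf_vm_density(e, mu[2], kappa[2]))
  }
  total
}

bf_plv <- function(phases_deg) {
  th <- phases_deg * pi / 180
  cbar <- sum(cos(th)) / length(th)
  sbar <- sum(sin(th)) / length(th)
  sqrt(cbar^2 + sbar^2)
}

bf_v_test <- function(angles_deg, theta0_deg) {
  th <- angles_deg * pi / 180
  n <- length(th)
  C <- sum(cos(th)); S <- sum(sin(th))
  R <- sqrt(C^2 + S^2) / n
  mbar <- atan2(S, C)
  V <- n * R * cos(mbar - theta0_deg * pi / 180)
  u <- V * sqrt(2 / n)
  list(V = V, u = u, p = 1 - stats::pnorm(u))
}

# per-trial pairing by explicit enumeration of both assignments
bf_assign_first <- function(targets, responses) {
  if (bf_circ_dist(responses[1], targets[1]) <= bf_circ_dist(responses[1], targets[2])) {
    c(a = bf_circ_diff(responses[1], targets[1]), b = bf_circ_diff(responses[2], targets[2]))
  } else {
    c(a = bf_circ_diff(responses[2], targets[1]), b = bf_circ_diff(responses[1], targets[2]))
  }
}

bf_assign_global <- function(targets, responses) {
  d <- c(bf_circ_dist(responses[1], targets[1]), bf_circ_dist(responses[1], targets[2]),
         bf_circ_dist(responses[2], targets[1]), bf_circ_dist(responses[2], targets[2]))
  # pairing 1: R1-Ta & R2-Tb ; pairing 2: R1-Tb & R2-Ta
  if (min(d[1], d[4]) <= min(d[2], d[3])) {
    c(a = bf_circ_diff(responses[1], targets[1]), b = bf_circ_diff(responses[2], targets[2]))
  } else {
    c(a = bf_circ_diff(responses[2], targets[1]), b = bf_circ_diff(responses[1], targets[2]))
  }
}
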