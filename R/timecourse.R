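#' Half-normal precision estimate from absolute errors
#'
#' Maximum-likelihood scale of a zero-location half-normal distribution:
#' the square root of the mean squared absolute error. Used for the
#' per-SOA precision time-courses, where the probed stream is unambiguous
#' and small clockwise/counter-clockwise biases are to be ignored.
#'
#' @param abs_errors Absolute errors in degrees, in \[0, 180\].
#' @return Scale (SD) in degrees.
#' @export
fit_halfnormal_sd <- function(abs_errors) {
  if (length(abs_errors) == 0) stop("empty input", call. = FALSE)
  if (any(!is.finite(abs_errors)) || any(abs_errors < 0) || any(abs_errors > 180)) {
    stop("absolute errors must lie in [0, 180]", call. = FALSE)
  }
  sqrt(mean(abs_errors^2))
}

#' Build per-SOA precision time-courses from trial records
#'
#' Groups the absolute report errors of an SOA experiment by subject x
#' condition x SOA, estimates a half-normal SD per cell, and (by default)
#' z-normalizes each subject's cells. Conditions are `cue_absent`
#' (cue-present FALSE), `cued_stream` (probed stream was the cued one),
#' and `uncued_stream`.
#'
#' @param records Trial records with columns `subject`, `soa`,
#'   `cue_present`, `cued_stream`, `probed_stream`, `target_a`,
#'   `target_b`, `response_1`.
#' @param normalize Z-normalize per subject after the per-cell fits.
#' @return Object of class `timecourse_matrix`: `values` (3-d array
#'   subject x condition x SOA), `cell_counts`, `soa_grid`, `conditions`,
#'   `normalized`.
#' @export
build_timecourses <- function(records, normalize = TRUE) {
  need <- c("subject", "soa", "cue_present", "cued_stream", "probed_stream",
            "target_a", "target_b", "response_1")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lack columns: ", paste(miss, collapse = ", "), call. = FALSE)

  tgt <- ifelse(records$probed_stream == "a", records$target_a, records$target_b)
  abs_err <- abs(circular_difference(records$response_1, tgt))
  condition <- ifelse(!records$cue_present, "cue_absent",
                      ifelse(records$probed_stream == records$cued_stream,
                             "cued_stream", "uncued_stream"))
  conditions <- c("cue_absent", "cued_stream", "uncued_stream")
  subjects <- sort(unique(records$subject))
  soas <- sort(unique(records$soa))

  f_sub <- factor(records$subject, levels = subjects)
  f_cond <- factor(condition, levels = conditions)
  f_soa <- factor(records$soa, levels = soas)
  counts <- tapply(abs_err, list(f_sub, f_cond, f_soa), length)
  if (any(is.na(counts))) {
    idx <- which(is.na(counts), arr.ind = TRUE)[1, ]
    stop(sprintf("empty cell: subject %s, condition %s, SOA %s",
                 subjects[idx[1]], conditions[idx[2]], soas[idx[3]]), call. = FALSE)
  }
  values <- tapply(abs_err, list(f_sub, f_cond, f_soa), fit_halfnormal_sd)
  dimnames(values) <- list(subject = subjects, condition = conditions, soa = soas)

  tc <- structure(
    list(values = values, cell_counts = counts, soa_grid = soas,
         conditions = conditions, normalized = FALSE),
    class = "timecourse_matrix"
  )
  if (normalize) tc <- znormalize_subject(tc) else tc
}

#' Z-normalize a precision time-course matrix per subject
#'
#' Subtracts each subject's mean and divides by each subject's SD across
#' all of that subject's cells (all conditions x SOAs), removing large
#' between-subject differences in overall performance.
#'
#' @param tc A `timecourse_matrix` with `normalized = FALSE`.
#' @return The normalized `timecourse_matrix`.
#' @export
znormalize_subject <- function(tc) {
  stopifnot(inherits(tc, "timecourse_matrix"))
  if (tc$normalized) stop("matrix is already normalized", call. = FALSE)
  v <- tc$values
  for (s in seq_len(dim(v)[1])) {
    cells <- v[s, , ]
    sdev <- stats::sd(as.numeric(cells))
    if (!is.finite(sdev) || sdev == 0) {
      stop("degenerate subject ", dimnames(v)[[1]][s], ": zero within-subject SD",
           call. = FALSE)
    }
    v[s, , ] <- (cells - mean(cells)) / sdev
  }
  tc$values <- v
  tc$normalized <- TRUE
  tc
}

#' @export
print.timecourse_matrix <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<timecourse_matrix> %d subjects x %d conditions x %d SOAs (%s)\n",
              d[1], d[2], d[3], if (x$normalized) "z-normalized" else "raw"))
  invisible(x)
}

#' Fourier phase comparison of two short precision time-courses
#'
#' Each series is mean-removed, zero-padded to `pad_to` points, and
#' discrete-Fourier-transformed. Frequency bin k sits at k / (pad_to *
#' dt). The per-bin phase difference is phase(a) - phase(b), wrapped to
#' (-180, 180\].
#'
#' @param timecourse_a,timecourse_b Numeric series of equal length (one
#'   value per SOA).
#' @param dt SOA spacing in seconds.
#' @param pad_to FFT length after zero padding.
#' @return Data frame with one row per positive-frequency bin (1 ..
#'   pad_to/2): `bin`, `freq` (Hz), `amp_a`, `amp_b`, `phase_diff`
#'   (degrees).
#' @export
spectral_phase <- function(timecourse_a, timecourse_b, dt, pad_to = 16) {
  na <- length(timecourse_a)
  if (na != length(timecourse_b)) stop("series must have equal length", call. = FALSE)
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (pad_to < na) stop("pad_to must be >= series length", call. = FALSE)
  pad <- function(x) c(x - mean(x), rep(0, pad_to - length(x)))
  Xa <- stats::fft(pad(timecourse_a))
  Xb <- stats::fft(pad(timecourse_b))
  k <- seq_len(pad_to %/% 2)
  data.frame(
    bin = k,
    freq = k / (pad_to * dt),
    amp_a = Mod(Xa[k + 1]),
    amp_b = Mod(Xb[k + 1]),
    phase_diff = wrap_signed(rad2deg(Arg(Xa[k + 1]) - Arg(Xb[k + 1])))
  )
}

#' Phase-locking value across subjects
#'
#' Modulus of the mean unit phasor of per-subject phase differences at one
#' frequency bin; 1 means a perfectly consistent phase relation, 0 no
#' consistency.
#'
#' @param phase_diffs Per-subject phase differences in degrees.
#' @return PLV in \[0, 1\].
#' @export
plv_across_subjects <- function(phase_diffs) {
  if (length(phase_diffs) < 2) stop("need at least 2 subjects", call. = FALSE)
  Mod(mean(exp(1i * deg2rad(phase_diffs))))
}

#' V-test (modified Rayleigh test) against a specified direction
#'
#' Tests circular non-uniformity of per-subject phase angles with a
#' specified mean direction `theta0` (0 degrees for in-phase, 180 for
#' counter-phase). V = n * R * cos(mean - theta0); u = V * sqrt(2/n) is
#' referred to the upper tail of the standard normal.
#'
#' @param angles Angles in degrees (at least 5).
#' @param theta0 Hypothesized mean direction, degrees.
#' @return List with `V`, `u`, `p` (one-sided), `mean_angle` (degrees),
#'   `R`, and `n`.
#' @export
v_test <- function(angles, theta0) {
  n <- length(angles)
  if (n < 5) stop("need at least 5 angles", call. = FALSE)
  cm <- circ_mean_resultant(angles)
  V <- n * cm$R * cos(deg2rad(cm$mean - theta0))
  u <- V * sqrt(2 / n)
  list(V = V, u = u, p = stats::pnorm(u, lower.tail = FALSE),
       mean_angle = cm$mean, R = cm$R, n = n)
}

#' Alternation analysis of cued vs. uncued precision time-courses
#'
#' For each subject, computes the Fourier phase difference between the
#' cued-stream and uncued-stream precision time-courses, then the
#' phase-locking value per frequency bin across subjects, picks the peak
#' PLV bin inside the resolvable band, and runs v-tests of the phase
#' differences at that bin against 0 (in-phase) and 180 degrees
#' (counter-phase).
#'
#' @param tc A `timecourse_matrix` from [build_timecourses()].
#' @param pad_to FFT length after zero padding.
#' @param band Length-2 frequency band (Hz) within which the peak PLV bin
#'   is selected; defaults to \[1/(n_soa * dt), 1/(2 dt)\], the band
#'   resolvable by the SOA sampling.
#' @return Object of class `alternation_result`: per-bin `freq` and
#'   `plv`, per-subject `phase_diff` matrix (subject x bin, degrees),
#'   `peak_bin`, `peak_freq`, `peak_plv`, v-tests `v0` and `v180`, and
#'   `band`.
#' @export
alternation_analysis <- function(tc, pad_to = 16, band = NULL) {
  stopifnot(inherits(tc, "timecourse_matrix"))
  v <- tc$values
  n_sub <- dim(v)[1]
  # snap the SOA spacing to a clean decimal so the frequency axis is exact
  dt <- round(mean(diff(tc$soa_grid)), 10)
  n_soa <- length(tc$soa_grid)
  if (is.null(band)) band <- c(1 / (n_soa * dt), 1 / (2 * dt))

  sp1 <- spectral_phase(v[1, "cued_stream", ], v[1, "uncued_stream", ], dt, pad_to)
  phase <- matrix(NA_real_, n_sub, nrow(sp1))
  phase[1, ] <- sp1$phase_diff
  for (s in seq_len(n_sub)[-1]) {
    phase[s, ] <- spectral_phase(v[s, "cued_stream", ], v[s, "uncued_stream", ],
                                 dt, pad_to)$phase_diff
  }
  plv <- apply(phase, 2, plv_across_subjects)
  in_band <- sp1$freq >= band[1] - 1e-9 & sp1$freq <= band[2] + 1e-9
  if (!any(in_band)) stop("no frequency bin inside the requested band", call. = FALSE)
  peak_bin <- which(in_band)[which.max(plv[in_band])]

  structure(
    list(freq = sp1$freq, plv = plv, phase_diff = phase,
         peak_bin = peak_bin, peak_freq = sp1$freq[peak_bin],
         peak_plv = plv[peak_bin],
         v0 = v_test(phase[, peak_bin], 0),
         v180 = v_test(phase[, peak_bin], 180),
         band = band, dt = dt, pad_to = pad_to),
    class = "alternation_result"
  )
}

#' @export
print.alternation_result <- function(x, ...) {
  cat(sprintf("<alternation_result> peak PLV %.3f at %.4f Hz (band %.3f-%.3f Hz)\n",
              x$peak_plv, x$peak_freq, x$band[1], x$band[2]))
  n <- x$v0$n
  cat(sprintf("  v-test vs   0 deg: v(%d) = %.2f, p = %.4f, m = %.2f deg\n",
              n - 1, x$v0$V, x$v0$p, x$v0$mean_angle))
  cat(sprintf("  v-test vs 180 deg: v(%d) = %.2f, p = %.4f, m = %.2f deg\n",
              n - 1, x$v180$V, x$v180$p, x$v180$mean_angle))
  invisible(x)
}
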