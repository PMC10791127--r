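#' Two-resource synthetic observer
#'
#' Describes an observer who tracks two color streams with a limited
#' precision resource: at any moment one stream is reported with error SD
#' `sd_high` (the favored, precisely tracked stream) and the other with
#' `sd_low`. Under `fixed` allocation the favored stream is drawn once per
#' trial with probability 1/2; under `alternating` allocation the favor
#' switches deterministically following the sign of a cosine phase function
#' at `alternation_freq`.
#'
#' @param sd_high Error SD (degrees) of the precisely tracked stream.
#' @param sd_low Error SD (degrees) of the other stream; must be >=
#'   `sd_high`.
#' @param allocation `"fixed"` or `"alternating"`.
#' @param alternation_freq Alternation frequency in Hz (alternating only).
#' @param alternation_phase Phase offset in degrees of the alternation
#'   cycle.
#' @param cue_resets_phase If `TRUE`, a luminance cue resets the
#'   alternation phase so that the cued stream is favored at the cue;
#'   without a cue (or with `FALSE`) each trial gets an independent uniform
#'   random phase.
#' @param swap_rate Probability that the two reports of a double-report
#'   trial are exchanged (stress parameter for the pairing rule; 0 by
#'   default, as the report model has no swap component).
#' @param first_confidence Probability that the favored stream is reported
#'   first on double-report trials.
#' @return Object of class `observer_model`.
#' @export
observer_model <- function(sd_high, sd_low,
                           allocation = c("fixed", "alternating"),
                           alternation_freq = 1,
                           alternation_phase = 0,
                           cue_resets_phase = TRUE,
                           swap_rate = 0,
                           first_confidence = 0.9) {
  allocation <- match.arg(allocation)
  if (!(sd_high > 0 && sd_high <= sd_low)) {
    stop("need 0 < sd_high <= sd_low", call. = FALSE)
  }
  if (allocation == "alternating" && alternation_freq <= 0) {
    stop("alternation_freq must be > 0 for alternating allocation", call. = FALSE)
  }
  structure(list(sd_high = sd_high, sd_low = sd_low,
                 allocation = allocation,
                 alternation_freq = alternation_freq,
                 alternation_phase = alternation_phase,
                 cue_resets_phase = isTRUE(cue_resets_phase),
                 swap_rate = swap_rate,
                 first_confidence = first_confidence),
            class = "observer_model")
}

#' @export
print.observer_model <- function(x, ...) {
  cat(sprintf("<observer_model> sd_high=%g deg, sd_low=%g deg, %s allocation",
              x$sd_high, x$sd_low, x$allocation))
  if (x$allocation == "alternating") {
    cat(sprintf(" @ %g Hz (phase %g deg, cue reset: %s)",
                x$alternation_freq, x$alternation_phase, x$cue_resets_phase))
  }
  cat("\n")
  invisible(x)
}

#' Experiment design for the synthetic observer
#'
#' `exp1`: double report of both streams after 6-8 s of tracking.
#' `exp2`: single report of one randomly probed stream after 6-8 s.
#' `exp3a/b/c`: single report at one of six fixed SOAs after hue onset,
#' with a luminance cue on half the trials 200 ms after onset; per SOA the
#' design holds 36 cued-stream probes and 36 uncued-stream probes among the
#' cue-present trials plus 72 cue-absent trials.
#'
#' @param experiment One of `"exp1"`, `"exp2"`, `"exp3a"`, `"exp3b"`,
#'   `"exp3c"`.
#' @param n_trials Number of trials for exp1/exp2 (ignored for exp3).
#' @param soa_grid Probe times in seconds after hue onset (exp3 only);
#'   defaults to the per-variant grid: 3.0-4.0 s in 200 ms steps (exp3a),
#'   3.0-3.5 s in 100 ms steps (exp3b), 3.0-3.2 s in 40 ms steps (exp3c).
#' @param trials_per_soa Named counts `c(cued, uncued, absent)` per SOA.
#' @param cue_time_s Cue onset in seconds after hue onset.
#' @param trial_length_frames Range (frames) of the random trial length for
#'   exp1/exp2; probe-time targets are the hues at the truncation frame.
#' @return Object of class `experiment_design`.
#' @export
experiment_design <- function(experiment = c("exp1", "exp2", "exp3a", "exp3b", "exp3c"),
                              n_trials = 150,
                              soa_grid = NULL,
                              trials_per_soa = c(cued = 36, uncued = 36, absent = 72),
                              cue_time_s = 0.2,
                              trial_length_frames = c(360, 480)) {
  experiment <- match.arg(experiment)
  if (is.null(soa_grid)) {
    soa_grid <- switch(experiment,
                       exp3a = seq(3.0, 4.0, by = 0.2),
                       exp3b = seq(3.0, 3.5, by = 0.1),
                       exp3c = seq(3.0, 3.2, by = 0.04),
                       NULL)
  }
  if (startsWith(experiment, "exp3")) {
    stopifnot(length(soa_grid) >= 2, all(diff(soa_grid) > 0))
    stopifnot(all(c("cued", "uncued", "absent") %in% names(trials_per_soa)))
  } else if (!is.null(soa_grid)) {
    stop("soa_grid applies to exp3 designs only", call. = FALSE)
  }
  structure(list(experiment = experiment, n_trials = n_trials,
                 soa_grid = soa_grid, trials_per_soa = trials_per_soa,
                 cue_time_s = cue_time_s,
                 trial_length_frames = trial_length_frames),
            class = "experiment_design")
}

# which stream the observer tracks precisely at probe time t (seconds).
# reference stream: the cued stream when the cue resets the phase,
# otherwise stream a with an extra per-trial random phase.
favored_stream_at <- function(model, t, ref_stream, t_ref, extra_phase) {
  arg <- 2 * pi * model$alternation_freq * (t - t_ref) +
    deg2rad(model$alternation_phase) + extra_phase
  ifelse(cos(arg) > 0, ref_stream, other_stream(ref_stream))
}

other_stream <- function(s) ifelse(s == "a", "b", "a")

#' Simulate an experiment of the two-resource observer
#'
#' Targets are the probe-time hues of the supplied trajectory pairs (pairs
#' are sampled with replacement; trial length is drawn uniformly from the
#' design's frame range for exp1/exp2, or fixed at each SOA for exp3). Each
#' report equals its target plus a von Mises error whose SD is `sd_high`
#' for the currently favored stream and `sd_low` for the other.
#'
#' @param model An [observer_model()].
#' @param design An [experiment_design()].
#' @param trajectories List of `trajectory_pair` objects.
#' @param seed Optional integer seed; the simulation is deterministic given
#'   the seed.
#' @return Data frame of trial records with columns `trial_id`,
#'   `experiment`, `soa`, `probe_time_s`, `cue_present`, `cued_stream`,
#'   `probed_stream`, `target_a`, `target_b`, `response_1`, `response_2`,
#'   and the latent ground-truth column `favored_stream` (kept so that
#'   recovery analyses can be validated; it is not visible to any fitting
#'   routine).
#' @export
simulate_experiment <- function(model, design, trajectories, seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, simulate_experiment(model, design, trajectories)))
  }
  stopifnot(inherits(model, "observer_model"), inherits(design, "experiment_design"))
  if (length(trajectories) == 0) {
    stop("trajectories must be a non-empty list of trajectory pairs", call. = FALSE)
  }
  ang_a <- vapply(trajectories, function(p) p$stream_a$angles, numeric(length(trajectories[[1]]$stream_a$angles)))
  ang_b <- vapply(trajectories, function(p) p$stream_b$angles, numeric(nrow(ang_a)))
  n_frames <- nrow(ang_a)
  frame_rate <- trajectories[[1]]$stream_a$frame_rate

  exp3 <- startsWith(design$experiment, "exp3")
  if (exp3) {
    per <- design$trials_per_soa
    soa <- rep(design$soa_grid, each = sum(per))
    type <- rep(rep(c("cued", "uncued", "absent"), times = per[c("cued", "uncued", "absent")]),
                times = length(design$soa_grid))
    n <- length(soa)
    probe_t <- soa
    frames <- pmin(pmax(round(soa * frame_rate), 1L), n_frames)
    cue_present <- type != "absent"
    cued_stream <- ifelse(cue_present, sample(c("a", "b"), n, replace = TRUE), "none")
    probed_stream <- ifelse(type == "cued", cued_stream,
                            ifelse(type == "uncued", other_stream(cued_stream),
                                   sample(c("a", "b"), n, replace = TRUE)))
  } else {
    n <- design$n_trials
    fr_range <- design$trial_length_frames
    frames <- sample(seq.int(fr_range[1], min(fr_range[2], n_frames)), n, replace = TRUE)
    probe_t <- frames / frame_rate
    soa <- rep(NA_real_, n)
    cue_present <- rep(FALSE, n)
    cued_stream <- rep("none", n)
    probed_stream <- if (design$experiment == "exp1") rep("both", n) else sample(c("a", "b"), n, replace = TRUE)
  }

  pair_idx <- sample.int(length(trajectories), n, replace = TRUE)
  target_a <- ang_a[cbind(frames, pair_idx)]
  target_b <- ang_b[cbind(frames, pair_idx)]

  if (model$allocation == "fixed") {
    favored <- sample(c("a", "b"), n, replace = TRUE)
  } else {
    reset <- cue_present & model$cue_resets_phase
    ref <- ifelse(reset, cued_stream, "a")
    t_ref <- ifelse(reset, design$cue_time_s, 0)
    extra <- ifelse(reset, 0, stats::runif(n, 0, 2 * pi))
    favored <- favored_stream_at(model, probe_t, ref, t_ref, extra)
  }

  kappa_high <- vm_kappa_from_sd(model$sd_high)
  kappa_low <- vm_kappa_from_sd(model$sd_low)
  err_high <- rvonmises(n, 0, kappa_high)
  err_low <- rvonmises(n, 0, kappa_low)
  err_a <- ifelse(favored == "a", err_high, err_low)
  err_b <- ifelse(favored == "b", err_high, err_low)

  if (design$experiment == "exp1") {
    rep_a <- wrap_positive(target_a + err_a)
    rep_b <- wrap_positive(target_b + err_b)
    first <- ifelse(stats::runif(n) < model$first_confidence, favored, other_stream(favored))
    response_1 <- ifelse(first == "a", rep_a, rep_b)
    response_2 <- ifelse(first == "a", rep_b, rep_a)
    if (model$swap_rate > 0) {
      sw <- stats::runif(n) < model$swap_rate
      tmp <- response_1[sw]
      response_1[sw] <- response_2[sw]
      response_2[sw] <- tmp
    }
  } else {
    tgt <- ifelse(probed_stream == "a", target_a, target_b)
    err <- ifelse(probed_stream == favored, err_high, err_low)
    response_1 <- wrap_positive(tgt + err)
    response_2 <- rep(NA_real_, n)
  }

  data.frame(trial_id = seq_len(n),
             experiment = design$experiment,
             soa = soa,
             probe_time_s = probe_t,
             cue_present = cue_present,
             cued_stream = cued_stream,
             probed_stream = probed_stream,
             target_a = target_a,
             target_b = target_b,
             response_1 = response_1,
             response_2 = response_2,
             favored_stream = favored,
             stringsAsFactors = FALSE)
}

#' Simulate several subjects of one experiment
#'
#' Each subject shares the trajectory pool (as in the original design,
#' where the same stimulus set served all subjects) but has independent
#' trial randomization and report noise.
#'
#' @inheritParams simulate_experiment
#' @param n_subjects Number of simulated subjects.
#' @return Data frame of trial records with a leading `subject` column.
#' @export
simulate_subjects <- function(model, design, trajectories, n_subjects, seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, simulate_subjects(model, design, trajectories, n_subjects)))
  }
  out <- lapply(seq_len(n_subjects), function(s) {
    cbind(subject = s, simulate_experiment(model, design, trajectories))
  })
  do.call(rbind, out)
}

#' Kolmogorov-Smirnov uniformity checks of the probe-time targets
#'
#' Tests the target hues of both streams against the circular uniform
#' distribution, and the inter-target distance against a uniform
#' distribution on \[`min_dist`, 180\] degrees.
#'
#' @param records Trial records from [simulate_experiment()] (or a read
#'   trial file); needs columns `target_a`, `target_b`.
#' @param min_dist Lower bound of the admissible inter-target distance.
#' @return Data frame with one row per check (`target_a`, `target_b`,
#'   `distance`) and columns `D`, `p`, `n`.
#' @export
targets_uniformity_check <- function(records, min_dist = 60) {
  if (nrow(records) < 20) {
    stop("need at least 20 trial records for uniformity checks", call. = FALSE)
  }
  d <- circular_distance(records$target_a, records$target_b)
  checks <- list(
    target_a = wrap_positive(records$target_a) / 360,
    target_b = wrap_positive(records$target_b) / 360,
    distance = (d - min_dist) / (180 - min_dist)
  )
  out <- lapply(names(checks), function(nm) {
    kt <- ks_unif01(checks[[nm]])
    data.frame(check = nm, D = kt$D, p = kt$p, n = length(checks[[nm]]))
  })
  do.call(rbind, out)
}

# KS test of values against uniform [0,1]; asymptotic p, tolerant of ties
ks_unif01 <- function(u) {
  kt <- suppressWarnings(stats::ks.test(u, "punif", exact = FALSE))
  list(D = unname(kt$statistic), p = kt$p.value)
}
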