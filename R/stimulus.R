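#' Generate a constrained random-walk hue trajectory
#'
#' A trajectory starts at a uniformly random hue and moves around the hue
#' circle at a fixed speed (1 degree per frame by default). Candidate
#' reversal frames are spaced by independent uniform integer draws from
#' `interval_range`; at each candidate the direction of motion reverts with
#' probability `reversal_prob`. The walk is continuous: every frame-to-frame
#' step has magnitude exactly `speed`.
#'
#' @param n_frames Number of frames (480 frames = 8 s at 60 Hz).
#' @param speed Degrees traversed per frame.
#' @param interval_range Integer vector `c(lo, hi)`: candidate reversal
#'   frames are spaced by uniform draws from `lo:hi` frames.
#' @param reversal_prob Probability that the direction actually reverts at a
#'   candidate frame.
#' @param frame_rate Frames per second (display refresh), used only to
#'   convert frames to seconds in summaries.
#' @param start_angle Optional fixed start hue in degrees; defaults to a
#'   uniform random draw.
#' @param seed Optional integer seed for a reproducible trajectory.
#' @return An object of class `hue_trajectory`: a list with `angles`
#'   (length `n_frames`, degrees in \[0, 360)), `reversal_frames` (frames at
#'   which the direction reverted), `candidate_frames`, `speed`, and
#'   `frame_rate`.
#' @export
generate_trajectory <- function(n_frames = 480, speed = 1,
                                interval_range = c(30, 100),
                                reversal_prob = 1,
                                frame_rate = 60,
                                start_angle = NULL,
                                seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(
      seed,
      generate_trajectory(n_frames, speed, interval_range, reversal_prob,
                          frame_rate, start_angle)
    ))
  }
  stopifnot(n_frames >= 1, length(interval_range) == 2)
  lo <- as.integer(interval_range[1]); hi <- as.integer(interval_range[2])
  if (lo < 1 || lo > hi) {
    stop("interval_range must satisfy 1 <= lo <= hi", call. = FALSE)
  }
  if (reversal_prob < 0 || reversal_prob > 1) {
    stop("reversal_prob must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(start_angle)) start_angle <- stats::runif(1, 0, 360)

  # candidate reversal frames: cumulative uniform-integer gaps
  candidates <- integer(0)
  pos <- 0L
  repeat {
    pos <- pos + sample.int(hi - lo + 1L, 1L) + lo - 1L
    if (pos >= n_frames) break
    candidates <- c(candidates, pos)
  }
  reverted <- candidates[stats::runif(length(candidates)) < reversal_prob]

  dir0 <- if (stats::runif(1) < 0.5) -1 else 1
  if (n_frames == 1L) {
    dirs <- numeric(0)
  } else {
    flips <- rep(1, n_frames - 1L)
    flips[reverted] <- -1
    dirs <- dir0 * cumprod(flips)
  }
  angles <- wrap_positive(start_angle + speed * cumsum(c(0, dirs)))

  structure(
    list(angles = angles,
         reversal_frames = as.integer(reverted),
         candidate_frames = as.integer(candidates),
         speed = speed,
         frame_rate = frame_rate),
    class = "hue_trajectory"
  )
}

#' @export
print.hue_trajectory <- function(x, ...) {
  cat(sprintf("<hue_trajectory> %d frames @ %g Hz, %g deg/frame, %d reversals\n",
              length(x$angles), x$frame_rate, x$speed, length(x$reversal_frames)))
  invisible(x)
}

#' Generate a pool of independent hue trajectories
#'
#' @param n Number of trajectories.
#' @param ... Passed to [generate_trajectory()].
#' @param seed Optional integer seed.
#' @return List of `hue_trajectory` objects.
#' @export
generate_trajectory_pool <- function(n, ..., seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, generate_trajectory_pool(n, ...)))
  }
  lapply(seq_len(n), function(i) generate_trajectory(...))
}

#' Pair two trajectories under a minimum hue-distance constraint
#'
#' Scans randomly ordered candidate pairs from the pool and returns the
#' first pair whose per-frame circular distance never falls below
#' `min_dist`. Pairing looks only at the constraint, never at trajectory
#' content, so the histories of the paired streams stay independent.
#'
#' @param pool List of `hue_trajectory` objects (all the same length).
#' @param min_dist Minimum per-frame circular distance in degrees.
#' @param max_tries Maximum number of candidate pairs inspected before
#'   giving up.
#' @param seed Optional integer seed.
#' @return An object of class `trajectory_pair`: list with `stream_a`,
#'   `stream_b`, and `min_dist`.
#' @export
pair_trajectories <- function(pool, min_dist = 60, max_tries = 5000L, seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, pair_trajectories(pool, min_dist, max_tries)))
  }
  n <- length(pool)
  if (n < 2) stop("pool must contain at least two trajectories", call. = FALSE)
  if (min_dist <= 0 || min_dist > 180) {
    stop("min_dist must lie in (0, 180]", call. = FALSE)
  }
  idx <- utils::combn(n, 2)
  ord <- sample.int(ncol(idx))
  tries <- min(length(ord), max_tries)
  for (k in seq_len(tries)) {
    i <- idx[1, ord[k]]; j <- idx[2, ord[k]]
    if (admissible_pair(pool[[i]], pool[[j]], min_dist)) {
      return(structure(
        list(stream_a = pool[[i]], stream_b = pool[[j]], min_dist = min_dist),
        class = "trajectory_pair"
      ))
    }
  }
  stop("no admissible trajectory pair found in pool (min_dist = ",
       min_dist, " deg)", call. = FALSE)
}

admissible_pair <- function(ta, tb, min_dist) {
  all(circular_distance(ta$angles, tb$angles) >= min_dist)
}

#' Draw many admissible trajectory pairs from a pool
#'
#' Pairs are sampled independently (a trajectory may appear in more than one
#' pair), each checked against the full-length distance constraint.
#'
#' @inheritParams pair_trajectories
#' @param n_pairs Number of pairs to return.
#' @return List of `trajectory_pair` objects.
#' @export
make_trajectory_pairs <- function(pool, n_pairs, min_dist = 60,
                                  max_tries = 200L * n_pairs, seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, make_trajectory_pairs(pool, n_pairs, min_dist, max_tries)))
  }
  n <- length(pool)
  if (n < 2) stop("pool must contain at least two trajectories", call. = FALSE)
  pairs <- vector("list", n_pairs)
  found <- 0L
  for (k in seq_len(max_tries)) {
    ij <- sample.int(n, 2L)
    if (admissible_pair(pool[[ij[1]]], pool[[ij[2]]], min_dist)) {
      found <- found + 1L
      pairs[[found]] <- structure(
        list(stream_a = pool[[ij[1]]], stream_b = pool[[ij[2]]], min_dist = min_dist),
        class = "trajectory_pair"
      )
      if (found == n_pairs) return(pairs)
    }
  }
  stop("could not assemble ", n_pairs, " admissible pairs after ",
       max_tries, " tries", call. = FALSE)
}

#' Iso-luminant color circle in CIELUV chromaticity
#'
#' Parameters of the hue circle: a circle of fixed chromaticity radius
#' centered on the white point in a constant-luminance plane of u'v'
#' chromaticity space. Defaults are a D65-referenced white point at
#' (0.1978, 0.4683), 14.5 cd/m^2, and radius 0.0576.
#'
#' @param white_u,white_v Chromaticity coordinates of the white point.
#' @param luminance Luminance of the plane, cd/m^2.
#' @param radius Chromaticity radius of the hue circle.
#' @return Object of class `color_circle`.
#' @export
color_circle <- function(white_u = 0.1978, white_v = 0.4683,
                         luminance = 14.5, radius = 0.0576) {
  if (radius <= 0 || luminance <= 0) {
    stop("color_circle requires radius > 0 and luminance > 0", call. = FALSE)
  }
  structure(list(white_u = white_u, white_v = white_v,
                 luminance = luminance, radius = radius),
            class = "color_circle")
}

#' Map hue angles to iso-luminant color coordinates
#'
#' Hue 0 lies on the +u' axis; angles increase counter-clockwise.
#'
#' @param angle Hue angles in degrees.
#' @param circle A [color_circle()].
#' @return Data frame with columns `u`, `v`, `luminance`.
#' @export
hue_to_color <- function(angle, circle = color_circle()) {
  stopifnot(inherits(circle, "color_circle"))
  th <- deg2rad(angle)
  data.frame(u = circle$white_u + circle$radius * cos(th),
             v = circle$white_v + circle$radius * sin(th),
             luminance = rep(circle$luminance, length(th)))
}

#' Descriptive statistics of a set of paired hue trajectories
#'
#' Summarizes the stimulus set the way one would audit it before an
#' experiment: how often hue direction reverses, how long the intervals
#' between reversals are, how the between-stream hue distance is
#' distributed, and how strongly the two streams' visited hues overlap.
#'
#' @param pairs List of `trajectory_pair` objects.
#' @param breaks Histogram breaks (degrees) for the per-frame distance
#'   distribution.
#' @return Object of class `stimulus_stats`: combined reversal mean/SD per
#'   trial, inter-reversal interval mean/SD in seconds (intervals of the
#'   merged reversal sequence of both streams), a per-frame distance
#'   histogram (data frame `lower`, `upper`, `count`, `density`), and the
#'   mean/SD of the per-trial hue intersection fraction (proportion of one
#'   stream's visited integer hues also visited by the other, averaged over
#'   both directions).
#' @export
stimulus_statistics <- function(pairs, breaks = seq(0, 180, by = 5)) {
  if (length(pairs) == 0) stop("need at least one trajectory pair", call. = FALSE)
  stopifnot(all(vapply(pairs, inherits, logical(1), "trajectory_pair")))

  n_rev <- vapply(pairs, function(p) {
    length(p$stream_a$reversal_frames) + length(p$stream_b$reversal_frames)
  }, numeric(1))

  intervals <- unlist(lapply(pairs, function(p) {
    fr <- sort(c(p$stream_a$reversal_frames, p$stream_b$reversal_frames))
    if (length(fr) < 2) return(numeric(0))
    diff(fr) / p$stream_a$frame_rate
  }))

  dists <- unlist(lapply(pairs, function(p) {
    circular_distance(p$stream_a$angles, p$stream_b$angles)
  }))
  h <- graphics::hist(dists, breaks = breaks, plot = FALSE)
  dist_hist <- data.frame(lower = utils::head(h$breaks, -1),
                          upper = utils::tail(h$breaks, -1),
                          count = h$counts,
                          density = h$density)

  inter <- vapply(pairs, function(p) {
    va <- unique(round(p$stream_a$angles) %% 360)
    vb <- unique(round(p$stream_b$angles) %% 360)
    common <- length(intersect(va, vb))
    mean(c(common / length(va), common / length(vb)))
  }, numeric(1))

  structure(
    list(combined_reversals_mean = mean(n_rev),
         combined_reversals_sd = stats::sd(n_rev),
         inter_reversal_mean_s = if (length(intervals)) mean(intervals) else NA_real_,
         inter_reversal_sd_s = if (length(intervals) > 1) stats::sd(intervals) else NA_real_,
         distance_histogram = dist_hist,
         intersection_fraction_mean = mean(inter),
         intersection_fraction_sd = stats::sd(inter),
         intersection_fractions = inter,
         n_pairs = length(pairs)),
    class = "stimulus_stats"
  )
}

#' @export
print.stimulus_stats <- function(x, ...) {
  cat(sprintf("<stimulus_stats> %d pairs\n", x$n_pairs))
  cat(sprintf("  combined reversals/trial: %.2f (SD %.2f)\n",
              x$combined_reversals_mean, x$combined_reversals_sd))
  cat(sprintf("  inter-reversal interval: %.4f s (SD %.4f s)\n",
              x$inter_reversal_mean_s, x$inter_reversal_sd_s))
  cat(sprintf("  hue intersection fraction: %.3f (SD %.3f)\n",
              x$intersection_fraction_mean, x$intersection_fraction_sd))
  invisible(x)
}

#' Write / read a trajectory pair as delimited text
#'
#' One file per trial with columns `frame`, `hue_a_deg`, `hue_b_deg`.
#'
#' @param pair A `trajectory_pair`.
#' @param path Output file path.
#' @return `write_trajectory_pair` returns `path` invisibly;
#'   `read_trajectory_pair` returns a `trajectory_pair` (reversal frames are
#'   recovered from the sign changes of the hue steps).
#' @export
write_trajectory_pair <- function(pair, path) {
  stopifnot(inherits(pair, "trajectory_pair"))
  df <- data.frame(frame = seq_along(pair$stream_a$angles),
                   hue_a_deg = pair$stream_a$angles,
                   hue_b_deg = pair$stream_b$angles)
  write_numeric_csv(df, path)
  invisible(path)
}

#' @rdname write_trajectory_pair
#' @param frame_rate,speed Trajectory metadata not stored in the file.
#' @export
read_trajectory_pair <- function(path, frame_rate = 60, speed = 1) {
  df <- utils::read.csv(path)
  stopifnot(all(c("frame", "hue_a_deg", "hue_b_deg") %in% names(df)))
  mk <- function(ang) {
    steps <- wrap_signed(diff(ang))
    dirs <- sign(steps)
    rev_fr <- which(diff(dirs) != 0) + 1L
    structure(list(angles = ang, reversal_frames = as.integer(rev_fr),
                   candidate_frames = as.integer(rev_fr),
                   speed = speed, frame_rate = frame_rate),
              class = "hue_trajectory")
  }
  structure(list(stream_a = mk(df$hue_a_deg), stream_b = mk(df$hue_b_deg),
                 min_dist = min(circular_distance(df$hue_a_deg, df$hue_b_deg))),
            class = "trajectory_pair")
}
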