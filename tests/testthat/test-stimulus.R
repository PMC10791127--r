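test_that("trajectories step exactly one speed unit per frame and reverse only at reversal frames", {
  tr <- generate_trajectory(480, seed = 21)
  expect_length(tr$angles, 480)
  steps <- wrap_signed(diff(tr$angles))
  expect_true(all(abs(abs(steps) - tr$speed) < 1e-9))
  dir_changes <- which(diff(sign(steps)) != 0) + 1L
  expect_identical(dir_changes, tr$reversal_frames)
})

test_that("reversal probability endpoints behave as specified", {
  forced <- generate_trajectory(480, reversal_prob = 1, seed = 22)
  expect_identical(forced$reversal_frames, forced$candidate_frames)

  mono <- generate_trajectory(480, reversal_prob = 0, seed = 23)
  expect_length(mono$reversal_frames, 0)
  # monotone walk ends 479 degrees from its start (mod 360)
  end_diff <- circular_distance(mono$angles[480], mono$angles[1])
  expect_equal(end_diff, circular_distance(479, 0))
})

test_that("trajectory generation is deterministic given a seed", {
  a <- generate_trajectory(480, seed = 24)
  b <- generate_trajectory(480, seed = 24)
  expect_identical(a, b)
})

test_that("invalid trajectory arguments are rejected", {
  expect_error(generate_trajectory(480, interval_range = c(0, 10)), "interval_range")
  expect_error(generate_trajectory(480, interval_range = c(50, 30)), "interval_range")
  expect_error(generate_trajectory(480, reversal_prob = 1.5), "reversal_prob")
})

test_that("pairing accepts and rejects constant trajectories by distance", {
  ok <- list(const_trajectory(0), const_trajectory(90))
  pair <- pair_trajectories(ok, min_dist = 60, seed = 25)
  expect_s3_class(pair, "trajectory_pair")
  bad <- list(const_trajectory(0), const_trajectory(30))
  expect_error(pair_trajectories(bad, min_dist = 60, seed = 25), "no admissible")
})

test_that("every returned pair respects the per-frame distance constraint", {
  pairs <- test_pairs(20)
  for (p in pairs) {
    d <- mapply(bf_circ_dist, p$stream_a$angles, p$stream_b$angles)
    expect_gte(min(d), 60)
  }
})

test_that("hue angles map onto the iso-luminant circle", {
  circ <- color_circle()
  at0 <- hue_to_color(0, circ)
  expect_equal(at0$u, 0.2554)
  expect_equal(at0$v, 0.4683)
  expect_equal(at0$luminance, 14.5)
  at180 <- hue_to_color(180, circ)
  expect_equal(at180$u, circ$white_u - circ$radius)
  expect_equal(at180$v, circ$white_v)
  all_hues <- hue_to_color(0:359, circ)
  r <- sqrt((all_hues$u - circ$white_u)^2 + (all_hues$v - circ$white_v)^2)
  expect_lt(max(abs(r - circ$radius)), 1e-12)
  expect_error(color_circle(radius = 0), "radius")
})

test_that("stimulus statistics summarize reversals, distances and hue overlap", {
  quiet <- withr::with_seed(26, {
    pool <- generate_trajectory_pool(6, reversal_prob = 0)
    make_trajectory_pairs(pool, 2, max_tries = 5000)
  })
  st0 <- stimulus_statistics(quiet)
  expect_equal(st0$combined_reversals_mean, 0)

  # reversed copy visits exactly the same hues: full overlap
  tr <- generate_trajectory(480, seed = 27)
  mirror <- tr
  mirror$angles <- rev(tr$angles)
  st1 <- stimulus_statistics(list(manual_pair(tr, mirror)))
  expect_equal(st1$intersection_fraction_mean, 1)

  st <- stimulus_statistics(test_pairs(20))
  below <- st$distance_histogram$upper <= 60
  expect_equal(sum(st$distance_histogram$count[below]), 0)
  expect_true(st$intersection_fraction_mean >= 0 && st$intersection_fraction_mean <= 1)
})

test_that("trajectory pairs round-trip through delimited text", {
  p <- test_pairs(1)[[1]]
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_pair(p, f)
  back <- read_trajectory_pair(f)
  expect_equal(back$stream_a$angles, p$stream_a$angles)
  expect_equal(back$stream_b$angles, p$stream_b$angles)
  expect_identical(back$stream_a$reversal_frames, p$stream_a$reversal_frames)
})
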