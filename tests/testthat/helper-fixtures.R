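# Shared seeded stimulus set, built once per test run.
test_pairs <- local({
  cache <- NULL
  function(n = 60) {
    if (is.null(cache)) {
      pool <- generate_trajectory_pool(40, seed = 101)
      cache <<- make_trajectory_pairs(pool, 60, seed = 102)
    }
    cache[seq_len(n)]
  }
})

# a constant-hue trajectory, for constructing hand-made pairs
const_trajectory <- function(angle, n_frames = 480) {
  structure(list(angles = rep(wrap_positive(angle), n_frames),
                 reversal_frames = integer(0), candidate_frames = integer(0),
                 speed = 0, frame_rate = 60),
            class = "hue_trajectory")
}

manual_pair <- function(ta, tb, min_dist = 60) {
  structure(list(stream_a = ta, stream_b = tb, min_dist = min_dist),
            class = "trajectory_pair")
}
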