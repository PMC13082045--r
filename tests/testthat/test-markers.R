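# stride duration chosen so one cycle spans exactly 100 samples at
# 200 Hz: the 101-point normalized profile then lands on samples and the
# generative-inverse recovery is exact
trial_spec <- function() exotendon_spec(240, slack_m = 0.115)

test_that("gait cycles are segmented at vertical-position minima", {
  tr <- generate_marker_trial(trial_spec(), stride_duration = 0.5,
                              n_cycles = 8, peak_tension = 150)
  b <- segment_gait_cycles(tr)
  expect_gte(length(b) - 1, 5)
  expect_true(all(abs(diff(b) - 100) <= 1))   # period T +- 1 sample

  # stationary markers: no events
  flat <- marker_trial(tr$time, tr$p1 * 0 + 1, tr$p2 * 0 + 2, 200)
  expect_error(segment_gait_cycles(flat), "cycles")

  # exactly 5 complete cycles are accepted
  tr5 <- generate_marker_trial(trial_spec(), stride_duration = 0.5,
                               n_cycles = 6.2, peak_tension = 150)
  b5 <- segment_gait_cycles(tr5)
  expect_equal(length(b5) - 1, 5L)
  # one fewer complete cycle errors
  tr4 <- generate_marker_trial(trial_spec(), stride_duration = 0.5,
                               n_cycles = 5.1, peak_tension = 150)
  expect_error(segment_gait_cycles(tr4), "cycles")
})

test_that("noiseless marker trials invert to the ground-truth tension", {
  cases <- list(list(spec = trial_spec(), peak = 120),
                list(spec = exotendon_spec(30, slack_m = 0.345),
                     peak = 25))
  for (cs in cases) {
    spec <- cs$spec
    tr <- generate_marker_trial(spec, stride_duration = 0.5,
                                n_cycles = 7, peak_tension = cs$peak,
                                noise_sd = 0)
    out <- tension_from_markers(tr)
    truth <- attr(tr, "truth_profile")
    expect_lt(max(abs(out$mean - truth)), 1e-9)
    expect_lt(max(abs(sweep(out$profiles, 2, truth))), 1e-9)
  }
})

test_that("a never-taut trial yields an identically zero profile", {
  spec <- exotendon_spec(120, slack_m = 0.9)
  tr <- generate_marker_trial(spec, stride_duration = 0.5,
                              peak_tension = 0)
  out <- tension_from_markers(tr)
  # distance touches the slack length exactly between dips; allow float
  # rounding at that boundary
  expect_lt(max(abs(out$mean)), 1e-9)
  expect_lt(out$peak, 1e-9)
})

test_that("tension pipeline equals the pointwise scalar law", {
  spec <- trial_spec()
  tr <- generate_marker_trial(spec, stride_duration = 0.5,
                              n_cycles = 6, peak_tension = 180,
                              noise_sd = 0.002, seed = 4)
  out <- tension_from_markers(tr)
  d <- sqrt(rowSums((tr$p1 - tr$p2)^2))
  expect_lt(max(abs(out$tension -
                      spec$stiffness * pmax(0, d - spec$slack_m))), 1e-12)
})

test_that("marker noise perturbs the peak within the propagation bound", {
  spec <- trial_spec()
  sigma <- 0.002
  clean <- tension_from_markers(generate_marker_trial(
    spec, stride_duration = 0.5, n_cycles = 8, peak_tension = 150))
  set.seed(9)
  peaks <- replicate(40, {
    tr <- generate_marker_trial(spec, stride_duration = 0.5,
                                n_cycles = 8, peak_tension = 150,
                                noise_sd = sigma,
                                seed = sample.int(1e6, 1))
    tension_from_markers(tr)$peak
  })
  # pointwise part: k amplifies the distance noise (SD ~ sqrt(2) sigma
  # per axis pair); plus a small peak-smearing allowance from noise in
  # the foot-strike segmentation (one-sample cycle jitter)
  bound <- 4 * spec$stiffness * sqrt(2 * 3) * sigma + 0.04 * clean$peak
  expect_lt(max(abs(peaks - clean$peak)), bound)
})

test_that("gaps are bridged up to 5 samples, longer gaps drop cycles", {
  spec <- trial_spec()
  tr <- generate_marker_trial(spec, stride_duration = 0.5, n_cycles = 7,
                              peak_tension = 150)
  # short gap: interpolated, all cycles kept
  tr_short <- tr; tr_short$p1[250:253, ] <- NA
  out_s <- tension_from_markers(tr_short)
  expect_equal(out_s$dropped_cycles, 0L)
  # long gap: the containing cycle is dropped
  tr_long <- tr; tr_long$p1[250:280, ] <- NA
  out_l <- tension_from_markers(tr_long)
  expect_gte(out_l$dropped_cycles, 1L)
  expect_equal(nrow(out_l$profiles), nrow(out_s$profiles) - out_l$dropped_cycles)
})

test_that("group averaging is cycle-then-runner", {
  spec <- trial_spec()
  r1 <- tension_from_markers(generate_marker_trial(
    spec, stride_duration = 0.5, peak_tension = 100))
  r2 <- tension_from_markers(generate_marker_trial(
    spec, stride_duration = 0.5, peak_tension = 200))
  g <- group_tension_profile(list(r1, r2))
  expect_equal(g$mean, (r1$mean + r2$mean) / 2, tolerance = 1e-12)
  expect_equal(g$peak, max(g$mean))
})
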