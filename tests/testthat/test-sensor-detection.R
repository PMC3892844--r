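make_trace <- function(x, fs = 100, ch = "vert") {
  z <- numeric(length(x))
  if (ch == "vert") accel_trace(z, x, z, fs)
  else accel_trace(x, z, z, fs)
}

test_that("low-pass filter preserves DC and passband, kills stopband", {
  fs <- 100
  t <- seq(0, 10, by = 1 / fs)
  const <- make_trace(rep(0.5, length(t)))
  expect_equal(lowpass_filter(const, 20)$vert, rep(0.5, length(t)))

  # interior amplitude (edges excluded) against the analytic response:
  # a zero-phase 4th-order Butterworth at 20 Hz passes 2 Hz within 1%
  interior <- t > 1 & t < 9
  s2 <- make_trace(sin(2 * pi * 2 * t))
  a2 <- max(abs(lowpass_filter(s2, 20)$vert[interior]))
  expect_gt(a2, 0.99)
  expect_lt(a2, 1.01)

  # and attenuates 40 Hz to below 10%
  s40 <- make_trace(sin(2 * pi * 40 * t))
  a40 <- max(abs(lowpass_filter(s40, 20)$vert[interior]))
  expect_lt(a40, 0.1)

  expect_error(lowpass_filter(s2, 50), "Nyquist")
})

test_that("vertical minima of a pure sinusoid sit at the closed-form times", {
  fs <- 100
  t <- seq(0, 3, by = 1 / fs)
  tr <- make_trace(-cos(2 * pi * 3 * t))
  got <- detect_vertical_minima(tr, detection_config())
  # minima of -cos at t = 0, 1/3, 2/3, ... (endpoint minima unobservable)
  expected <- seq(1 / 3, 3 - 1 / 3, by = 1 / 3)
  expect_equal(length(got), length(expected) + sum(got < 0.2))
  for (e in expected)
    expect_lte(min(abs(got - e)), 0.01 + 1e-9)
})

test_that("detected events match brute-force argmin/argmax per cycle", {
  sim <- simulate_walk(clean_params(n_steps = 15, overlap_time = -0.04))
  cfg <- detection_config()
  filt <- lowpass_filter(sim$trace, cfg$cutoff_hz)
  t <- trace_times(filt)
  vm <- detect_vertical_minima(filt, cfg)
  hs <- detect_heel_strikes(filt, cfg)
  for (k in seq_len(15)) {
    # oracle: exhaustive argmin of the filtered vertical channel over the
    # true cycle window, argmax of AP over the true step window
    w_v <- which(abs(t - sim$truth$vert_min_time[k]) <= 0.12)
    o_v <- t[w_v[which.min(filt$vert[w_v])]]
    expect_lte(min(abs(vm - o_v)), 1e-9)
    w_a <- which(abs(t - sim$truth$heel_strike_time[k]) <= 0.12)
    o_a <- t[w_a[which.max(filt$ap[w_a])]]
    expect_lte(min(abs(hs - o_a)), 1e-9)
    # and both oracles are within one sample of the true event times
    expect_lte(abs(o_a - sim$truth$heel_strike_time[k]), 0.01 + 1e-9)
  }
})

test_that("degenerate channels are rejected or reported", {
  z <- rep(0, 200)
  expect_error(detect_vertical_minima(accel_trace(z, z, z, 100)),
               "no step cycles")
  expect_error(detect_vertical_minima(accel_trace(z, z + 1, z, 100)),
               "no step cycles")
  expect_warning(got <- detect_heel_strikes(accel_trace(z, z, z, 100)),
                 "no heel strikes")
  expect_length(got, 0)
})

test_that("a single AP pulse is located exactly", {
  fs <- 100
  t <- seq(0, 2, by = 1 / fs)
  ap <- numeric(length(t))
  in_p <- abs(t - 1) <= 0.025
  ap[in_p] <- 2 * cos(pi * (t[in_p] - 1) / 0.05)
  tr <- accel_trace(ap, numeric(length(t)), numeric(length(t)), fs)
  got <- detect_heel_strikes(tr, detection_config())
  expect_length(got, 1)
  expect_lte(abs(got - 1), 0.01 + 1e-9)
})

test_that("offset classification is strict at the flight threshold", {
  cfg <- detection_config(flight_threshold = 0.03)
  a <- assess_steps(c(1, 2, 3), c(1.05, 2.00, 3.03), cfg)
  expect_equal(a$offset, c(0.05, 0.00, 0.03))
  # after the threshold -> flight; coincident or exactly at it -> legal
  expect_equal(a$verdict, c("illegal", "legal", "legal"))
})

test_that("unpairable events are excluded, counted, or rejected", {
  cfg <- detection_config()
  # heel strike missing for the middle step: excluded and counted
  a <- assess_steps(c(1, 2, 3), c(1.02, 3.02), cfg)
  expect_equal(nrow(a), 2)
  expect_equal(attr(a, "n_unpaired_minima"), 1L)
  # nothing pairable at all: structured error naming orphans
  expect_error(assess_steps(c(1, 2), c(10, 20), cfg), "orphan")
})

test_that("end-to-end verdicts equal ground truth at zero noise", {
  ov <- mixed_overlaps(30, seed = 4)
  sim <- simulate_walk(gait_params(n_steps = 30, overlap_time = ov,
                                   noise_sd = 0, seed = 4))
  a <- detect_steps(sim$trace)
  expect_equal(nrow(a), 30)
  expect_equal(a$verdict == "illegal", sim$truth$legality == "illegal")
})

test_that("more flight never flips a verdict from illegal to legal", {
  verdicts <- vapply(c(0.02, 0, -0.01, -0.02, -0.04, -0.06), function(ov) {
    sim <- simulate_walk(clean_params(n_steps = 10, overlap_time = ov))
    a <- detect_steps(sim$trace)
    mean(a$verdict == "illegal")
  }, numeric(1))
  expect_true(all(diff(verdicts) >= 0))
})

test_that("verdicts are invariant to DC offset and time translation", {
  sim <- simulate_walk(clean_params(n_steps = 12, overlap_time = -0.03))
  base <- detect_steps(sim$trace)
  shifted <- accel_trace(sim$trace$ap + 0.7, sim$trace$vert + 0.7,
                         sim$trace$ml + 0.7, sim$trace$sample_rate)
  expect_equal(detect_steps(shifted)$verdict, base$verdict)
  translated <- accel_trace(sim$trace$ap, sim$trace$vert, sim$trace$ml,
                            sim$trace$sample_rate, start_time = 100)
  a_tr <- detect_steps(translated)
  expect_equal(a_tr$verdict, base$verdict)
  expect_equal(a_tr$offset, base$offset)
})

test_that("assessments never exceed detected vertical minima", {
  for (seed in 1:3) {
    sim <- simulate_walk(gait_params(n_steps = 15, noise_sd = 0.1,
                                     overlap_time = -0.02, seed = seed))
    cfg <- detection_config()
    filt <- lowpass_filter(sim$trace, cfg$cutoff_hz)
    vm <- detect_vertical_minima(filt, cfg)
    hs <- detect_heel_strikes(filt, cfg)
    a <- assess_steps(vm, hs, cfg)
    expect_lte(nrow(a), length(vm))
  }
})
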