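test_that("perfect and pure-offset pairings give degenerate agreement", {
  x <- c(-0.02, 0, 0.01, 0.03, 0.05)
  same <- data.frame(camera = x, sensor = x)
  r <- agreement(same)
  expect_equal(r$pearson_r, 1)
  expect_equal(r$tee, 0)
  expect_equal(r$bias_mean, 0)

  off <- data.frame(camera = x, sensor = x + 0.02)
  r2 <- agreement(off)
  expect_equal(r2$bias_mean, 0.02)
  expect_equal(r2$tee, 0)
  expect_equal(r2$pearson_r, 1)
})

test_that("agreement matches the frozen brute-force least-squares oracle", {
  # 5-point fixture; expected values computed by closed-form OLS
  # (normal equations by hand) and chi-square limits, frozen here
  pairs <- data.frame(camera = c(0.00, 0.02, -0.04, 0.05, -0.01),
                      sensor = c(0.01, 0.05, -0.02, 0.04, 0.02))
  r <- agreement(pairs)
  expect_equal(r$n, 5L)
  expect_equal(r$pearson_r, 0.869000714549709, tolerance = 1e-10)
  expect_equal(r$tee, 0.015647292357213, tolerance = 1e-10)
  expect_equal(r$tee_lower_cl, 0.008864027552990, tolerance = 1e-10)
  expect_equal(r$tee_upper_cl, 0.058341669292567, tolerance = 1e-10)
  expect_equal(r$bias_mean, 0.016, tolerance = 1e-10)
  expect_equal(r$bias_sd, 0.016733200530682, tolerance = 1e-10)
  expect_true(r$tee_lower_cl <= r$tee && r$tee <= r$tee_upper_cl)
})

test_that("agreement rejects degenerate input", {
  expect_error(agreement(data.frame(camera = c(1, 2), sensor = c(1, 2))),
               "at least 3")
  expect_error(agreement(data.frame(camera = c(1, 1, 1),
                                    sensor = c(1, 2, 3))), "constant")
  expect_error(agreement(data.frame(camera = c(1, 2, NA),
                                    sensor = c(1, 2, 3))), "finite")
})

test_that("agreement is invariant to step order", {
  set.seed(12)
  pairs <- data.frame(camera = rnorm(30, 0, 0.02),
                      sensor = rnorm(30, 0, 0.02))
  r1 <- agreement(pairs)
  r2 <- agreement(pairs[sample(30), ])
  expect_equal(r1, r2)
})

test_that("TEE shrinks as residual noise shrinks", {
  set.seed(13)
  x <- runif(100, -0.05, 0.05)
  tees <- vapply(c(0.05, 0.02, 0.01, 0), function(sd) {
    agreement(data.frame(camera = x,
                         sensor = x + rnorm(100, 0, sd)))$tee
  }, numeric(1))
  expect_true(all(diff(tees) < c(0, 0, 0) + 1e-12))
  expect_equal(tees[4], 0)
})

test_that("reliability matches the frozen 2x2 ANOVA oracle", {
  # events x repeats {(10,10),(20,22)}; hand decomposition:
  # one-way within-event SS = 2 on 2 df -> typical error 1 frame;
  # two-way MS_event = 121, MS_resid = 1 -> ICC(3,1) = 120/122
  r <- reliability(matrix(c(10, 20, 10, 22), nrow = 2))
  expect_equal(r$typical_error, 1, tolerance = 1e-10)
  expect_equal(r$te_lower_cl, 0.520658266698817, tolerance = 1e-10)
  expect_equal(r$te_upper_cl, 6.284734696485383, tolerance = 1e-10)
  expect_equal(r$icc, 120 / 122, tolerance = 1e-10)
})

test_that("reliability degenerate cases behave as defined", {
  # identical repeats across varying events: no within-event error
  m <- matrix(rep(c(10, 20, 35, 50), 3), ncol = 3)
  r <- reliability(m)
  expect_equal(r$typical_error, 0)
  expect_equal(r$icc, 1)

  # constant per-repeat shifts only: consistency ICC stays 1
  m2 <- cbind(c(10, 20, 35, 50), c(12, 22, 37, 52), c(9, 19, 34, 49))
  r2 <- reliability(m2)
  expect_equal(r2$icc, 1)
  expect_gt(r2$typical_error, 0)  # one-way TE sees the shifts

  # zero between-event variance: ICC undefined
  r3 <- reliability(matrix(c(5, 5, 5, 5), nrow = 2))
  expect_true(is.na(r3$icc))

  expect_error(reliability(matrix(1:3, nrow = 1)), "at least 2")
  expect_error(reliability(matrix(c(1, NA, 2, 3), 2)), "ragged")
})

test_that("confusion reproduces the worked 80-step table", {
  pairs <- cells_to_pairs(illegal_agree = 53, illegal_missed = 4,
                          legal_agree = 20, legal_flagged = 3)
  cs <- confusion(pairs)
  expect_equal(cs$illegal_agree, 53)
  expect_equal(cs$illegal_missed, 4)
  expect_equal(cs$legal_agree, 20)
  expect_equal(cs$legal_flagged, 3)
  expect_equal(cs$total, 80)
  expect_equal(cs$accuracy_pct, 91.25)
  expect_equal(round(cs$accuracy_pct), 91)
  expect_equal(cs$illegal_only_pct, 96.25)
})

test_that("confusion handles edge tables and conserves counts", {
  all_agree <- cells_to_pairs(10, 0, 10, 0)
  expect_equal(confusion(all_agree)$accuracy_pct, 100)
  sym <- cells_to_pairs(10, 10, 10, 10)
  expect_equal(confusion(sym)$accuracy_pct, 50)
  # threshold labels pool with legal
  thr <- data.frame(camera_label = c("threshold", "threshold", "illegal"),
                    sensor_verdict = c("legal", "illegal", "illegal"))
  cs <- confusion(thr)
  expect_equal(cs$legal_agree, 1)
  expect_equal(cs$legal_flagged, 1)
  expect_equal(cs$illegal_agree, 1)
  # conservation over random tables
  set.seed(3)
  for (i in 1:5) {
    n <- sample(5:50, 1)
    tab <- data.frame(
      camera_label = sample(c("legal", "illegal", "threshold"), n, TRUE),
      sensor_verdict = sample(c("legal", "illegal"), n, TRUE))
    cs <- confusion(tab)
    expect_equal(cs$illegal_agree + cs$illegal_missed + cs$legal_agree +
                   cs$legal_flagged, n)
  }
  expect_error(confusion(cells_to_pairs(0, 0, 0, 0)), "at least one")
})

test_that("bias_mean recovers a known systematic sensor-camera offset", {
  # simulate with a transmission delay differing from the detection
  # threshold by delta; the agreement bias must recover delta
  delta <- 0.01
  set.seed(21)
  ov <- runif(120, -0.06, -0.02)
  sim <- simulate_walk(gait_params(n_steps = 120, overlap_time = ov,
                                   noise_sd = 0, seed = 21,
                                   transmission_delay = 0.03 - delta))
  a <- detect_steps(sim$trace)
  pairs <- compare_steps(label_camera_steps(sim$annotation), a)
  expect_lte(abs(agreement(pairs)$bias_mean - delta), 0.01)
})
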