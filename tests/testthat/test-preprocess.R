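# Trajectory conditioning and gait-cycle segmentation.

make_trial <- function(xyz_list, rate = 100) marker_trial(xyz_list, rate)

test_that("gap interpolation: identity, cubic reproduction, spline oracle, errors", {
  tt <- seq(0, 2, by = 0.01)
  n <- length(tt)
  traj <- cbind(100 * sin(2 * pi * tt), 50 * cos(2 * pi * tt), tt * 10)
  tr <- make_trial(list(M = traj))
  expect_identical(interpolate_gaps(tr)$coords, tr$coords)

  # cubic polynomial: spline fill is exact
  cub <- cbind(2 + 3 * tt - 4 * tt^2 + tt^3, tt^3, 1 - tt^2)
  tr2 <- make_trial(list(M = cub))
  tr2$coords[50:54, , 1] <- NA
  tr2$gap[50:54, 1] <- TRUE
  filled <- interpolate_gaps(tr2)
  expect_equal(unname(filled$coords[, , 1]), unname(cub), tolerance = 1e-8)
  expect_false(any(filled$gap))

  # sinusoid: against an independent spline fit on the same knots
  tr3 <- make_trial(list(M = traj))
  tr3$coords[80:82, , 1] <- NA
  tr3$gap[80:82, 1] <- TRUE
  filled3 <- interpolate_gaps(tr3)
  obs <- setdiff(seq_len(n), 80:82)
  for (d in 1:3) {
    oracle <- splinefun(obs, traj[obs, d], method = "fmm")(80:82)
    expect_equal(unname(filled3$coords[80:82, d, 1]), oracle, tolerance = 1e-9)
  }

  tr4 <- make_trial(list(M = traj))
  tr4$coords[30:45, , 1] <- NA
  tr4$gap[30:45, 1] <- TRUE
  expect_error(interpolate_gaps(tr4, max_gap = 10), "exceeds max_gap")
  tr5 <- make_trial(list(M = traj))
  tr5$coords[1:3, , 1] <- NA
  tr5$gap[1:3, 1] <- TRUE
  expect_error(interpolate_gaps(tr5), "boundary")
})

test_that("low-pass filter: DC exact, passband flat, stopband suppressed", {
  tt <- seq(0, 10, by = 0.01)
  const <- make_trial(list(M = cbind(rep(123.4, length(tt)), -7, 0.02)))
  expect_equal(lowpass_filter(const)$coords, const$coords, tolerance = 1e-9)

  sine <- function(f) sin(2 * pi * f * tt)
  tr1 <- make_trial(list(M = cbind(sine(1), sine(1), sine(1))))
  y1 <- lowpass_filter(tr1)$coords[, 1, 1]
  core <- 150:(length(tt) - 150)
  amp1 <- max(abs(y1[core]))
  expect_gt(amp1, 0.99)

  tr30 <- make_trial(list(M = cbind(sine(30), sine(30), sine(30))))
  y30 <- lowpass_filter(tr30)$coords[, 1, 1]
  expect_lt(max(abs(y30[core])), 0.05)

  # gaps must be filled first; rate must exceed 2x cutoff
  trg <- make_trial(list(M = cbind(sine(1), sine(1), sine(1))))
  trg$gap[10, 1] <- TRUE
  expect_error(lowpass_filter(trg), "gaps")
  slow <- marker_trial(list(M = cbind(sine(1), sine(1), sine(1))), rate = 10)
  expect_error(lowpass_filter(slow), "twice the cutoff")
})

test_that("conditioning commutes with global translation", {
  tt <- seq(0, 3, by = 0.01)
  traj <- cbind(90 * sin(2 * pi * tt) + rnorm(length(tt), 0, 2),
                40 * cos(2 * pi * tt), 5 * tt)
  tr <- make_trial(list(M = traj))
  tr$coords[100:103, , 1] <- NA
  tr$gap[100:103, 1] <- TRUE
  shift <- c(500, -200, 75)
  tr_s <- tr
  tr_s$coords <- tr$coords + rep(shift, each = length(tt))
  a <- lowpass_filter(interpolate_gaps(tr))
  b <- lowpass_filter(interpolate_gaps(tr_s))
  expect_equal(b$coords, a$coords + rep(shift, each = length(tt)),
               tolerance = 1e-6)
})

test_that("heel strikes are recovered from synthetic gait", {
  fx <- fixture_artifact()
  tr <- fx$filtered
  for (side in c("R", "L")) {
    hs <- detect_heel_strikes(tr, side)
    truth <- fx$gt$truth$events[[side]]
    d <- vapply(truth, function(e) min(abs(hs$events - e)), numeric(1))
    expect_gte(mean(d <= 1), 0.95)
    expect_lt(abs(length(hs$events) - length(truth)), 3)
  }
})

test_that("median detected stride duration matches the configured cadence", {
  subj <- generate_subject(9)
  gt <- generate_trial(subj, 1.2, duration_s = 30, artifact = NULL,
                       noise_sd = 0, seed = 5, stride_jitter_sd = 0)
  hs <- detect_heel_strikes(gt$trial, "R")
  T_expect <- stride_time(gait_template(), 1.2)
  expect_lt(abs(median(diff(hs$events)) / gt$trial$rate - T_expect),
            1 / gt$trial$rate + 1e-9)
})

test_that("constant markers raise a detection failure", {
  n <- 500
  tr <- make_trial(list(R.Heel = matrix(rep(c(1, 2, 3), each = n), n),
                        R.PSIS = matrix(rep(c(0, 0, 0), each = n), n),
                        L.PSIS = matrix(rep(c(0, 0, 1), each = n), n)))
  expect_error(detect_heel_strikes(tr, "R"), "detection failure")
})

test_that("time normalization: constants, identity resampling, mirror symmetry", {
  strides <- cbind(1, 101)
  expect_equal(curve_values(time_normalize(rep(7.5, 101), strides)),
               rep(7.5, 101))
  x <- sin(seq(0, 2 * pi, length.out = 101))
  expect_equal(curve_values(time_normalize(x, strides)), x, tolerance = 1e-12)
  # two mirror-image strides about a constant average to that constant
  x2 <- c(5 + sin(seq(0, 2 * pi, length.out = 101)),
          5 - sin(seq(0, 2 * pi, length.out = 101)))
  gc <- time_normalize(x2, rbind(c(1, 101), c(102, 202)))
  expect_equal(curve_values(gc), rep(5, 101), tolerance = 1e-9)
  expect_equal(gc$n_strides, 2)
  expect_error(time_normalize(x, matrix(numeric(0), 0, 2)), "stride")
})

test_that("a two-minute trial yields the expected stride count", {
  subj <- generate_subject(31)
  gt <- generate_trial(subj, 1.2, duration_s = 120, artifact = NULL,
                       noise_sd = 0.3, seed = 8)
  expect_gte(length(gt$truth$events$R), 100)
  expect_lte(length(gt$truth$events$R), 112)
  hs <- detect_heel_strikes(lowpass_filter(gt$trial), "R")
  expect_lte(abs(length(hs$events) - length(gt$truth$events$R)), 3)
})
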