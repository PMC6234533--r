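# The statistics layer: closed-form cases, bootstrap behaviour, decay
# fits, equivalence and speed comparisons.

grid <- seq(0, 1, length.out = 101)

test_that("rms_error: identity, constant offset, sinusoid closed form", {
  x <- 30 * sin(2 * pi * grid) + 10
  expect_equal(rms_error(x, x), 0)
  expect_equal(rms_error(x + 4.2, x), 4.2, tolerance = 1e-12)
  a <- 7
  expect_equal(rms_error(x + a * sin(2 * pi * grid), x), a / sqrt(2),
               tolerance = 0.02)
  expect_error(rms_error(x, x[1:50]), "grid")
  c1 <- time_normalize(x, cbind(1, 101), name = "a", units = "deg")
  c2 <- time_normalize(x, cbind(1, 101), name = "a", units = "mm")
  expect_error(rms_error(c1, c2), "unit mismatch")
})

test_that("cross_correlation: self, negation, orthogonal sinusoids", {
  x <- sin(2 * pi * grid)
  expect_equal(cross_correlation(x, x), 1)
  expect_equal(cross_correlation(x, -x), -1)
  expect_equal(cross_correlation(sin(2 * pi * grid), cos(2 * pi * grid)), 0,
               tolerance = 0.05)
  expect_error(cross_correlation(rep(1, 101), x), "zero variance")
  # max-lag variant recovers a shifted copy
  y <- sin(2 * pi * (grid - 0.05))
  expect_gt(cross_correlation(x, y, max_lag_frac = 0.1),
            cross_correlation(x, y))
})

test_that("rms/r_xy affine behaviour", {
  x <- 20 * sin(2 * pi * grid) + 5
  y <- x + rnorm(101)
  # RMS depends only on the difference: shared translation cancels
  expect_equal(rms_error(x + 100, y + 100), rms_error(x, y), tolerance = 1e-9)
  # r_xy invariant to positive affine maps of either curve
  expect_equal(cross_correlation(3 * x + 7, y), cross_correlation(x, y),
               tolerance = 1e-12)
})

test_that("rom_and_peaks: constants, constructed range, sampled sinusoid", {
  expect_equal(unname(rom_and_peaks(rep(3.5, 101))), c(3.5, 3.5, 0))
  curve <- 12 + 40 * (sin(2 * pi * grid) + 1) / 2  # range exactly 40
  expect_equal(unname(rom_and_peaks(curve)["range"]), 40, tolerance = 1e-12)
  a <- 9
  expect_equal(unname(rom_and_peaks(a * sin(2 * pi * grid))["range"]), 2 * a,
               tolerance = 2 * a * (1 - cos(pi / 100)) + 1e-9)
  expect_error(rom_and_peaks(numeric(0)), "empty")
})

test_that("bootstrap bands: collapse, determinism, coverage", {
  m <- matrix(rep(sin(2 * pi * grid), 5), 5, byrow = TRUE)
  b <- bootstrap_band(m, n_boot = 200, seed = 1)
  expect_equal(b$lower, b$upper, tolerance = 1e-12)
  expect_equal(b$lower, sin(2 * pi * grid), tolerance = 1e-12)

  set.seed(2)
  m2 <- matrix(rnorm(40 * 101), 40, 101)
  b1 <- bootstrap_band(m2, n_boot = 500, seed = 7)
  b2 <- bootstrap_band(m2, n_boot = 500, seed = 7)
  expect_identical(b1, b2)
  expect_error(bootstrap_band(m2[1, , drop = FALSE]), "2 subjects")

  # pointwise coverage of the true mean (zero) on i.i.d. Gaussian subjects
  set.seed(3)
  nsim <- 60
  cover <- matrix(NA, nsim, 101)
  for (s in seq_len(nsim)) {
    ms <- matrix(rnorm(40 * 101), 40, 101)
    bs <- bootstrap_band(ms, n_boot = 400, seed = s)
    cover[s, ] <- bs$lower <= 0 & bs$upper >= 0
  }
  expect_gt(mean(cover), 0.90)
  expect_lt(mean(cover), 0.99)

  # band width shrinks roughly as 1/sqrt(n)
  widths <- vapply(c(10, 40, 160), function(n) {
    set.seed(4)
    mn <- matrix(rnorm(n * 101), n, 101)
    b <- bootstrap_band(mn, n_boot = 400, seed = 11)
    mean(b$upper - b$lower)
  }, numeric(1))
  slope <- coef(lm(log(widths) ~ log(c(10, 40, 160))))[2]
  expect_lt(abs(slope + 0.5), 0.15)

  # BCa variant also covers the common-curve case
  bca <- bootstrap_band(m2, n_boot = 400, seed = 5, type = "bca")
  expect_true(all(bca$upper >= bca$lower))
})

test_that("fit_error_decay: exact cubic, linear oracle, degenerate variance", {
  counts <- 0:8
  cub <- 5 - 2 * counts + 0.4 * counts^2 - 0.02 * counts^3
  fit <- fit_error_decay(counts, cub, order = 3)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$coefficients, c(5, -2, 0.4, -0.02), tolerance = 1e-9)

  y <- 3 - 0.5 * counts + rnorm(9, 0, 0.1)
  f1 <- fit_error_decay(counts, y, order = 1)
  X <- cbind(1, counts)
  beta <- solve(crossprod(X), crossprod(X, y))  # normal equations oracle
  expect_equal(f1$coefficients, as.vector(beta), tolerance = 1e-9)

  fc <- fit_error_decay(counts, rep(2, 9), order = 2)
  expect_equal(fc$r_squared, 0)
  expect_error(fit_error_decay(0:2, 1:3, order = 3), "distinct")
})

test_that("equivalence test: identity, deterministic shift, null flag rate", {
  subj <- sprintf("s%02d", 1:10)
  mk <- function(vals) data.frame(
    subject = rep(subj, each = 2),
    coordinate = "knee_flexion",
    metric = rep(c("rom", "peak_max"), 10),
    value = vals)
  base <- rnorm(20, 60, 1)
  r1 <- equivalence_test(mk(base), mk(base), r_xy = c(knee_flexion = 1))
  expect_false(any(r1$table$exceeds))
  expect_true(all(is.na(r1$table$p)))
  expect_true(all(r1$fidelity$high_fidelity))

  # 6-degree deterministic shift: flagged, p at the underflow-safe floor
  shifted <- mk(base)
  shifted$value[shifted$metric == "rom"] <-
    shifted$value[shifted$metric == "rom"] + 6
  r2 <- equivalence_test(shifted, mk(base), r_xy = c(knee_flexion = 1))
  rom_row <- r2$table[r2$table$metric == "rom", ]
  expect_true(rom_row$exceeds)
  expect_lte(rom_row$p, 1e-10)
  expect_false(r2$fidelity$high_fidelity)

  # simulated null: flag rate matches the normal tail probability
  set.seed(9)
  nsim <- 2000
  sd_subj <- 4
  n <- 10
  flags <- vapply(seq_len(nsim), function(i) {
    d <- rnorm(n, 0, sd_subj)
    abs(mean(d)) > 5
  }, logical(1))
  p_theory <- 2 * pnorm(-5 / (sd_subj / sqrt(n)))
  expect_equal(mean(flags), p_theory, tolerance = 0.01)
})

test_that("paired t-tests keep their nominal level under the null", {
  set.seed(13)
  nsim <- 1000
  rej <- vapply(seq_len(nsim), function(i) {
    d <- rnorm(10)
    t.test(d)$p.value < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)
})

test_that("speed comparison flags monotone excursions and respects the null", {
  subj <- sprintf("s%02d", 1:10)
  set.seed(21)
  mk_rom <- function(base) do.call(rbind, lapply(c(0.9, 1.2, 1.5), function(v)
    data.frame(subject = subj, speed = v, coordinate = "hip_flexion",
               rom = base(v) + rnorm(10, 0, 0.3))))
  tab <- speed_comparison(mk_rom(function(v) 30 + 10 * v))
  expect_equal(tab$significance[tab$speed == 1.2], "s")
  expect_equal(tab$significance[tab$speed == 1.5], "sm")
  expect_true(all(tab$ci_lower <= tab$mean_rom & tab$mean_rom <= tab$ci_upper))

  flat <- mk_rom(function(v) 40)
  tabf <- speed_comparison(flat)
  expect_equal(tabf$significance[tabf$speed == 0.9], "")

  bad <- mk_rom(function(v) 40)
  bad <- bad[-1, ]
  expect_error(speed_comparison(bad), "missing cells")
})
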