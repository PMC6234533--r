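# The statistics layer: RMS error, zero-lag cross-correlation, range of
# motion, subject-level bootstrap confidence bands, polynomial error-decay
# fits, the 5-degree equivalence procedure and walking-speed comparisons.

#' Analysis threshold constants
#'
#' The fixed thresholds used throughout the equivalence analysis: the
#' kinematic-uncertainty threshold attributable to soft-tissue artifact
#' (5 degrees), the cross-correlation cutoff below which curve shapes are
#' considered substantially different (0.90), and the test level (0.05,
#' with no multiple-comparison correction).
#'
#' @return Named list `equiv_threshold_deg`, `r_xy_cutoff`, `alpha`.
#' @export
kin_constants <- function() {
  list(equiv_threshold_deg = 5, r_xy_cutoff = 0.90, alpha = 0.05)
}

#' Root-mean-square error between two cycle curves
#'
#' @param curve,reference numeric vectors (or `gait_curve`s) on the same
#'   grid and in the same units.
#' @return RMS of the pointwise difference.
#' @export
rms_error <- function(curve, reference) {
  x <- curve_values(curve); y <- curve_values(reference)
  ux <- if (inherits(curve, "gait_curve")) curve$units else NULL
  uy <- if (inherits(reference, "gait_curve")) reference$units else NULL
  if (!is.null(ux) && !is.null(uy) && !identical(ux, uy))
    stop(sprintf("unit mismatch: %s vs %s", ux, uy))
  if (length(x) != length(y)) stop("curves must share one grid")
  sqrt(mean((x - y)^2))
}

#' Zero-lag cross-correlation of two cycle curves
#'
#' Pearson correlation of the mean-centered curves on a shared phase grid
#' (the curves are already phase-aligned by heel-strike normalization).
#' With `max_lag_frac > 0`, returns instead the maximum correlation over
#' circular lags of up to that fraction of the cycle.
#'
#' @param curve,reference numeric vectors (or `gait_curve`s), same grid.
#' @param max_lag_frac optional maximum lag as a fraction of the cycle
#'   (default 0: zero-lag).
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
cross_correlation <- function(curve, reference, max_lag_frac = 0) {
  x <- curve_values(curve); y <- curve_values(reference)
  if (length(x) != length(y)) stop("curves must share one grid")
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined correlation: an input has zero variance")
  if (max_lag_frac <= 0) return(stats::cor(x, y))
  n <- length(x)
  lags <- -round(max_lag_frac * n):round(max_lag_frac * n)
  max(vapply(lags, function(l) {
    xi <- if (l == 0) x else if (l > 0) c(x[-seq_len(l)], x[seq_len(l)]) else
      c(x[(n + l + 1):n], x[seq_len(n + l)])
    stats::cor(xi, y)
  }, numeric(1)))
}

#' Extremes and range of motion of a cycle curve
#'
#' @param curve numeric vector or `gait_curve`.
#' @return Named numeric `max`, `min`, `range` (max - min).
#' @export
rom_and_peaks <- function(curve) {
  x <- curve_values(curve)
  if (!length(x)) stop("empty curve")
  c(max = max(x), min = min(x), range = max(x) - min(x))
}

#' Subject-level bootstrap confidence band for a mean gait curve
#'
#' Resamples subjects with replacement and forms the pointwise interval of
#' the resampled grand-mean curves: `percentile` (default) or `bca`
#' (bias-corrected and accelerated, using jackknife acceleration)
#' intervals. Deterministic given the seed.
#'
#' @param subject_curves `subjects x points` matrix, one (already
#'   stride-averaged) curve per subject.
#' @param n_boot number of bootstrap resamples (default 2000).
#' @param level confidence level (default 0.95).
#' @param seed RNG seed.
#' @param type `"percentile"` or `"bca"`.
#' @return List with `lower`, `upper`, `mean` (length = points).
#' @export
bootstrap_band <- function(subject_curves, n_boot = 2000, level = 0.95,
                           seed = 1, type = c("percentile", "bca")) {
  type <- match.arg(type)
  m <- as.matrix(subject_curves)
  n <- nrow(m)
  if (n < 2) stop("bootstrap requires at least 2 subjects")
  set.seed(seed)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n_boot, n)
  boots <- matrix(0, n_boot, ncol(m))
  for (b in seq_len(n_boot))
    boots[b, ] <- colMeans(m[idx[b, ], , drop = FALSE])
  a <- (1 - level) / 2
  if (type == "percentile") {
    lower <- apply(boots, 2, quantile, probs = a, names = FALSE)
    upper <- apply(boots, 2, quantile, probs = 1 - a, names = FALSE)
  } else {
    gm <- colMeans(m)
    jack <- t(vapply(seq_len(n), function(i)
      colMeans(m[-i, , drop = FALSE]), numeric(ncol(m))))
    lower <- numeric(ncol(m)); upper <- numeric(ncol(m))
    for (p in seq_len(ncol(m))) {
      if (sd(boots[, p]) == 0) { lower[p] <- upper[p] <- gm[p]; next }
      z0 <- stats::qnorm(mean(boots[, p] < gm[p]))
      jm <- mean(jack[, p]) - jack[, p]
      acc <- sum(jm^3) / (6 * max(sum(jm^2), 1e-300)^1.5)
      q1 <- stats::pnorm(z0 + (z0 + stats::qnorm(a)) / (1 - acc * (z0 + stats::qnorm(a))))
      q2 <- stats::pnorm(z0 + (z0 + stats::qnorm(1 - a)) / (1 - acc * (z0 + stats::qnorm(1 - a))))
      lower[p] <- quantile(boots[, p], q1, names = FALSE)
      upper[p] <- quantile(boots[, p], q2, names = FALSE)
    }
  }
  list(lower = lower, upper = upper, mean = colMeans(m))
}

#' Polynomial fit of kinematic error versus marker count
#'
#' Ordinary least-squares polynomial of the given order for mean RMS error
#' as a function of the number of included thigh/shank markers (0-8), with
#' the coefficient of determination. For a zero-variance response R^2 is
#' defined as 0.
#'
#' @param counts numeric marker counts.
#' @param rms mean RMS error at each count.
#' @param order polynomial order (1 = linear, 3 = cubic).
#' @return List with `coefficients` (intercept first), `r_squared`,
#'   `fitted`.
#' @export
fit_error_decay <- function(counts, rms, order = 3) {
  if (length(unique(counts)) < order + 2)
    stop("need at least order + 2 distinct marker counts")
  fit <- lm(rms ~ poly(counts, order, raw = TRUE))
  tss <- sum((rms - mean(rms))^2)
  r2 <- if (tss <= 0) 0 else 1 - sum(stats::residuals(fit)^2) / tss
  list(coefficients = unname(coef(fit)), r_squared = r2,
       fitted = unname(stats::fitted(fit)))
}

#' Five-degree equivalence test between marker sets
#'
#' Implements the equivalence procedure: peak and range-of-motion
#' differences between a candidate condition and the reference are
#' compared on group means against the 5-degree soft-tissue-artifact
#' uncertainty threshold; only flagged differences are tested with
#' two-sided paired t-tests (no multiple-comparison correction). A
#' coordinate is labelled high fidelity when no summary exceeds the
#' threshold and its curve correlation exceeds the cutoff.
#'
#' @param summaries,ref_summaries data.frames with columns `subject`,
#'   `coordinate`, `metric` (e.g. `peak_max`, `peak_min`, `rom`) and
#'   `value` (degrees); rows paired by subject/coordinate/metric.
#' @param r_xy named per-coordinate curve correlations vs the reference.
#' @param constants threshold constants, see [kin_constants()].
#' @return List with `table` (per coordinate x metric: group-mean delta,
#'   `exceeds` flag, `p` for flagged rows) and `fidelity` (per
#'   coordinate: `high_fidelity` logical).
#' @export
equivalence_test <- function(summaries, ref_summaries, r_xy,
                             constants = kin_constants()) {
  key <- c("subject", "coordinate", "metric")
  mg <- merge(summaries, ref_summaries, by = key,
              suffixes = c("", "_ref"))
  if (nrow(mg) != nrow(summaries))
    stop("unpaired inputs: subject/coordinate/metric rows do not match")
  mg$delta <- mg$value - mg$value_ref
  rows <- list()
  for (co in unique(mg$coordinate)) {
    for (me in unique(mg$metric[mg$coordinate == co])) {
      d <- mg$delta[mg$coordinate == co & mg$metric == me]
      mean_d <- mean(d)
      exceeds <- abs(mean_d) > constants$equiv_threshold_deg
      p <- NA_real_
      if (exceeds) {
        # a (numerically) constant nonzero shift underflows the t statistic
        p <- if (sd(d) < 1e-9 * max(1, abs(mean_d))) .Machine$double.xmin else
          t.test(d, mu = 0)$p.value
      }
      rows[[length(rows) + 1]] <- data.frame(
        coordinate = co, metric = me, mean_delta_deg = mean_d,
        exceeds = exceeds, p = p)
    }
  }
  tab <- do.call(rbind, rows)
  fid <- vapply(unique(tab$coordinate), function(co) {
    !any(tab$exceeds[tab$coordinate == co]) &&
      isTRUE(r_xy[[co]] > constants$r_xy_cutoff)
  }, logical(1))
  list(table = tab,
       fidelity = data.frame(coordinate = unique(tab$coordinate),
                             high_fidelity = unname(fid)))
}

#' Walking-speed comparison of joint excursions
#'
#' Paired t-tests of range of motion between walking speeds
#' (slow-moderate, slow-fast, moderate-fast) per coordinate and marker
#' set, without multiple-comparison correction. Significance markers
#' follow the convention: `s` = greater than slow, `m` = greater than
#' moderate.
#'
#' @param rom data.frame with columns `subject`, `speed` (numeric m/s),
#'   `coordinate`, optionally `marker_set`, and `rom` (degrees); every
#'   subject must appear at every speed.
#' @param constants see [kin_constants()].
#' @return data.frame per coordinate (x marker_set) x speed: group mean,
#'   bootstrap 95% CI, and the significance marker string.
#' @export
speed_comparison <- function(rom, constants = kin_constants()) {
  if (!"marker_set" %in% names(rom)) rom$marker_set <- "full"
  speeds <- sort(unique(rom$speed))
  if (length(speeds) != 3) stop("exactly three speeds are expected")
  out <- list()
  for (ms in unique(rom$marker_set)) {
    for (co in unique(rom$coordinate)) {
      sub <- rom[rom$marker_set == ms & rom$coordinate == co, ]
      wide <- stats::reshape(sub[, c("subject", "speed", "rom")],
                             idvar = "subject", timevar = "speed",
                             direction = "wide")
      if (any(!complete.cases(wide)))
        stop("missing cells: every subject needs every speed")
      v <- lapply(speeds, function(s) wide[[paste0("rom.", s)]])
      pt <- function(i, j) t.test(v[[j]], v[[i]], paired = TRUE)$p.value
      p_sm <- pt(1, 2); p_sf <- pt(1, 3); p_mf <- pt(2, 3)
      sig <- c("", "", "")
      if (p_sm < constants$alpha && mean(v[[2]]) > mean(v[[1]])) sig[2] <- "s"
      if (p_sf < constants$alpha && mean(v[[3]]) > mean(v[[1]])) sig[3] <- "s"
      if (p_mf < constants$alpha && mean(v[[3]]) > mean(v[[2]]))
        sig[3] <- paste0(sig[3], "m")
      for (i in seq_along(speeds)) {
        ci <- if (length(v[[i]]) >= 2)
          bootstrap_band(matrix(v[[i]], ncol = 1), n_boot = 2000,
                         seed = 1)[c("lower", "upper")]
        else list(lower = NA, upper = NA)
        out[[length(out) + 1]] <- data.frame(
          marker_set = ms, coordinate = co, speed = speeds[i],
          mean_rom = mean(v[[i]]), ci_lower = ci$lower, ci_upper = ci$upper,
          significance = sig[i],
          p_vs_slow = if (i == 2) p_sm else if (i == 3) p_sf else NA,
          p_vs_moderate = if (i == 3) p_mf else NA)
      }
    }
  }
  do.call(rbind, out)
}
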