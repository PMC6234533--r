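# Trajectory conditioning (gap interpolation, zero-phase low-pass
# filtering) and gait-cycle segmentation from kinematic heel-strike events.

#' Fill marker gaps by cubic-spline interpolation
#'
#' Fills gaps of at most `max_gap` frames per marker and coordinate with a
#' cubic spline fitted through the observed samples. Observed samples are
#' unchanged; the gap mask is cleared for filled frames. Gaps at the start
#' or end of a trajectory (nothing to interpolate against on one side) and
#' gaps longer than `max_gap` are errors.
#'
#' @param trial a `marker_trial`.
#' @param max_gap longest fillable gap, in frames (default 10).
#' @return A new `marker_trial` with gaps filled.
#' @export
interpolate_gaps <- function(trial, max_gap = 10) {
  stopifnot(inherits(trial, "marker_trial"))
  out <- trial
  nf <- n_frames(trial)
  for (lab in trial$labels) {
    g <- trial$gap[, lab]
    if (!any(g)) next
    runs <- rle(g)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    for (i in which(runs$values)) {
      if (starts[i] == 1 || ends[i] == nf)
        stop(sprintf("marker %s: gap at trial boundary (frames %d-%d) cannot be interpolated",
                     lab, starts[i], ends[i]))
      if (runs$lengths[i] > max_gap)
        stop(sprintf("marker %s: gap of %d frames (frames %d-%d) exceeds max_gap = %d",
                     lab, runs$lengths[i], starts[i], ends[i], max_gap))
    }
    obs <- which(!g)
    for (d in 1:3) {
      f <- splinefun(obs, trial$coords[obs, d, lab], method = "fmm")
      out$coords[g, d, lab] <- f(which(g))
    }
    out$gap[, lab] <- FALSE
  }
  out
}

# zero-phase Butterworth with odd-reflection padding; mean-centered so a
# constant trajectory passes through exactly
zero_phase_lowpass <- function(x, rate, cutoff, order) {
  n <- length(x)
  mu <- mean(x)
  xc <- x - mu
  pad <- min(n - 1, max(3 * order, ceiling(3 * rate / cutoff)))
  left <- 2 * xc[1] - xc[(pad + 1):2]
  right <- 2 * xc[n] - xc[(n - 1):(n - pad)]
  xp <- c(left, xc, right)
  bf <- signal::butter(order, 2 * cutoff / rate, type = "low")
  yp <- signal::filtfilt(bf, xp)
  yp[(pad + 1):(pad + n)] + mu
}

#' Zero-phase low-pass filter marker trajectories
#'
#' Applies a zero-phase (forward-backward) Butterworth low-pass filter to
#' each coordinate of each marker. Gaps must be filled first. The filter is
#' run on odd-reflection-padded, mean-centered data so that trial edges are
#' well behaved and the trajectory mean is preserved.
#'
#' @param trial a gap-free `marker_trial`.
#' @param cutoff low-pass cutoff frequency (Hz; default 6, the gait-lab
#'   standard for walking).
#' @param order Butterworth order before the forward-backward pass
#'   (default 4).
#' @return A filtered `marker_trial` of identical dimensions.
#' @export
lowpass_filter <- function(trial, cutoff = 6, order = 4) {
  stopifnot(inherits(trial, "marker_trial"))
  if (any(trial$gap))
    stop("trial has unfilled gaps; run interpolate_gaps() first")
  if (trial$rate <= 2 * cutoff)
    stop("frame rate must exceed twice the cutoff frequency")
  out <- trial
  for (lab in trial$labels)
    for (d in 1:3)
      out$coords[, d, lab] <- zero_phase_lowpass(trial$coords[, d, lab],
                                                 trial$rate, cutoff, order)
  out
}

#' Detect heel strikes from heel anterior displacement
#'
#' Treadmill-gait event detection: heel strikes are local maxima of the
#' anterior (X) displacement of the heel marker relative to the pelvis
#' origin (sacrum proxy: the PSIS midpoint). The dominant stride period is
#' estimated from the autocorrelation of that signal; candidate maxima are
#' thinned with a minimum separation of `min_sep_frac` times the period and
#' strides outside a plausibility band of durations are discarded.
#'
#' @param trial a filtered, gap-free `marker_trial`.
#' @param side `"R"` or `"L"`.
#' @param min_sep_frac minimum peak separation as a fraction of the
#'   estimated stride period (default 0.4).
#' @param duration_band plausible stride-duration range in seconds
#'   (default `c(0.6, 2.5)`).
#' @return A `stride_index`: list with `events` (heel-strike frame
#'   indices), `strides` (two-column matrix of start/end frames of
#'   plausible strides), `side` and `rate`.
#' @export
detect_heel_strikes <- function(trial, side = c("R", "L"),
                                min_sep_frac = 0.4,
                                duration_band = c(0.6, 2.5)) {
  side <- match.arg(side)
  heel <- trial_marker(trial, paste0(side, ".Heel"))
  sacrum_x <- (trial_marker(trial, "R.PSIS")[, 1] +
                 trial_marker(trial, "L.PSIS")[, 1]) / 2
  x <- heel[, 1] - sacrum_x
  n <- length(x)
  if (sd(x) < 1e-6)
    stop("heel-strike detection failure: no anterior heel motion")

  # dominant stride period from the autocorrelation peak beyond 0.4 s
  lag_max <- min(n - 1, round(3 * trial$rate))
  a <- acf(x, lag.max = lag_max, plot = FALSE)$acf[, 1, 1]
  lo <- max(3, round(0.4 * trial$rate))
  cand <- which(diff(sign(diff(a))) == -2) + 1
  cand <- cand[cand >= lo]
  if (!length(cand))
    stop("heel-strike detection failure: no periodicity found")
  period <- cand[which.max(a[cand])] - 1

  peaks <- which(diff(sign(diff(x))) == -2) + 1
  if (length(peaks) < 2)
    stop("heel-strike detection failure: fewer than 2 candidate events")
  # greedy thinning, tallest first
  keep <- integer(0)
  for (p in peaks[order(x[peaks], decreasing = TRUE)])
    if (!length(keep) || all(abs(keep - p) >= min_sep_frac * period))
      keep <- c(keep, p)
  events <- sort(keep)

  dur <- diff(events) / trial$rate
  ok <- dur >= duration_band[1] & dur <= duration_band[2]
  strides <- cbind(start = events[-length(events)][ok], end = events[-1][ok])
  if (length(events) < 2)
    stop("heel-strike detection failure: fewer than 2 events")
  structure(list(events = events, strides = strides, side = side,
                 rate = trial$rate), class = "stride_index")
}

#' @export
print.stride_index <- function(x, ...) {
  cat(sprintf("<stride_index> side %s: %d events, %d plausible strides, median %.3f s\n",
              x$side, length(x$events), nrow(x$strides),
              median(diff(x$events)) / x$rate))
  invisible(x)
}

#' Time-normalize per-stride curves to the gait cycle
#'
#' Resamples a per-frame signal to `n_points` points over each 0-100% gait
#' cycle (linear interpolation on a uniform phase grid) and averages over
#' strides.
#'
#' @param x numeric vector (one value per frame) or `frames x k` matrix.
#' @param strides a `stride_index`, or a two-column matrix of stride
#'   start/end frames.
#' @param n_points grid length (default 101, i.e. 0, 1, ..., 100% of the
#'   cycle).
#' @param name,units optional curve metadata.
#' @return A `gait_curve`: list with `values` (length `n_points` vector or
#'   `n_points x k` matrix, the stride mean), `per_stride` (strides x
#'   n_points x k array), `n_strides`, `name`, `units`.
#' @export
time_normalize <- function(x, strides, n_points = 101, name = NULL,
                           units = NULL) {
  if (inherits(strides, "stride_index")) strides <- strides$strides
  if (is.null(dim(strides))) strides <- matrix(strides, ncol = 2)
  if (nrow(strides) < 1) stop("at least one complete stride is required")
  xm <- if (is.null(dim(x))) matrix(x, ncol = 1) else as.matrix(x)
  k <- ncol(xm)
  phase <- seq(0, 1, length.out = n_points)
  per <- array(NA_real_, c(nrow(strides), n_points, k))
  for (i in seq_len(nrow(strides))) {
    at <- strides[i, 1] + phase * (strides[i, 2] - strides[i, 1])
    fr <- seq(floor(strides[i, 1]), ceiling(strides[i, 2]))  # boundaries may be fractional
    for (d in seq_len(k))
      per[i, , d] <- approx(fr, xm[fr, d], xout = at)$y
  }
  vals <- apply(per, c(2, 3), mean)
  if (k == 1) vals <- drop(vals)
  structure(list(values = vals, per_stride = per,
                 n_strides = nrow(strides), n_points = n_points,
                 name = name, units = units), class = "gait_curve")
}

#' @export
print.gait_curve <- function(x, ...) {
  cat(sprintf("<gait_curve>%s %d points, mean of %d strides%s\n",
              if (is.null(x$name)) "" else paste0(" ", x$name),
              x$n_points, x$n_strides,
              if (is.null(x$units)) "" else paste0(" (", x$units, ")")))
  invisible(x)
}

# numeric values from a gait_curve or plain vector
curve_values <- function(x) {
  if (inherits(x, "gait_curve")) x$values else x
}
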