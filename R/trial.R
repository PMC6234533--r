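# MarkerTrial container: labeled 3-D trajectories with a frame rate and a
# per-marker gap mask.

#' Create a marker trial
#'
#' Bundles labeled marker trajectories into a trial object. Coordinates are
#' stored as an array `(frames x 3 x markers)` in mm; missing samples are
#' tracked in a per-marker-per-frame gap mask (gaps also hold `NA`
#' coordinates).
#'
#' @param coords either a named list of `frames x 3` matrices or an array
#'   `(frames, 3, markers)` with marker dimnames.
#' @param rate capture frame rate (Hz).
#' @param meta optional list of metadata (subject id, belt speed m/s, ...).
#' @return An object of class `marker_trial` with elements `coords`,
#'   `labels`, `rate`, `gap` (frames x markers logical) and `meta`.
#' @export
marker_trial <- function(coords, rate, meta = list()) {
  if (is.list(coords)) {
    labs <- names(coords)
    nf <- nrow(coords[[1]])
    arr <- array(NA_real_, c(nf, 3, length(coords)),
                 dimnames = list(NULL, c("x", "y", "z"), labs))
    for (i in seq_along(coords)) {
      if (nrow(coords[[i]]) != nf)
        stop("all trajectories must share one frame count")
      arr[, , i] <- as.matrix(coords[[i]])
    }
    coords <- arr
  }
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 3, rate > 0)
  labs <- dimnames(coords)[[3]]
  if (is.null(labs)) stop("markers must be labeled")
  gap <- apply(coords, c(1, 3), function(v) any(!is.finite(v)))
  structure(list(coords = coords, labels = labs, rate = rate,
                 gap = gap, meta = meta),
            class = "marker_trial")
}

#' @export
print.marker_trial <- function(x, ...) {
  cat(sprintf("<marker_trial> %d markers x %d frames @ %g Hz (%.1f s), %d gap samples\n",
              length(x$labels), dim(x$coords)[1], x$rate,
              dim(x$coords)[1] / x$rate, sum(x$gap)))
  invisible(x)
}

#' Extract one marker's trajectory
#' @param trial a `marker_trial`.
#' @param label marker label.
#' @return `frames x 3` matrix (mm).
#' @export
trial_marker <- function(trial, label) {
  if (!label %in% trial$labels) stop(sprintf("unknown marker: %s", label))
  trial$coords[, , label]
}

#' Number of frames in a trial
#' @param trial a `marker_trial`.
#' @return Integer frame count.
#' @export
n_frames <- function(trial) dim(trial$coords)[1]

# trial coords as a 3 x nmark x nframes cube ordered like `labels`
trial_cube <- function(trial, labels) {
  missing <- setdiff(labels, trial$labels)
  sub <- array(NA_real_, c(dim(trial$coords)[1], 3, length(labels)),
               dimnames = list(NULL, NULL, labels))
  for (l in setdiff(labels, missing)) sub[, , l] <- trial$coords[, , l]
  aperm(sub, c(2, 3, 1))
}
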