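# TRC marker-trajectory files: the tab-delimited motion-capture exchange
# format with DataRate/NumFrames/Units header rows and X/Y/Z triplets per
# marker. Units are mm internally; metre files are auto-converted.

#' Read a TRC marker file
#'
#' Parses the standard TRC layout (two header-description rows, marker
#' label row, X1/Y1/Z1 row, then `Frame# Time` data). Blank coordinate
#' cells become gaps (`NA` + gap mask). Files in metres are converted to
#' mm with a warning.
#'
#' @param path file path.
#' @return A `marker_trial`.
#' @export
read_trc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6) stop(sprintf("%s: truncated TRC file", path))
  hdr_keys <- strsplit(lines[2], "\t")[[1]]
  hdr_vals <- strsplit(lines[3], "\t")[[1]]
  hdr <- setNames(as.list(hdr_vals), hdr_keys)
  need <- c("DataRate", "NumFrames", "NumMarkers", "Units")
  if (!all(need %in% names(hdr)))
    stop(sprintf("%s: malformed TRC header (line 2/3): need %s", path,
                 paste(setdiff(need, names(hdr)), collapse = ", ")))
  rate <- as.numeric(hdr$DataRate)
  nf <- as.integer(hdr$NumFrames)
  nm <- as.integer(hdr$NumMarkers)
  units <- hdr$Units
  if (!units %in% c("mm", "m"))
    stop(sprintf("%s line 3: unknown units '%s'", path, units))

  labels <- strsplit(lines[4], "\t")[[1]]
  labels <- labels[labels != ""][-(1:2)]  # drop Frame#, Time
  if (length(labels) != nm)
    stop(sprintf("%s line 4: %d labels but NumMarkers = %d", path,
                 length(labels), nm))

  data_lines <- lines[-(1:5)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  if (length(data_lines) != nf)
    stop(sprintf("%s: %d data rows but NumFrames = %d", path,
                 length(data_lines), nf))
  cells <- strsplit(data_lines, "\t")
  ncol_exp <- 2 + 3 * nm
  arr <- array(NA_real_, c(nf, 3, nm),
               dimnames = list(NULL, c("x", "y", "z"), labels))
  for (f in seq_len(nf)) {
    row <- cells[[f]]
    length(row) <- ncol_exp
    vals <- suppressWarnings(as.numeric(row[-(1:2)]))
    arr[f, , ] <- matrix(vals, 3, nm)
  }
  if (units == "m") {
    warning(sprintf("%s: units are m; converting to mm", path))
    arr <- arr * 1000
  }
  marker_trial(arr, rate, meta = list(path = path))
}

#' Write a TRC marker file
#'
#' @param trial a `marker_trial`.
#' @param path output path.
#' @param digits decimal places written (default 5).
#' @return `path`, invisibly.
#' @export
write_trc <- function(trial, path, digits = 5) {
  stopifnot(inherits(trial, "marker_trial"))
  nf <- n_frames(trial)
  nm <- length(trial$labels)
  rate <- trial$rate
  l1 <- sprintf("PathFileType\t4\t(X/Y/Z)\t%s", basename(path))
  l2 <- "DataRate\tCameraRate\tNumFrames\tNumMarkers\tUnits\tOrigDataRate\tOrigDataStartFrame\tOrigNumFrames"
  l3 <- sprintf("%g\t%g\t%d\t%d\tmm\t%g\t1\t%d", rate, rate, nf, nm, rate, nf)
  l4 <- paste(c("Frame#", "Time",
                as.vector(rbind(trial$labels, "", ""))), collapse = "\t")
  l5 <- paste(c("", "", paste0(rep(c("X", "Y", "Z"), nm),
                               rep(seq_len(nm), each = 3))), collapse = "\t")
  fmt <- function(v) ifelse(is.finite(v), formatC(v, format = "f", digits = digits), "")
  body <- vapply(seq_len(nf), function(f) {
    vals <- fmt(as.vector(trial$coords[f, , ]))
    paste(c(f, formatC((f - 1) / rate, format = "f", digits = 5), vals),
          collapse = "\t")
  }, character(1))
  writeLines(c(l1, l2, l3, l4, l5, body), path)
  invisible(path)
}
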