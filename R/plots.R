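# Optional figures (ggplot2, in Suggests): gait-cycle band plots and
# error-decay box plots.

#' Plot a gait-cycle mean curve with its confidence band
#'
#' @param band list with `mean`, `lower`, `upper` (see
#'   [bootstrap_band()]).
#' @param title,ylab labels.
#' @return A ggplot object.
#' @export
plot_gait_band <- function(band, title = NULL, ylab = "angle (deg)") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  df <- data.frame(cycle = seq(0, 100, length.out = length(band$mean)),
                   mean = band$mean, lower = band$lower, upper = band$upper)
  ggplot2::ggplot(df, ggplot2::aes(x = cycle)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = lower, ymax = upper),
                         fill = "goldenrod", alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = mean)) +
    ggplot2::labs(x = "gait cycle (%)", y = ylab, title = title) +
    ggplot2::theme_minimal()
}

#' Plot RMS error versus included-marker count
#'
#' Box-range plot of sweep errors by marker cardinality with the fitted
#' polynomial decay curve.
#'
#' @param sweep_angles the `angles` data.frame from [run_sweep()].
#' @param coordinate coordinate to plot (default knee flexion).
#' @param fit optional [fit_error_decay()] result to overlay.
#' @return A ggplot object.
#' @export
plot_error_decay <- function(sweep_angles, coordinate = "knee_flexion",
                             fit = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  df <- sweep_angles[sweep_angles$coordinate == coordinate &
                       !sweep_angles$failed, ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = factor(cardinality),
                                        y = rms_deg)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(x = "thigh/shank markers included",
                  y = "RMS error (deg)", title = coordinate) +
    ggplot2::theme_minimal()
  if (!is.null(fit))
    p <- p + ggplot2::geom_line(
      data = data.frame(cardinality = 0:8, rms = fit$fitted),
      ggplot2::aes(x = cardinality + 1, y = rms),
      color = "firebrick")
  p
}

utils::globalVariables(c("cycle", "lower", "upper", "cardinality", "rms_deg", "rms"))
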