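# ggplot2 autoplot methods for the package's result types. All are
# headless-safe (they return the plot object without drawing).

#' @exportS3Method ggplot2::autoplot
autoplot.psd_tbl <- function(object, ...) {
  ggplot(object, aes(.data$frequency, .data$power)) +
    geom_line() +
    scale_y_log10() +
    labs(x = "frequency (Hz)", y = expression(PSD ~ (units^2 / Hz))) +
    theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.xcorr_tbl <- function(object, ...) {
  ggplot(object, aes(.data$lag, .data$value)) +
    geom_line() +
    geom_vline(xintercept = attr(object, "lag_at_max"), linetype = 2) +
    labs(x = "lag (s)", y = "cross-correlation") +
    theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.coherence_tbl <- function(object, ...) {
  ggplot(object, aes(.data$frequency, .data$coherence)) +
    geom_line() +
    labs(x = "frequency (Hz)", y = expression(gamma^2)) +
    theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.stft_tbl <- function(object, ...) {
  ggplot(object, aes(.data$time, .data$frequency, fill = .data$magnitude)) +
    geom_tile() +
    scale_fill_viridis_c() +
    labs(x = "time (s)", y = "frequency (Hz)") +
    theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.bispec_tbl <- function(object, ...) {
  ggplot(object, aes(.data$f1, .data$f2, fill = .data$magnitude)) +
    geom_tile() +
    scale_fill_viridis_c() +
    labs(x = "f1 (Hz)", y = "f2 (Hz)") +
    theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.msd_tbl <- function(object, ...) {
  ggplot(object, aes(.data$lag, .data$msd)) +
    geom_point() +
    labs(x = "lag (s)", y = "MSD") +
    theme_minimal()
}

#' Plot an MSD fit over its data
#'
#' @param object An `msd_fit`.
#' @param ... Unused.
#' @return A ggplot object: the MSD points with the fitted curve.
#' @exportS3Method ggplot2::autoplot
autoplot.msd_fit <- function(object, ...) {
  d <- object$data
  d$fitted <- object$fitted
  ggplot(d, aes(.data$lag, .data$msd)) +
    geom_point() +
    geom_line(aes(y = .data$fitted), colour = "red") +
    labs(x = "lag (s)", y = "MSD",
         title = sprintf("%s fit, R^2 = %.3f", object$model,
                         object$r_squared)) +
    theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.trajectory_tbl <- function(object, ...) {
  ggplot(object, aes(.data$x, .data$y, colour = factor(.data$particle))) +
    geom_path(show.legend = FALSE) +
    labs(x = "x", y = "y") +
    theme_minimal()
}

#' Plot a stimulus sequence
#'
#' @param object A `stimulus_tbl`.
#' @param log_y Use a log voltage axis (natural for the phi decay).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.stimulus_tbl <- function(object, log_y = FALSE, ...) {
  p <- ggplot(object, aes(.data$step, .data$value)) +
    geom_line() +
    labs(x = "step", y = "voltage (V)") +
    theme_minimal()
  if (log_y) p <- p + scale_y_log10()
  p
}
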