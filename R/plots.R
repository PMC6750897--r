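#' Plot a fitted divergence model over its observations
#'
#' @param object A `"div_fit"` object.
#' @param horizon Right edge of the time axis in Gy (default: data range).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.div_fit <- function(object, horizon = NULL, ...) {
  d <- object$data
  horizon <- horizon %||% max(d$time)
  curve <- tibble::tibble(time = seq(0, horizon, length.out = 200))
  curve$identity <- evaluate_model(object$params, curve$time)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$identity)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = curve, colour = "firebrick") +
    ggplot2::labs(x = "Divergence time (Gy)", y = "Sequence identity (%)",
                  title = sprintf("Model %s fit", object$params$model)) +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::theme_minimal()
}

#' Plot stratified identity-versus-time curves
#'
#' Works on the `binned` table of [fitness_binned_divergence()] or
#' [shell_divergence()].
#'
#' @param binned Tibble with `group`, `time_bin`, `mean_identity` and an
#'   error column (`sd_identity` or `sem_identity`).
#' @param error One of `"sd"`, `"sem"`, `"none"`.
#' @return A ggplot object.
#' @export
plot_site_divergence <- function(binned, error = c("sd", "sem", "none")) {
  error <- match.arg(error)
  d <- binned[!is.na(binned$mean_identity), ]
  d$bin_mid <- bin_midpoints(d$time_bin)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$bin_mid,
                                       y = .data$mean_identity,
                                       colour = .data$group)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "Divergence time (Gy)", y = "Sequence identity (%)",
                  colour = "Site group") +
    ggplot2::theme_minimal()
  err_col <- switch(error, sd = "sd_identity", sem = "sem_identity", none = NULL)
  if (!is.null(err_col) && err_col %in% names(d)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_identity - .data[[err_col]],
                   ymax = .data$mean_identity + .data[[err_col]]),
      width = 0.05)
  }
  p
}

#' Plot the RMSD-versus-time trend
#'
#' @param trend Output of [rmsd_time_trend()].
#' @return A ggplot object showing per-bin medians with 25-75 percentile
#'   ribbons and the moving average.
#' @export
plot_rmsd_trend <- function(trend) {
  b <- trend$bins[!is.na(trend$bins$time_bin), ]
  b$bin_mid <- bin_midpoints(b$time_bin)
  ggplot2::ggplot(b, ggplot2::aes(x = .data$bin_mid)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$median)) +
    ggplot2::geom_line(data = trend$moving_average,
                       ggplot2::aes(x = .data$time, y = .data$rmsd_ma),
                       colour = "firebrick", na.rm = TRUE) +
    ggplot2::labs(x = "Divergence time (Gy)", y = expression(RMSD ~ (ring(A)))) +
    ggplot2::theme_minimal()
}

# midpoints of cut() interval labels
bin_midpoints <- function(bins) {
  lab <- as.character(bins)
  m <- regmatches(lab, gregexpr("-?[0-9.]+(e[+-]?[0-9]+)?", lab))
  vapply(m, function(v) mean(as.numeric(v[1:2])), numeric(1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
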