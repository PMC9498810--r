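#' @import ggplot2
NULL

#' Density plot of estimated elongation rates
#'
#' Density of retained per-gene rates with the median marked, mirroring
#' the standard presentation of DRB-release rate distributions (bimodal
#' in real data: a slow class below ~2 kb/min and a fast class around
#' 3.5 kb/min).
#'
#' @param object A `rate_fit` from [estimate_rates()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rate_fit
#' @export
autoplot.rate_fit <- function(object, ...) {
  d <- object$estimates |> filter(.data$retained)
  ggplot(d, aes(x = .data$rate_kb_min)) +
    geom_density(fill = "steelblue", alpha = 0.4) +
    geom_vline(xintercept = median(d$rate_kb_min), linetype = "dashed") +
    labs(x = "elongation rate (kb/min)", y = "density",
         title = sprintf("n = %d retained genes, median %.2f kb/min",
                         nrow(d), median(d$rate_kb_min))) +
    theme_minimal()
}

#' Metagene profile plot
#'
#' @param profile Output of [metagene_profile()].
#' @return A ggplot of mean coverage against distance from the TSS.
#' @export
plot_metagene <- function(profile) {
  ggplot(profile, aes(x = .data$position, y = .data$coverage)) +
    geom_line(color = "steelblue") +
    geom_vline(xintercept = 0, linetype = "dashed") +
    labs(x = "distance from TSS (bp)", y = "mean normalized coverage") +
    theme_minimal()
}

#' Boxplot of a measurement across speed classes
#'
#' @param data Tibble with the measurement, a `speed_class` column and
#'   optionally a `condition` column (used as fill).
#' @param value Column name (string) of the measurement.
#' @param log_scale Plot the y axis on log10 scale?
#' @return A ggplot.
#' @export
plot_class_boxplot <- function(data, value, log_scale = FALSE) {
  p <- ggplot(data, aes(x = .data$speed_class, y = .data[[value]])) +
    labs(x = "elongation speed class", y = value) +
    theme_minimal()
  p <- if ("condition" %in% names(data)) {
    p + geom_boxplot(aes(fill = .data$condition), outlier.shape = NA)
  } else {
    p + geom_boxplot(fill = "steelblue", alpha = 0.4, outlier.shape = NA)
  }
  if (log_scale) p <- p + scale_y_log10()
  p
}
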