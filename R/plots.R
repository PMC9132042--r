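#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an electrophysiology trace
#'
#' @param object An `"ephys_trace"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ephys_trace <- function(object, ...) {
  vc <- attr(object, "value_col") %||% "current"
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data[[vc]])) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (ms)",
                  y = paste0(vc, " (", attr(object, "unit"), ")"),
                  title = attr(object, "condition")) +
    ggplot2::theme_minimal()
  st <- stim_times(object)
  if (length(st)) {
    p <- p + ggplot2::geom_vline(xintercept = st, linetype = "dotted",
                                 colour = "grey50")
  }
  p
}

#' Plot the volume-averaged hotspot transporter current
#'
#' @param object A `"hotspot_sim"`.
#' @param ... Unused.
#' @return A ggplot of the hotspot current around the glutamate bolus.
#' @export
autoplot.hotspot_sim <- function(object, ...) {
  autoplot(object$hotspot) +
    ggplot2::labs(title = sprintf("hotspot I_GluT (%s)",
                                  if (is.null(object$clamp)) "free V"
                                  else sprintf("clamped %g mV", object$clamp)),
                  y = "I_GluT (pA/um2)")
}

#' Plot paired peak currents along the distance profile
#'
#' @param object A `"distance_profile"`.
#' @param ... Unused.
#' @return A ggplot with baseline and elevated-K peaks per site.
#' @export
autoplot.distance_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("distance", "peak_baseline", "peak_elevated")],
    cols = c("peak_baseline", "peak_elevated"),
    names_to = "condition", values_to = "peak", names_prefix = "peak_")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$distance, y = .data$peak,
                                     colour = .data$condition)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::labs(x = "distance from soma (um)",
                  y = "peak I_GluT density (pA/um2)") +
    ggplot2::theme_minimal()
}

#' Plot a facilitation profile
#'
#' @param object A `"facilitation_profile"`.
#' @param ... Unused.
#' @return A ggplot of normalized peak amplitude per stimulus.
#' @export
autoplot.facilitation_profile <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$stim, y = .data$norm_amplitude)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$flagged)) +
    ggplot2::labs(x = "stimulus #", y = "normalized I_GluT amplitude") +
    ggplot2::theme_minimal()
}
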