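#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an endogram
#'
#' Median ventilation against median drive per drive bin, with the eupneic
#' reference lines: the curve's height at 100% drive is the passive
#' collapsibility (Vpassive) and its rise above eupnea is the compensation.
#'
#' @param object An `endogram`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot endogram
#' @export
autoplot.endogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$drive_median, y = .data$vent_median)) +
    ggplot2::geom_hline(yintercept = 100, linetype = "dotted", colour = "grey50") +
    ggplot2::geom_vline(xintercept = 100, linetype = "dotted", colour = "grey50") +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_breaths), alpha = 0.6,
                        colour = "#2166ac") +
    ggplot2::scale_size_area(max_size = 3, guide = "none") +
    ggplot2::labs(x = "Ventilatory drive (%eupnea)",
                  y = "Ventilation (%eupnea)", title = "Endogram") +
    ggplot2::theme_minimal()
}

#' Plot ventilation and estimated drive over the night
#'
#' @param object A `drivefit_night` object.
#' @param span Optional numeric `c(from_s, to_s)` to zoom into.
#' @param ... Unused.
#' @return A ggplot of per-breath ventilation and total drive (%eupnea).
#' @method autoplot drivefit_night
#' @export
autoplot.drivefit_night <- function(object, span = NULL, ...) {
  br <- object$breaths
  if (!is.null(span)) {
    br <- br[br$t_start >= span[1] & br$t_start < span[2], ]
  }
  long <- tidyr::pivot_longer(
    dplyr::select(br, "t_start", "ventilation_pct", "total_drive"),
    cols = c("ventilation_pct", "total_drive"),
    names_to = "signal", values_to = "value"
  )
  long$signal <- dplyr::recode(long$signal, ventilation_pct = "ventilation",
                               total_drive = "drive")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t_start / 60, y = .data$value,
                                     colour = .data$signal)) +
    ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = 100, linetype = "dotted", colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(ventilation = "#2166ac", drive = "#b2182b")) +
    ggplot2::labs(x = "Time (min)", y = "%eupnea", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot night traits with confidence intervals
#'
#' @param endotypes An `endotype_set` or night trait tibble.
#' @return A ggplot of trait estimates and 95% bootstrap intervals.
#' @export
plot_traits <- function(endotypes) {
  night <- if (inherits(endotypes, "endotype_set")) endotypes$night else endotypes
  night <- night[!is.na(night$estimate), ]
  ggplot2::ggplot(night, ggplot2::aes(x = .data$trait, y = .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi)) +
    ggplot2::facet_wrap(~ifelse(.data$trait %in% c("lg1", "lgn"),
                                "loop gain", "%eupnea"), scales = "free") +
    ggplot2::labs(x = NULL, y = "estimate (95% CI)") +
    ggplot2::theme_minimal()
}
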