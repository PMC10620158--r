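# ggplot2 displays for the pipeline's result types.

#' Plot a profile with its detected peaks
#'
#' @param profile Profile tibble (ideally baseline-corrected).
#' @param peaks Optional peak tibble from [detect_peaks()].
#' @return A ggplot object.
#' @export
plot_profile <- function(profile, peaks = NULL) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(.data$position_um, .data$intensity)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = "Distance from wound edge (µm)",
                  y = "Intensity (a.u.)") +
    ggplot2::theme_minimal()
  if (!is.null(peaks) && nrow(peaks) > 0) {
    p <- p + ggplot2::geom_point(data = peaks,
                                 ggplot2::aes(.data$position_um, .data$amplitude),
                                 colour = "red", size = 2)
  }
  p
}

#' Plot per-animal edge ratios by rank and treatment
#'
#' @param animals Output of [aggregate_ratios()].
#' @return A ggplot object: one point per animal, bars at group means.
#' @export
plot_edge_ratios <- function(animals) {
  has_trt <- "treatment" %in% names(animals)
  aes_pt <- if (has_trt) {
    ggplot2::aes(.data$rank, .data$mean_ratio, colour = .data$treatment)
  } else {
    ggplot2::aes(.data$rank, .data$mean_ratio)
  }
  ggplot2::ggplot(animals, aes_pt) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.7) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.5,
                          linewidth = 0.3,
                          position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::labs(x = NULL, y = "Peak intensity / wound-margin peak") +
    ggplot2::theme_minimal()
}

#' @describeIn group_closure_summary Mean +/- SEM closure curves per group.
#' @param object A `closure_summary` tibble.
#' @param ... Ignored.
#' @export
autoplot.closure_summary <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_min, .data$mean,
                                       colour = .data$treatment)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sem,
                                          ymax = .data$mean + .data$sem),
                             size = 0.2) +
    ggplot2::labs(x = "Time (min)", y = "Percent of original wound area") +
    ggplot2::theme_minimal()
}
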