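# Wound-closure kinetics: percent-of-original-area curves, initial closure
# rates, and per-timepoint group summaries.

#' Closure analysis configuration
#'
#' @param frame_interval_s Acquisition interval (default 11 s).
#' @param measure_every_k_frames Measurement cadence: areas are kept every
#'   k-th frame (default 10, i.e. one measurement per 110 s).
#' @param rate_window_min Window for the initial-rate fit (default 10 min,
#'   the phase in which treatment effects on closure are concentrated).
#' @return A list of class `closure_config`.
#' @export
closure_config <- function(frame_interval_s = 11, measure_every_k_frames = 10,
                           rate_window_min = 10) {
  check_positive_scalar(frame_interval_s, "frame_interval_s")
  check_positive_scalar(measure_every_k_frames, "measure_every_k_frames")
  check_positive_scalar(rate_window_min, "rate_window_min")
  structure(list(frame_interval_s = frame_interval_s,
                 measure_every_k_frames = measure_every_k_frames,
                 rate_window_min = rate_window_min),
            class = "closure_config")
}

#' Percent-of-original wound area
#'
#' Resamples the series to every k-th frame, then expresses each area as a
#' percentage of the first measured area. Values above 100 are kept (wounds
#' can transiently expand). Rescaling all areas by a positive constant leaves
#' the percent column unchanged.
#'
#' @param series Tibble with `frame` and `area_mm2` (a `time_s` column is
#'   recomputed from the config if absent).
#' @param config A [closure_config()].
#' @return Tibble `frame`, `time_s`, `time_min`, `area_mm2`,
#'   `percent_of_original`.
#' @export
percent_of_original <- function(series, config = closure_config()) {
  stopifnot(inherits(config, "closure_config"))
  need <- c("frame", "area_mm2")
  missing <- setdiff(need, names(series))
  if (length(missing) > 0L) {
    rlang::abort(sprintf("`series` lacks column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  k <- config$measure_every_k_frames
  out <- series |>
    dplyr::arrange(.data$frame) |>
    dplyr::filter((.data$frame - min(.data$frame)) %% k == 0)
  if (nrow(out) < 2L) {
    rlang::abort(sprintf("Need >= 2 measured frames after resampling every %g frames.", k))
  }
  if (!"time_s" %in% names(out)) {
    out$time_s <- out$frame * config$frame_interval_s
  }
  a0 <- out$area_mm2[1]
  if (a0 <= 0) rlang::abort("First measured area is zero; percent of original is undefined.")
  out |>
    dplyr::mutate(time_min = .data$time_s / 60,
                  percent_of_original = 100 * (.data$area_mm2 / a0)) |>
    dplyr::select("frame", "time_s", "time_min", "area_mm2",
                  "percent_of_original")
}

#' Initial wound-closure rate
#'
#' Least-squares slope of percent-of-original versus time over the first
#' `rate_window_min` minutes; negative for closing wounds, in percentage
#' points per minute. The percent curves remain the primary output — this is
#' a convenience summary of their early phase.
#'
#' @param percent_series Output of [percent_of_original()].
#' @param config A [closure_config()].
#' @return Slope in %/min (a single number).
#' @export
initial_closure_rate <- function(percent_series, config = closure_config()) {
  stopifnot(inherits(config, "closure_config"))
  t0 <- min(percent_series$time_min)
  win <- dplyr::filter(percent_series,
                       .data$time_min <= t0 + config$rate_window_min)
  if (nrow(win) < 3L) {
    rlang::abort(sprintf("Need >= 3 points within the first %g min; got %d.",
                         config$rate_window_min, nrow(win)))
  }
  unname(coef(lm(percent_of_original ~ time_min, data = win))[2])
}

#' Per-timepoint group summary of closure curves
#'
#' Aligns percent curves from several wounds onto a common timepoint grid
#' (nearest-time matching within half a sampling interval), reports mean,
#' SEM and n per treatment at each timepoint, and runs a per-timepoint
#' two-group t test (two treatments) or one-way ANOVA (more than two).
#' Matching the source assay's reporting, the per-timepoint p-values are
#' unadjusted by default; `adjust = "holm"` is available.
#'
#' @param curves Tidy tibble of percent curves: `wound_id`, `treatment`,
#'   `time_min`, `percent_of_original` (one wound = one animal = one
#'   experimental unit).
#' @param adjust `"none"` (default) or `"holm"` across timepoints.
#' @param equal_variance Passed to the per-timepoint t test.
#' @return Tibble with one row per (time, treatment): `time_min`, `treatment`,
#'   `mean`, `sem` (`NA` at n = 1), `n`, and the per-timepoint `statistic`,
#'   `df`, `p_value`, `method` repeated across its groups.
#' @export
group_closure_summary <- function(curves, adjust = c("none", "holm"),
                                  equal_variance = TRUE) {
  adjust <- match.arg(adjust)
  need <- c("wound_id", "treatment", "time_min", "percent_of_original")
  missing <- setdiff(need, names(curves))
  if (length(missing) > 0L) {
    rlang::abort(sprintf("`curves` lacks column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  grid <- sort(unique(curves$time_min))
  if (length(grid) > 1L) {
    step <- stats::median(diff(grid))
    snapped <- round(curves$time_min / step) * step
    off <- abs(snapped - curves$time_min) > step / 2 + 1e-9
    if (any(off)) rlang::abort("Some timepoints are more than half an interval off the common grid.")
    curves$time_min <- snapped
  }
  per_tp <- curves |>
    dplyr::group_by(.data$time_min) |>
    dplyr::group_modify(function(d, key) {
      groups <- split(d$percent_of_original, d$treatment)
      groups <- groups[vapply(groups, length, integer(1)) > 0]
      test <- if (length(groups) >= 2 && all(vapply(groups, length, integer(1)) >= 2)) {
        if (length(groups) == 2) {
          unpaired_t_test(groups[[1]], groups[[2]], equal_variance = equal_variance)
        } else {
          one_way_anova(groups)
        }
      } else {
        NULL
      }
      sumtab <- d |>
        dplyr::group_by(.data$treatment) |>
        dplyr::summarise(mean = mean(.data$percent_of_original),
                         sem = if (dplyr::n() > 1)
                           sd(.data$percent_of_original) / sqrt(dplyr::n())
                         else NA_real_,
                         n = dplyr::n(), .groups = "drop")
      if (is.null(test)) {
        sumtab$statistic <- NA_real_; sumtab$df <- NA_real_
        sumtab$p_value <- NA_real_; sumtab$method <- NA_character_
      } else {
        sumtab$statistic <- test$statistic
        sumtab$df <- test$df[length(test$df)]
        sumtab$p_value <- test$p_value
        sumtab$method <- test$method
      }
      sumtab
    }) |>
    dplyr::ungroup()
  if (adjust == "holm") {
    one_per_tp <- !duplicated(per_tp$time_min)
    adj <- stats::p.adjust(per_tp$p_value[one_per_tp], method = "holm")
    per_tp$p_value <- adj[match(per_tp$time_min, per_tp$time_min[one_per_tp])]
  }
  class(per_tp) <- c("closure_summary", class(per_tp))
  per_tp
}
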