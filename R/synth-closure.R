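# Synthetic wound-closure time series with a known monotone model.

#' Generate a synthetic wound-area time series
#'
#' Two closure models are offered: exponential area decay
#' `A(t) = A0 * exp(-k t)` (default) and a linear-front model in which the
#' wound radius shrinks at constant speed, `A(t) = pi * max(0, r0 - v t)^2`.
#' Noise multiplies each area by a lognormal factor with unit mean and the
#' requested coefficient of variation; areas are clipped at zero.
#'
#' @param initial_area_mm2 Starting wound area (default 0.05 mm2).
#' @param rate_constant_per_min Exponential decay rate `k` (1/min).
#' @param model `"exponential"` or `"linear_front"`.
#' @param front_speed_um_per_min Front speed `v` for the linear-front model.
#' @param frame_interval_s Acquisition interval (default 11 s).
#' @param n_frames Number of frames (>= 2).
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param seed Integer seed.
#' @return List with `series` (tibble `frame`, `time_s`, `area_mm2`) and
#'   `truth` (`true_area_mm2` per frame, model parameters, `seed`).
#' @examples
#' sim <- make_closure_series(rate_constant_per_min = log(2) / 10, n_frames = 60)
#' sim$series$area_mm2[1] / sim$series$area_mm2[56]  # ~2 at t = 10 min
#' @export
make_closure_series <- function(initial_area_mm2 = 0.05,
                                rate_constant_per_min = 0.1,
                                model = c("exponential", "linear_front"),
                                front_speed_um_per_min = 10,
                                frame_interval_s = 11, n_frames = 200,
                                noise_cv = 0, seed = NULL) {
  model <- match.arg(model)
  check_positive_scalar(initial_area_mm2, "initial_area_mm2")
  check_positive_scalar(frame_interval_s, "frame_interval_s")
  check_nonneg(noise_cv, "noise_cv")
  if (n_frames < 2) rlang::abort("`n_frames` must be >= 2.")
  frame <- 0:(n_frames - 1)
  t_min <- frame * frame_interval_s / 60
  true_area <- switch(model,
    exponential = initial_area_mm2 * exp(-rate_constant_per_min * t_min),
    linear_front = {
      r0_mm <- sqrt(initial_area_mm2 / pi)
      r_mm <- pmax(r0_mm - (front_speed_um_per_min / 1000) * t_min, 0)
      pi * r_mm^2
    })
  area <- with_seed(seed, {
    if (noise_cv > 0) {
      sdlog <- sqrt(log(1 + noise_cv^2))
      true_area * rlnorm(n_frames, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else {
      true_area
    }
  })
  list(
    series = tibble::tibble(frame = frame, time_s = frame * frame_interval_s,
                            area_mm2 = pmax(area, 0)),
    truth = list(true_area_mm2 = true_area, model = model,
                 rate_constant_per_min = rate_constant_per_min,
                 front_speed_um_per_min = front_speed_um_per_min,
                 initial_area_mm2 = initial_area_mm2,
                 frame_interval_s = frame_interval_s, seed = seed)
  )
}
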