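# 1-D surrogate of the plot-profile measurement: Gaussian cell-edge peaks on
# a configurable baseline, with exact ground truth.

#' Generate a synthetic line intensity profile
#'
#' Renders `n_peaks` Gaussian peaks at regular cell spacing on top of a
#' linear baseline, with additive Gaussian noise. The returned ground truth
#' lists the exact peak centres and amplitudes, so peak detection and ratio
#' estimation can be tested against known values.
#'
#' @param n_peaks Number of cell-edge peaks (0 allowed).
#' @param spacing_um Centre-to-centre peak spacing (default 50, the cell
#'   diameter of the tissue); must exceed `peak_fwhm_um`.
#' @param amplitudes Non-negative peak amplitudes (a.u.), recycled to
#'   `n_peaks`. The first is the wound-margin edge.
#' @param peak_fwhm_um Full width at half maximum of each peak (default 22 um,
#'   inside the 20-40 um edge-width acceptance band while keeping adjacent-peak
#'   overlap at 50 um spacing below 3% of amplitude).
#' @param baseline List with `offset` (a.u.) and `slope_per_um` (a.u./um)
#'   describing a linear drift.
#' @param noise_sd Additive Gaussian noise sd (a.u.).
#' @param pixel_size_um Sample spacing (default 0.5).
#' @param first_center_um Position of the first (margin) peak (default 30).
#' @param tail_um Flat run kept after the last peak (default 75).
#' @param seed Integer seed; identical `(params, seed)` give identical output.
#' @return List with `profile` (tibble `position_um`, `intensity`, floored at
#'   0) and `truth` (list: `centers_um`, `amplitudes`, `baseline`, `seed`).
#' @examples
#' sim <- make_profile(4, amplitudes = c(200, 100, 80, 60), seed = 1)
#' sim$truth$centers_um
#' @export
make_profile <- function(n_peaks, spacing_um = 50,
                         amplitudes = numeric(0), peak_fwhm_um = 22,
                         baseline = list(offset = 0, slope_per_um = 0),
                         noise_sd = 0, pixel_size_um = 0.5,
                         first_center_um = 30, tail_um = 75, seed = NULL) {
  if (n_peaks < 0) rlang::abort("`n_peaks` must be >= 0.")
  check_positive_scalar(spacing_um, "spacing_um")
  check_positive_scalar(peak_fwhm_um, "peak_fwhm_um")
  check_positive_scalar(pixel_size_um, "pixel_size_um")
  check_nonneg(noise_sd, "noise_sd")
  if (spacing_um <= peak_fwhm_um) {
    rlang::abort("`spacing_um` must exceed `peak_fwhm_um` so peaks stay resolvable.")
  }
  if (n_peaks > 0) {
    if (length(amplitudes) == 0L) rlang::abort("`amplitudes` required when n_peaks > 0.")
    check_nonneg(amplitudes, "amplitudes")
    amplitudes <- rep_len(amplitudes, n_peaks)
  } else {
    amplitudes <- numeric(0)
  }
  centers <- if (n_peaks > 0) first_center_um + spacing_um * (seq_len(n_peaks) - 1) else numeric(0)
  total_um <- first_center_um + spacing_um * max(0, n_peaks - 1) + tail_um
  pos <- seq(0, total_um, by = pixel_size_um)
  sigma <- peak_fwhm_um / (2 * sqrt(2 * log(2)))
  signal <- (baseline$offset %||% 0) + (baseline$slope_per_um %||% 0) * pos
  for (i in seq_len(n_peaks)) {
    signal <- signal + amplitudes[i] * exp(-(pos - centers[i])^2 / (2 * sigma^2))
  }
  intensity <- with_seed(seed, signal + rnorm(length(pos), 0, noise_sd))
  list(
    profile = new_profile(pos, pmax(intensity, 0)),
    truth = list(centers_um = centers, amplitudes = amplitudes,
                 peak_fwhm_um = peak_fwhm_um, baseline = baseline, seed = seed)
  )
}
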