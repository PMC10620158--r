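# Cortical-actin line-profile analysis: extraction, baseline adjustment,
# width-constrained peak detection, cell-edge assignment and aggregation.

new_profile <- function(position_um, intensity) {
  tibble::tibble(position_um = as.numeric(position_um),
                 intensity = as.numeric(intensity))
}

profile_spacing_um <- function(profile) {
  d <- diff(profile$position_um)
  if (length(d) == 0L) rlang::abort("Profile has fewer than 2 samples.")
  dx <- mean(d)
  if (any(d <= 0) || max(abs(d - dx)) > 0.01 * dx) {
    rlang::abort("Profile positions must be uniformly spaced and strictly increasing.")
  }
  dx
}

#' Extract an intensity profile along a line ROI
#'
#' Samples the image by bilinear interpolation at uniform steps along the
#' line. Position 0 is the endpoint designated as abutting the wound
#' (`wound_end`), increasing away from the wound, so downstream peak ranks are
#' ordered wound-margin first regardless of how the line was drawn.
#'
#' @param image A [calibrated_image()].
#' @param start_px,end_px Numeric `(row, col)` endpoints in 0-based pixels.
#' @param wound_end Which endpoint abuts the wound, `"start"` or `"end"`.
#' @param step_px Sampling step along the line in pixels (must be <= 1 so no
#'   pixel is skipped; default 0.5).
#' @return A profile tibble (`position_um`, `intensity`).
#' @export
extract_profile <- function(image, start_px, end_px, wound_end = "start",
                            step_px = 0.5) {
  ps <- pixel_size_um(image)
  if (!wound_end %in% c("start", "end")) {
    rlang::abort("`wound_end` must be 'start' or 'end'.")
  }
  if (step_px <= 0 || step_px > 1) rlang::abort("`step_px` must be in (0, 1].")
  p0 <- as.numeric(start_px); p1 <- as.numeric(end_px)
  if (length(p0) != 2L || length(p1) != 2L || all(p0 == p1)) {
    rlang::abort("Endpoints must be two distinct (row, col) pairs.")
  }
  if (wound_end == "end") { tmp <- p0; p0 <- p1; p1 <- tmp }
  len_px <- sqrt(sum((p1 - p0)^2))
  n <- floor(len_px / step_px) + 1L
  t <- seq(0, by = step_px, length.out = n)
  rr <- p0[1] + t / len_px * (p1[1] - p0[1])
  cc <- p0[2] + t / len_px * (p1[2] - p0[2])
  nr <- nrow(image); nc <- ncol(image)
  if (any(rr < 0) || any(rr > nr - 1) || any(cc < 0) || any(cc > nc - 1)) {
    rlang::abort(sprintf(
      "Line (%.1f,%.1f)-(%.1f,%.1f) exits the %d x %d image.",
      start_px[1], start_px[2], end_px[1], end_px[2], nr, nc))
  }
  px <- as_pixel_matrix(image)
  # bilinear interpolation; 0-based (row, col) -> 1-based matrix indices
  r0 <- pmin(floor(rr), nr - 2); c0 <- pmin(floor(cc), nc - 2)
  fr <- rr - r0; fc <- cc - c0
  i00 <- px[cbind(r0 + 1, c0 + 1)]; i01 <- px[cbind(r0 + 1, c0 + 2)]
  i10 <- px[cbind(r0 + 2, c0 + 1)]; i11 <- px[cbind(r0 + 2, c0 + 2)]
  val <- i00 * (1 - fr) * (1 - fc) + i01 * (1 - fr) * fc +
    i10 * fr * (1 - fc) + i11 * fr * fc
  new_profile(t * ps, val)
}

#' Smooth a profile with a Gaussian kernel
#'
#' Light denoising applied before baseline adjustment and peak detection;
#' reduces the upward bias that pixel-level noise puts on local-maximum
#' amplitudes. Edges use kernel renormalisation (no padding values invented).
#'
#' @param profile Profile tibble (`position_um`, `intensity`).
#' @param sigma_um Kernel standard deviation in micrometres; 0 disables.
#' @return Smoothed profile tibble.
#' @export
smooth_profile <- function(profile, sigma_um = 2) {
  check_nonneg(sigma_um, "sigma_um")
  if (sigma_um == 0) return(new_profile(profile$position_um, profile$intensity))
  dx <- profile_spacing_um(profile)
  h <- max(1L, ceiling(3 * sigma_um / dx))
  k <- exp(-((-h:h) * dx)^2 / (2 * sigma_um^2))
  x <- profile$intensity
  n <- length(x)
  num <- stats::filter(c(rep(0, h), x, rep(0, h)), k, sides = 2)[(h + 1):(h + n)]
  den <- stats::filter(c(rep(0, h), rep(1, n), rep(0, h)), k, sides = 2)[(h + 1):(h + n)]
  new_profile(profile$position_um, as.numeric(num / den))
}

#' Adjust the baseline of an intensity profile
#'
#' Subtracts a morphological opening (rolling minimum followed by rolling
#' maximum over a flat window) from the signal. The opening is anti-extensive,
#' so the corrected profile is always non-negative; adding any constant to the
#' input leaves the output unchanged, and peaks narrower than the window pass
#' through with their amplitude preserved.
#'
#' @param profile Profile tibble (`position_um`, `intensity`).
#' @param window_um Structuring-element width in micrometres (default 80;
#'   must exceed the widest peak the subsequent detection should keep).
#' @return Baseline-corrected profile tibble.
#' @export
correct_baseline <- function(profile, window_um = 80) {
  check_positive_scalar(window_um, "window_um")
  dx <- profile_spacing_um(profile)
  h <- round(window_um / (2 * dx))
  if (2 * h + 1 < 3) {
    rlang::abort(sprintf("Baseline window of %g um spans fewer than 3 samples at %g um spacing.",
                         window_um, dx))
  }
  x <- profile$intensity
  er <- roll_extreme(x, h, min)
  op <- roll_extreme(er, h, max)
  new_profile(profile$position_um, x - op)
}

# Rolling min/max with truncated windows at the boundaries (window stays
# symmetric in index space, clipped to the signal).
roll_extreme <- function(x, h, fun) {
  n <- length(x)
  vapply(seq_len(n), function(i) fun(x[max(1L, i - h):min(n, i + h)]), numeric(1))
}

#' Peak detection parameters
#'
#' @param min_width_um,max_width_um Acceptance band on the width at half
#'   prominence, in micrometres (defaults 20 and 40, the band used to map
#'   local maxima to cell edges at ~50 um cell spacing).
#' @param min_prominence Minimum peak prominence in a.u.; `NULL` (default)
#'   uses 5x a robust noise estimate of the profile.
#' @return A list of class `peak_params`.
#' @export
peak_params <- function(min_width_um = 20, max_width_um = 40,
                        min_prominence = NULL) {
  check_positive_scalar(min_width_um, "min_width_um")
  check_positive_scalar(max_width_um, "max_width_um")
  if (min_width_um >= max_width_um) {
    rlang::abort("`min_width_um` must be smaller than `max_width_um`.")
  }
  if (!is.null(min_prominence)) check_nonneg(min_prominence, "min_prominence")
  structure(list(min_width_um = min_width_um, max_width_um = max_width_um,
                 min_prominence = min_prominence), class = "peak_params")
}

find_local_maxima <- function(x) {
  n <- length(x)
  out <- integer(0)
  i <- 2L
  while (i < n) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[i]) j <- j + 1L
      if (j < n && x[j + 1L] < x[i]) {
        out <- c(out, as.integer(floor((i + j) / 2)))
        i <- j + 1L
      } else {
        i <- j + 1L
      }
    } else {
      i <- i + 1L
    }
  }
  out
}

# Prominence of the peak at index p: height above the higher of the two base
# minima, where each base is the lowest sample between the peak and the
# nearest strictly-higher sample (or the signal end) on that side.
peak_prominence_at <- function(x, p) {
  n <- length(x)
  i <- p; lmin <- x[p]; lb <- p
  while (i >= 1L && x[i] <= x[p]) {
    if (x[i] < lmin) { lmin <- x[i]; lb <- i }
    i <- i - 1L
  }
  i <- p; rmin <- x[p]; rb <- p
  while (i <= n && x[i] <= x[p]) {
    if (x[i] < rmin) { rmin <- x[i]; rb <- i }
    i <- i + 1L
  }
  list(prominence = x[p] - max(lmin, rmin), left_base = lb, right_base = rb)
}

# Width of the peak at half its prominence, in samples, by linear
# interpolation of the crossing points, bounded by the peak's bases.
peak_width_at <- function(x, p, prom) {
  h <- x[p] - 0.5 * prom$prominence
  i <- p
  while (i > prom$left_base && x[i] > h) i <- i - 1L
  left_ip <- if (x[i] < h) i + (h - x[i]) / (x[i + 1L] - x[i]) else i
  i <- p
  while (i < prom$right_base && x[i] > h) i <- i + 1L
  right_ip <- if (x[i] < h) i - (h - x[i]) / (x[i - 1L] - x[i]) else i
  right_ip - left_ip
}

#' Detect cell-edge peaks in a baseline-corrected profile
#'
#' Finds interior local maxima (plateaus resolved to their centre sample),
#' computes each peak's prominence and width at half prominence, and keeps
#' peaks whose width lies within the acceptance band and whose prominence
#' reaches `min_prominence`. Maxima passing both filters correspond to cell
#' edges at the ~50 um cell spacing of the tissue.
#'
#' @param profile Baseline-corrected profile tibble.
#' @param params A [peak_params()] object.
#' @return Tibble of retained peaks, sorted by position: `position_um`,
#'   `amplitude`, `prominence`, `width_um`, `index`.
#' @export
detect_peaks <- function(profile, params = peak_params()) {
  stopifnot(inherits(params, "peak_params"))
  dx <- profile_spacing_um(profile)
  x <- profile$intensity
  span <- profile$position_um[length(x)] - profile$position_um[1]
  if (span < params$min_width_um) {
    rlang::abort(sprintf("Profile span %.1f um is shorter than min_width_um = %g um.",
                         span, params$min_width_um))
  }
  min_prom <- params$min_prominence %||% (5 * robust_noise_sd(x))
  idx <- find_local_maxima(x)
  rows <- purrr::map(idx, function(p) {
    pr <- peak_prominence_at(x, p)
    if (pr$prominence < min_prom) return(NULL)
    w_um <- peak_width_at(x, p, pr) * dx
    if (w_um < params$min_width_um || w_um > params$max_width_um) return(NULL)
    tibble::tibble(position_um = profile$position_um[p], amplitude = x[p],
                   prominence = pr$prominence, width_um = w_um, index = p)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(position_um = numeric(0), amplitude = numeric(0),
                          prominence = numeric(0), width_um = numeric(0),
                          index = integer(0))
  }
  dplyr::arrange(out, .data$position_um)
}

#' Assign detected peaks to cell-edge ranks
#'
#' The first retained peak from the wound end is the wound-margin cell's
#' edge; the next `max_ranks - 1` peaks are submarginal cells 1, 2, ... Each
#' submarginal amplitude is expressed as a ratio to the margin amplitude.
#' Ranks beyond the available peaks are marked missing (never imputed); a
#' profile with no retained peaks yields an all-missing series flagged for QC
#' rather than an error.
#'
#' @param peaks Peak tibble from [detect_peaks()], sorted by position.
#' @param max_ranks Number of ranks to report (default 4: margin + 3 cells).
#' @return Tibble with one row per rank: `rank` (`margin`, `cell1`, ...),
#'   `position_um`, `amplitude`, `ratio`, `qc`.
#' @export
assign_cell_edges <- function(peaks, max_ranks = 4) {
  stopifnot(max_ranks >= 1)
  labs <- c("margin", paste0("cell", seq_len(max_ranks - 1)))
  n <- nrow(peaks)
  amp <- pos <- rep(NA_real_, max_ranks)
  k <- min(n, max_ranks)
  if (k > 0) {
    amp[seq_len(k)] <- peaks$amplitude[seq_len(k)]
    pos[seq_len(k)] <- peaks$position_um[seq_len(k)]
  }
  ratio <- if (is.na(amp[1]) || amp[1] == 0) rep(NA_real_, max_ranks) else amp / amp[1]
  tibble::tibble(rank = factor(labs, levels = labs), position_um = pos,
                 amplitude = amp, ratio = ratio,
                 qc = if (n == 0L) "no_peaks" else "ok")
}

#' Analyze one profile end to end
#'
#' Convenience wrapper chaining [smooth_profile()], [correct_baseline()],
#' [detect_peaks()] and [assign_cell_edges()].
#'
#' @param profile Raw profile tibble.
#' @param smooth_sigma_um Gaussian denoising sigma (default 2 um).
#' @param baseline_window_um Opening window (default 80 um).
#' @param params [peak_params()].
#' @param max_ranks Ranks to report.
#' @return Cell-edge series tibble (see [assign_cell_edges()]).
#' @export
analyze_profile <- function(profile, smooth_sigma_um = 2,
                            baseline_window_um = 80, params = peak_params(),
                            max_ranks = 4) {
  if (is.null(params$min_prominence)) {
    # noise floor: raw white-noise scale (difference-based estimates fail on
    # the correlated post-smoothing noise) attenuated by the smoothing
    # kernel's ||k||2 / ||k||1, the factor by which Gaussian filtering
    # shrinks white noise
    fac <- if (smooth_sigma_um > 0) {
      dx <- profile_spacing_um(profile)
      h <- max(1L, ceiling(3 * smooth_sigma_um / dx))
      k <- exp(-((-h:h) * dx)^2 / (2 * smooth_sigma_um^2))
      sqrt(sum(k^2)) / sum(k)
    } else {
      1
    }
    params$min_prominence <- 5 * fac * robust_noise_sd(profile$intensity)
  }
  profile |>
    smooth_profile(sigma_um = smooth_sigma_um) |>
    correct_baseline(window_um = baseline_window_um) |>
    detect_peaks(params = params) |>
    assign_cell_edges(max_ranks = max_ranks)
}

#' Analyze an actin image over a set of line ROIs
#'
#' Extracts a profile for each ROI and runs the full per-line analysis,
#' carrying any grouping columns (`animal`, `wound`, `line`, `treatment`)
#' through to the result.
#'
#' @param image A [calibrated_image()].
#' @param rois ROI tibble from [read_line_rois()] (or built in code).
#' @param ... Passed to [analyze_profile()].
#' @return Long tibble: one row per (ROI, rank).
#' @export
analyze_actin_image <- function(image, rois, ...) {
  keep <- intersect(c("animal", "wound", "line", "treatment"), names(rois))
  purrr::map_dfr(seq_len(nrow(rois)), function(i) {
    r <- rois[i, ]
    prof <- extract_profile(image, c(r$start_row, r$start_col),
                            c(r$end_row, r$end_col), wound_end = r$wound_end)
    res <- analyze_profile(prof, ...)
    if (length(keep) > 0) res <- dplyr::bind_cols(r[rep(1, nrow(res)), keep], res)
    if (!"line" %in% names(res)) res$line <- i
    res
  })
}

#' Aggregate per-line edge ratios to wounds and animals
#'
#' Ratios (and margin amplitudes) are averaged per rank over lines within
#' each wound, then over wounds within each animal, with missing ranks
#' excluded pairwise. Warns — without failing — when a wound has fewer than 4
#' or more than 8 lines or an animal has more than 5 wounds, the expected
#' design of the assay; animals with no usable lines are dropped with a
#' message.
#'
#' @param lines Long tibble of per-line series (columns `animal`, `wound`,
#'   `rank`, `amplitude`, `ratio`, optional `treatment`).
#' @return Tibble with one row per (animal, rank): mean ratio, mean
#'   amplitude, `n_wounds`, `n_lines`.
#' @export
aggregate_ratios <- function(lines) {
  need <- c("animal", "wound", "rank", "amplitude", "ratio")
  missing <- setdiff(need, names(lines))
  if (length(missing) > 0L) {
    rlang::abort(sprintf("`lines` lacks column(s): %s", paste(missing, collapse = ", ")))
  }
  has_trt <- "treatment" %in% names(lines)
  usable <- lines
  dropped <- setdiff(unique(lines$animal),
                     unique(lines$animal[!is.na(lines$amplitude)]))
  if (length(dropped) > 0L) {
    rlang::inform(sprintf("Excluding animal(s) with no usable lines: %s",
                          paste(dropped, collapse = ", ")))
    usable <- dplyr::filter(usable, !(.data$animal %in% dropped))
  }
  line_counts <- lines |>
    dplyr::distinct(.data$animal, .data$wound,
                    line = if ("line" %in% names(lines)) .data$line else NA) |>
    dplyr::count(.data$animal, .data$wound, name = "n_lines")
  bad <- dplyr::filter(line_counts, .data$n_lines < 4 | .data$n_lines > 8)
  if (nrow(bad) > 0L) {
    rlang::warn(sprintf("%d wound(s) have lines outside the expected 4-8 per wound (e.g. animal %s wound %s: %d).",
                        nrow(bad), bad$animal[1], bad$wound[1], bad$n_lines[1]))
  }
  wound_means <- usable |>
    dplyr::group_by(.data$animal, .data$wound, .data$rank) |>
    dplyr::summarise(ratio = mean(.data$ratio, na.rm = TRUE),
                     amplitude = mean(.data$amplitude, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::mutate(ratio = ifelse(is.nan(.data$ratio), NA_real_, .data$ratio),
                  amplitude = ifelse(is.nan(.data$amplitude), NA_real_, .data$amplitude))
  wpa <- dplyr::count(dplyr::distinct(wound_means, .data$animal, .data$wound),
                      .data$animal, name = "n_wounds")
  if (any(wpa$n_wounds > 5)) {
    rlang::warn("Some animals have more than the expected 1-5 wounds.")
  }
  out <- wound_means |>
    dplyr::group_by(.data$animal, .data$rank) |>
    dplyr::summarise(mean_ratio = mean(.data$ratio, na.rm = TRUE),
                     mean_amplitude = mean(.data$amplitude, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::mutate(mean_ratio = ifelse(is.nan(.data$mean_ratio), NA_real_, .data$mean_ratio),
                  mean_amplitude = ifelse(is.nan(.data$mean_amplitude), NA_real_, .data$mean_amplitude)) |>
    dplyr::left_join(wpa, by = "animal") |>
    dplyr::left_join(dplyr::summarise(dplyr::group_by(line_counts, .data$animal),
                                      n_lines = sum(.data$n_lines), .groups = "drop"),
                     by = "animal")
  if (has_trt) {
    trt <- dplyr::distinct(lines, .data$animal, .data$treatment)
    out <- dplyr::left_join(out, trt, by = "animal") |>
      dplyr::relocate("treatment", .after = "animal")
  }
  out
}
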