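# Dye-uptake particle scoring and nuclear transcription positivity.

# 1-D Otsu split of a numeric vector: threshold maximising the between-class
# variance, searched over midpoints between sorted unique values.
otsu_threshold <- function(values) {
  v <- sort(values[is.finite(values)])
  u <- unique(v)
  if (length(u) < 2L) {
    rlang::abort("Otsu split needs at least two distinct values.")
  }
  cand <- (u[-1] + u[-length(u)]) / 2
  n <- length(v)
  best <- -Inf; thr <- cand[1]
  for (t in cand) {
    lo <- v[v <= t]; hi <- v[v > t]
    w0 <- length(lo) / n; w1 <- 1 - w0
    bcv <- w0 * w1 * (mean(hi) - mean(lo))^2
    if (bcv > best) { best <- bcv; thr <- t }
  }
  thr
}

#' Spot detection parameters
#'
#' The particle detector is deliberately transparent: a difference-of-Gaussians
#' band-pass sized to the admissible diameter band, a single intensity
#' threshold on the filtered image, then connected components gated by
#' equivalent diameter. Both knobs — the size constraint and the intensity
#' threshold — are explicit.
#'
#' @param min_diameter_um,max_diameter_um Equivalent-diameter acceptance band
#'   (defaults 1 and 4 um).
#' @param intensity_threshold Threshold on the band-pass response (a.u.,
#'   default 20).
#' @return A list of class `spot_params`.
#' @export
spot_params <- function(min_diameter_um = 1, max_diameter_um = 4,
                        intensity_threshold = 20) {
  check_positive_scalar(min_diameter_um, "min_diameter_um")
  check_positive_scalar(max_diameter_um, "max_diameter_um")
  if (min_diameter_um >= max_diameter_um) {
    rlang::abort("`min_diameter_um` must be smaller than `max_diameter_um`.")
  }
  check_nonneg(intensity_threshold, "intensity_threshold")
  structure(list(min_diameter_um = min_diameter_um,
                 max_diameter_um = max_diameter_um,
                 intensity_threshold = intensity_threshold),
            class = "spot_params")
}

#' Detect fluorescent particles
#'
#' Band-pass filters the image with a difference of Gaussians whose scales
#' bracket the admissible particle size, thresholds the response at
#' `intensity_threshold`, labels connected components, and keeps components
#' whose equivalent diameter (`2 * sqrt(area / pi)`, in um) lies within the
#' size band. One particle is reported per retained component, at its
#' intensity-weighted centroid.
#'
#' @param image A [calibrated_image()] of the particle channel.
#' @param params A [spot_params()] object.
#' @return List with `count` and `particles`, a tibble (`x_um`, `y_um`,
#'   `equiv_diameter_um`, `response`).
#' @export
detect_particles <- function(image, params = spot_params()) {
  stopifnot(inherits(params, "spot_params"))
  ps <- pixel_size_um(image)
  px <- as_pixel_matrix(image)
  if (params$intensity_threshold >= max(px)) {
    rlang::warn("Intensity threshold is at or above the image maximum; zero particles.")
  }
  s1 <- params$min_diameter_um / 2.355 / ps   # sigma in px, FWHM = min diameter
  s2 <- 2 * params$max_diameter_um / 2.355 / ps
  dog <- as.matrix(EBImage::gblur(px, sigma = s1)) -
    as.matrix(EBImage::gblur(px, sigma = s2))
  mask <- dog > params$intensity_threshold
  if (!any(mask)) {
    return(list(count = 0L,
                particles = tibble::tibble(x_um = numeric(0), y_um = numeric(0),
                                           equiv_diameter_um = numeric(0),
                                           response = numeric(0))))
  }
  lab <- EBImage::bwlabel(mask)
  ids <- seq_len(max(lab))
  idx <- which(lab > 0)
  labv <- lab[idx]
  rc <- arrayInd(idx, dim(lab))
  w <- dog[idx]
  area_px <- tabulate(labv, nbins = max(lab))
  eqd_um <- 2 * sqrt(area_px / pi) * ps
  sw <- vapply(split(w, labv), sum, numeric(1))
  xr <- vapply(split(w * rc[, 1], labv), sum, numeric(1)) / sw
  xc <- vapply(split(w * rc[, 2], labv), sum, numeric(1)) / sw
  resp <- vapply(split(dog[idx], labv), max, numeric(1))
  keep <- eqd_um >= params$min_diameter_um & eqd_um <= params$max_diameter_um
  out <- tibble::tibble(
    x_um = (xc[keep] - 0.5) * ps, y_um = (xr[keep] - 0.5) * ps,
    equiv_diameter_um = eqd_um[keep], response = resp[keep])
  list(count = sum(keep), particles = out)
}

#' Segment and count nuclei from a nuclear-stain channel
#'
#' Global Otsu threshold on the pixel intensities, connected-component
#' labelling, and an area gate discarding components below `min_area_um2`.
#' Optional distance-transform watershed splitting separates touching nuclei;
#' it is off by default because over-splitting inflates the denominator of
#' the particles-per-nucleus statistic.
#'
#' @param image A [calibrated_image()] of the nuclear channel.
#' @param min_area_um2 Minimum region area (default 20 um2).
#' @param watershed Split touching nuclei (default `FALSE`).
#' @return List with `count`, `nuclei` (tibble `label`, `x_um`, `y_um`,
#'   `area_um2`), and `labels` (the integer label matrix, for masking a
#'   paired channel).
#' @export
count_nuclei <- function(image, min_area_um2 = 20, watershed = FALSE) {
  ps <- pixel_size_um(image)
  px <- as_pixel_matrix(image)
  empty <- list(count = 0L,
                nuclei = tibble::tibble(label = integer(0), x_um = numeric(0),
                                        y_um = numeric(0), area_um2 = numeric(0)),
                labels = matrix(0L, nrow(px), ncol(px)))
  rng <- range(px)
  if (diff(rng) == 0) return(empty)
  scaled <- (px - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
  mask <- scaled > thr
  if (!any(mask)) return(empty)
  if (watershed) {
    dm <- EBImage::distmap(mask)
    lab <- EBImage::watershed(dm)
  } else {
    lab <- EBImage::bwlabel(mask)
  }
  lab <- as.matrix(lab)
  nlab <- max(lab)
  if (nlab == 0L) return(empty)
  area_px <- tabulate(lab[lab > 0], nbins = nlab)
  area_um2 <- area_px * ps^2
  keep_ids <- which(area_um2 >= min_area_um2)
  if (length(keep_ids) == 0L) return(empty)
  relab <- integer(nlab)
  relab[keep_ids] <- seq_along(keep_ids)
  out_lab <- matrix(0L, nrow(lab), ncol(lab))
  sel <- lab > 0
  out_lab[sel] <- relab[lab[sel]]
  idx <- which(out_lab > 0)
  labv <- out_lab[idx]
  rc <- arrayInd(idx, dim(out_lab))
  cy <- vapply(split(rc[, 1], labv), mean, numeric(1))
  cx <- vapply(split(rc[, 2], labv), mean, numeric(1))
  nuclei <- tibble::tibble(label = seq_along(keep_ids),
                           x_um = (cx - 0.5) * ps, y_um = (cy - 0.5) * ps,
                           area_um2 = area_um2[keep_ids])
  list(count = length(keep_ids), nuclei = nuclei, labels = out_lab)
}

#' Score one image pair as particles per nucleus
#'
#' @param particle_image,nuclear_image Co-registered [calibrated_image()]s.
#' @param params [spot_params()] for the particle channel.
#' @param min_nucleus_area_um2 Area gate for nuclei.
#' @param ... Further arguments to [count_nuclei()].
#' @return One-row tibble: `n_particles`, `n_nuclei`, `normalized`
#'   (particles per nucleus; `NA` when no nuclei).
#' @export
score_uptake_image <- function(particle_image, nuclear_image,
                               params = spot_params(),
                               min_nucleus_area_um2 = 20, ...) {
  np <- detect_particles(particle_image, params)$count
  nn <- count_nuclei(nuclear_image, min_area_um2 = min_nucleus_area_um2, ...)$count
  tibble::tibble(n_particles = np, n_nuclei = nn,
                 normalized = if (nn > 0) np / nn else NA_real_)
}

#' Per-animal mean normalized particle counts
#'
#' Averages particles-per-nucleus over the images of each animal (four per
#' animal in the standard design). Records with no nuclei are excluded with a
#' warning; animals with no valid images are dropped with a message.
#'
#' @param records Tibble with columns `animal`, `n_particles`, `n_nuclei`
#'   (and optionally `treatment`, `image`); `normalized` is computed if
#'   absent.
#' @param images_per_animal Expected images per animal (default 4); a
#'   deviation warns but does not fail.
#' @return Tibble per animal: `mean_normalized`, `n_images` (+ `treatment`).
#' @export
uptake_summary <- function(records, images_per_animal = 4) {
  need <- c("animal", "n_particles", "n_nuclei")
  missing <- setdiff(need, names(records))
  if (length(missing) > 0L) {
    rlang::abort(sprintf("`records` lacks column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  if (!"normalized" %in% names(records)) {
    records$normalized <- ifelse(records$n_nuclei > 0,
                                 records$n_particles / records$n_nuclei,
                                 NA_real_)
  }
  bad <- records$n_nuclei <= 0
  if (any(bad)) {
    rlang::warn(sprintf("Dropping %d record(s) with zero nuclei.", sum(bad)))
    records <- records[!bad, , drop = FALSE]
  }
  if (nrow(records) == 0L) rlang::abort("No records with nuclei remain.")
  has_trt <- "treatment" %in% names(records)
  out <- records |>
    dplyr::group_by(.data$animal) |>
    dplyr::summarise(mean_normalized = mean(.data$normalized),
                     n_images = dplyr::n(), .groups = "drop")
  if (any(out$n_images != images_per_animal)) {
    rlang::warn(sprintf("Some animals do not have the expected %d images.",
                        images_per_animal))
  }
  if (has_trt) {
    trt <- dplyr::distinct(records, .data$animal, .data$treatment)
    out <- dplyr::left_join(out, trt, by = "animal") |>
      dplyr::relocate("treatment", .after = "animal")
  }
  out
}

#' Fraction of transcription-positive nuclei
#'
#' Builds nuclear masks from the nuclear-stain channel, measures the mean
#' intensity of the paired transcription channel inside each mask, and calls
#' a nucleus positive when its mean exceeds the threshold. The default
#' threshold is an Otsu split of the per-nucleus means, which is invariant to
#' affine intensity rescaling as long as the two modes stay separable; an
#' absolute threshold can be supplied instead.
#'
#' @param eu_image,nuclear_image Co-registered [calibrated_image()]s with the
#'   same calibration.
#' @param threshold Either `"otsu"` (default) or an absolute intensity.
#' @param min_nucleus_area_um2 Area gate passed to [count_nuclei()].
#' @param ... Further arguments to [count_nuclei()].
#' @return List with `fraction`, `n_positive`, `n_nuclei`, `threshold`, and
#'   `per_nucleus`, a tibble (`label`, `mean_intensity`, `positive`).
#' @export
eu_positive_fraction <- function(eu_image, nuclear_image, threshold = "otsu",
                                 min_nucleus_area_um2 = 20, ...) {
  if (!isTRUE(all.equal(pixel_size_um(eu_image), pixel_size_um(nuclear_image))) ||
      !identical(dim(eu_image), dim(nuclear_image))) {
    rlang::abort("Transcription and nuclear channels must share size and calibration.")
  }
  seg <- count_nuclei(nuclear_image, min_area_um2 = min_nucleus_area_um2, ...)
  if (seg$count == 0L) {
    rlang::abort("No nuclei found; the positive fraction is undefined.")
  }
  eu <- as_pixel_matrix(eu_image)
  sel <- seg$labels > 0
  means <- vapply(split(eu[sel], seg$labels[sel]), mean, numeric(1))
  thr <- if (identical(threshold, "otsu")) otsu_threshold(means) else {
    check_nonneg(threshold, "threshold")
    threshold
  }
  positive <- means > thr
  list(fraction = mean(positive), n_positive = sum(positive),
       n_nuclei = seg$count, threshold = thr,
       per_nucleus = tibble::tibble(label = as.integer(names(means)),
                                    mean_intensity = unname(means),
                                    positive = unname(positive)))
}
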