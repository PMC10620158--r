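# Synthetic dye-uptake imagery: diffraction-limited particles over a field of
# Hoechst-like nuclei, plus a bimodal nuclear transcription channel, with
# exact coordinates and positivity flags as ground truth.

# Rejection-sampled point placement with a minimum pairwise separation.
place_points <- function(n, lo, hi, min_sep, max_tries = 200L) {
  if (n == 0L) return(matrix(numeric(0), ncol = 2))
  pts <- matrix(NA_real_, n, 2)
  placed <- 0L
  tries <- 0L
  while (placed < n) {
    cand <- runif(2, lo, hi)
    ok <- placed == 0L ||
      min((pts[seq_len(placed), 1] - cand[1])^2 +
          (pts[seq_len(placed), 2] - cand[2])^2) >= min_sep^2
    if (ok) {
      placed <- placed + 1L
      pts[placed, ] <- cand
      tries <- 0L
    } else {
      tries <- tries + 1L
      if (tries > max_tries) {
        rlang::abort(sprintf(
          "Could not place %d points at >= %.3g um separation in a [%.3g, %.3g] um field after %d retries; reduce the count or the separation.",
          n, min_sep, lo, hi, max_tries))
      }
    }
  }
  pts
}

render_gaussians <- function(npx, pixel_size_um, xy_um, amplitude, sigma_um) {
  img <- matrix(0, npx, npx)
  if (nrow(xy_um) == 0L) return(img)
  s_px <- sigma_um / pixel_size_um
  h <- ceiling(4 * s_px)
  off <- -h:h
  k_r <- matrix(off, length(off), length(off))
  k_c <- t(k_r)
  for (i in seq_len(nrow(xy_um))) {
    r0 <- xy_um[i, 2] / pixel_size_um + 0.5  # y -> row (1-based centre)
    c0 <- xy_um[i, 1] / pixel_size_um + 0.5
    rr <- round(r0) + off
    cc <- round(c0) + off
    g <- amplitude * exp(-(((round(r0) + k_r) - r0)^2 + ((round(c0) + k_c) - c0)^2) /
                           (2 * s_px^2))
    rsel <- rr >= 1 & rr <= npx
    csel <- cc >= 1 & cc <= npx
    img[rr[rsel], cc[csel]] <- img[rr[rsel], cc[csel]] + g[rsel, csel]
  }
  img
}

#' Generate paired uptake / nuclear / transcription channel images
#'
#' Places `n_nuclei` non-overlapping disc nuclei and `n_particles`
#' diffraction-limited Gaussian particles in one field and renders three
#' co-registered channels: a particle channel, a nuclear-stain channel, and a
#' nascent-transcription channel in which each nucleus is filled with a draw
#' from one of two well-separated intensity modes (positive or negative).
#' `round(eu_positive_fraction * n_nuclei)` nuclei are flagged positive, the
#' flags assigned at random.
#'
#' @param n_particles,n_nuclei Object counts (>= 0).
#' @param particle_sigma_um Particle Gaussian sigma (default 0.75 um; the
#'   particle "size" is the FWHM, 2.355 sigma).
#' @param particle_amplitude Peak particle intensity (a.u.).
#' @param nucleus_radius_um Nucleus disc radius (default 5).
#' @param nucleus_amplitude Nuclear-stain disc intensity (a.u.).
#' @param min_separation_um Minimum centre-to-centre separation within each
#'   object class (default 15).
#' @param eu_positive_fraction Fraction of nuclei flagged
#'   transcription-positive.
#' @param eu_pos_mean,eu_neg_mean,eu_sd Per-nucleus mean intensity modes and
#'   their spread for the transcription channel.
#' @param noise_sd Additive Gaussian noise sd on every channel.
#' @param pixel_size_um Calibration (default 0.5 um/px).
#' @param image_size_um Field side length (default 200).
#' @param seed Integer seed.
#' @return List with `particle_image`, `nuclear_image`, `eu_image`
#'   ([calibrated_image()]s) and `truth`: `particle_coords_um`,
#'   `nucleus_coords_um` (tibbles `x_um`, `y_um`), `eu_positive` (logical per
#'   nucleus), `eu_means`, and `seed`.
#' @export
make_uptake_images <- function(n_particles = 40, n_nuclei = 50,
                               particle_sigma_um = 0.75,
                               particle_amplitude = 100,
                               nucleus_radius_um = 5,
                               nucleus_amplitude = 150,
                               min_separation_um = 15,
                               eu_positive_fraction = 0.9,
                               eu_pos_mean = 120, eu_neg_mean = 30, eu_sd = 8,
                               noise_sd = 2, pixel_size_um = 0.5,
                               image_size_um = 200, seed = NULL) {
  stopifnot(n_particles >= 0, n_nuclei >= 0)
  check_positive_scalar(particle_sigma_um, "particle_sigma_um")
  check_positive_scalar(pixel_size_um, "pixel_size_um")
  check_nonneg(min_separation_um, "min_separation_um")
  check_nonneg(noise_sd, "noise_sd")
  if (eu_positive_fraction < 0 || eu_positive_fraction > 1) {
    rlang::abort("`eu_positive_fraction` must be in [0, 1].")
  }
  npx <- round(image_size_um / pixel_size_um)

  with_seed(seed, {
    pad_n <- nucleus_radius_um + 3
    pad_p <- 4 * particle_sigma_um
    nuc_xy <- place_points(n_nuclei, pad_n, image_size_um - pad_n,
                           min_separation_um)
    par_xy <- place_points(n_particles, pad_p, image_size_um - pad_p,
                           min_separation_um)

    particle_img <- render_gaussians(npx, pixel_size_um, par_xy,
                                     particle_amplitude, particle_sigma_um)

    # nuclei: filled discs, lightly blurred for soft edges
    pxy <- ((seq_len(npx) - 1) + 0.5) * pixel_size_um
    X <- matrix(pxy, npx, npx, byrow = TRUE)
    Y <- matrix(pxy, npx, npx)
    nuc_mask <- matrix(FALSE, npx, npx)
    nuc_lab <- matrix(0L, npx, npx)
    for (i in seq_len(n_nuclei)) {
      inside <- (X - nuc_xy[i, 1])^2 + (Y - nuc_xy[i, 2])^2 <= nucleus_radius_um^2
      nuc_mask <- nuc_mask | inside
      nuc_lab[inside] <- i
    }
    nuclear_img <- nucleus_amplitude * nuc_mask
    if (n_nuclei > 0) {
      nuclear_img <- as.matrix(EBImage::gblur(nuclear_img,
                                              sigma = 0.5 / pixel_size_um))
    }

    n_pos <- round(eu_positive_fraction * n_nuclei)
    flags <- rep(FALSE, n_nuclei)
    if (n_pos > 0) flags[sample.int(n_nuclei, n_pos)] <- TRUE
    eu_means <- ifelse(flags, rnorm(n_nuclei, eu_pos_mean, eu_sd),
                       rnorm(n_nuclei, eu_neg_mean, eu_sd))
    eu_means <- pmax(eu_means, 0)
    eu_img <- matrix(5, npx, npx)  # faint extranuclear background
    if (n_nuclei > 0) eu_img[nuc_lab > 0] <- eu_means[nuc_lab[nuc_lab > 0]]

    add_noise <- function(m) pmax(m + rnorm(length(m), 0, noise_sd), 0)
    list(
      particle_image = calibrated_image(add_noise(particle_img),
                                        pixel_size_um, channel = "yopro"),
      nuclear_image = calibrated_image(add_noise(nuclear_img),
                                       pixel_size_um, channel = "hoechst"),
      eu_image = calibrated_image(add_noise(eu_img), pixel_size_um,
                                  channel = "eu"),
      truth = list(
        particle_coords_um = tibble::tibble(x_um = par_xy[, 1], y_um = par_xy[, 2]),
        nucleus_coords_um = tibble::tibble(x_um = nuc_xy[, 1], y_um = nuc_xy[, 2]),
        eu_positive = flags, eu_means = eu_means, seed = seed)
    )
  })
}
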