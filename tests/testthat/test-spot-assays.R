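# helper: render Gaussian spots at given coordinates/amplitudes/sigmas
spot_image <- function(coords_um, amps, sigmas_um, size_um = 100, ps = 0.5,
                       noise_sd = 0, seed = 1) {
  set.seed(seed)
  npx <- round(size_um / ps)
  pxy <- ((seq_len(npx) - 1) + 0.5) * ps
  X <- matrix(pxy, npx, npx, byrow = TRUE)
  Y <- matrix(pxy, npx, npx)
  img <- matrix(0, npx, npx)
  for (i in seq_len(nrow(coords_um))) {
    img <- img + amps[i] * exp(-((X - coords_um[i, 1])^2 +
                                   (Y - coords_um[i, 2])^2) /
                                 (2 * sigmas_um[i]^2))
  }
  calibrated_image(pmax(img + rnorm(length(img), 0, noise_sd), 0), ps)
}

test_that("blank images yield zero particles and zero nuclei", {
  blank <- calibrated_image(matrix(1, 60, 60), pixel_size_um = 0.5)
  expect_warning(res <- detect_particles(blank), "threshold")
  expect_equal(res$count, 0)
  expect_equal(count_nuclei(blank)$count, 0)
})

test_that("well-separated particles are recovered exactly with accurate centroids", {
  up <- make_uptake_images(n_particles = 20, n_nuclei = 0,
                           min_separation_um = 10 * 0.75 * 2, seed = 11)
  res <- detect_particles(up$particle_image)
  expect_equal(res$count, 20)
  truth <- up$truth$particle_coords_um
  d <- as.matrix(dist(rbind(cbind(truth$x_um, truth$y_um),
                            cbind(res$particles$x_um, res$particles$y_um))))
  nearest <- apply(d[1:20, 21:40, drop = FALSE], 1, min)
  expect_true(all(nearest <= 0.5))  # within one 0.5 um pixel of truth
})

test_that("the size constraint and intensity threshold each remove their subset", {
  # 5 valid spots, 3 sub-threshold (low amplitude), 2 oversized (broad sigma)
  coords <- cbind(c(15, 35, 55, 75, 90, 15, 40, 65, 25, 70),
                  c(15, 15, 15, 15, 15, 50, 50, 50, 80, 80))
  amps <- c(rep(100, 5), rep(25, 3), rep(100, 2))
  sig <- c(rep(0.75, 8), rep(4, 2))
  img <- spot_image(coords, amps, sig, noise_sd = 1, seed = 4)
  res <- detect_particles(img, spot_params(min_diameter_um = 1,
                                           max_diameter_um = 4,
                                           intensity_threshold = 20))
  expect_equal(res$count, 5)
  expect_true(all(res$particles$y_um < 30))  # only the valid row survives
})

test_that("particles-per-nucleus is invariant to joint intensity/threshold rescaling", {
  up <- make_uptake_images(n_particles = 12, n_nuclei = 10, seed = 21,
                           image_size_um = 150)
  a <- detect_particles(up$particle_image, spot_params(intensity_threshold = 20))
  scaled <- calibrated_image(as_pixel_matrix(up$particle_image) * 3,
                             pixel_size_um(up$particle_image))
  b <- detect_particles(scaled, spot_params(intensity_threshold = 60))
  expect_equal(a$count, b$count)
})

test_that("nuclei are counted exactly on separated fields; watershed splits fusions", {
  up <- make_uptake_images(n_particles = 0, n_nuclei = 50, seed = 31,
                           image_size_um = 250)
  expect_equal(count_nuclei(up$nuclear_image)$count, 50)

  # two discs 8 um apart (radius 5): fused without watershed, split with it
  npx <- 200
  pxy <- ((seq_len(npx) - 1) + 0.5) * 0.5
  X <- matrix(pxy, npx, npx, byrow = TRUE)
  Y <- matrix(pxy, npx, npx)
  discs <- 150 * (((X - 46)^2 + (Y - 50)^2 <= 25) |
                    ((X - 54)^2 + (Y - 50)^2 <= 25))
  fused <- calibrated_image(discs, pixel_size_um = 0.5)
  expect_equal(count_nuclei(fused, watershed = FALSE)$count, 1)
  expect_equal(count_nuclei(fused, watershed = TRUE)$count, 2)
})

test_that("uptake summaries average normalized counts per animal", {
  rec <- tibble::tibble(animal = "j1",
                        n_particles = c(10, 20, 0, 6),
                        n_nuclei = c(5, 10, 10, 3))
  out <- uptake_summary(rec)
  expect_equal(out$mean_normalized, mean(c(2, 2, 0, 2)))
  expect_equal(out$n_images, 4)

  rec0 <- dplyr::mutate(rec, n_particles = 0)
  expect_equal(uptake_summary(rec0)$mean_normalized, 0)

  rec_bad <- rec
  rec_bad$n_nuclei[3] <- 0
  # dropping the zero-nuclei record also leaves 3 of the expected 4 images
  expect_warning(expect_warning(out2 <- uptake_summary(rec_bad), "zero nuclei"),
                 "expected 4")
  expect_equal(out2$mean_normalized, 2)
})

test_that("transcription positivity recovers the generated fraction", {
  up <- make_uptake_images(n_particles = 0, n_nuclei = 40,
                           eu_positive_fraction = 0.75, image_size_um = 220,
                           seed = 41)
  res <- eu_positive_fraction(up$eu_image, up$nuclear_image)
  expect_equal(res$fraction, 0.75)
  expect_equal(res$n_positive, 30)
  expect_equal(nrow(res$per_nucleus), 40)

  # all nuclei identically bright -> fraction 1 under an absolute threshold
  allhigh <- make_uptake_images(n_particles = 0, n_nuclei = 15, eu_sd = 1e-9,
                                eu_positive_fraction = 1, image_size_um = 150,
                                noise_sd = 0, seed = 42)
  res1 <- eu_positive_fraction(allhigh$eu_image, allhigh$nuclear_image,
                               threshold = 60)
  expect_equal(res1$fraction, 1)

  # Otsu split is scale invariant while the modes stay separable
  doubled <- calibrated_image(as_pixel_matrix(up$eu_image) * 2,
                              pixel_size_um(up$eu_image))
  expect_equal(eu_positive_fraction(doubled, up$nuclear_image)$fraction, 0.75)

  blank <- calibrated_image(matrix(0, 440, 440), pixel_size_um = 0.5)
  expect_error(eu_positive_fraction(up$eu_image, blank), "No nuclei")
})
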