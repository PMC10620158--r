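test_that("profile extraction samples by bilinear interpolation", {
  # constant image -> constant profile of the line's length
  img <- calibrated_image(matrix(7, 21, 21), pixel_size_um = 0.5)
  prof <- extract_profile(img, c(2, 2), c(18, 18), step_px = 0.5)
  expect_true(all(prof$intensity == 7))
  expect_equal(max(prof$position_um), floor(sqrt(2 * 16^2) / 0.5) * 0.5 * 0.5)

  # single bright column: maximum lands within half a pixel of the column
  px <- matrix(0, 21, 21); px[, 11] <- 100  # 0-based col 10
  img2 <- calibrated_image(px, pixel_size_um = 1)
  prof2 <- extract_profile(img2, c(10, 0), c(10, 20), step_px = 0.5)
  expect_lt(abs(prof2$position_um[which.max(prof2$intensity)] - 10), 0.5 + 1e-9)
  # off-lattice samples agree with the hand formula for this image:
  # value(c) = 100 * (1 - |c - 10|) for |c - 10| <= 1
  expect_equal(prof2$intensity[prof2$position_um == 9.5], 50)
  expect_equal(prof2$intensity[prof2$position_um == 10.5], 50)

  # swapping the wound end reverses the profile
  px3 <- matrix(seq_len(21), 21, 21, byrow = TRUE)
  img3 <- calibrated_image(px3 + 0, pixel_size_um = 1)
  a <- extract_profile(img3, c(5, 0), c(5, 20), wound_end = "start", step_px = 1)
  b <- extract_profile(img3, c(5, 0), c(5, 20), wound_end = "end", step_px = 1)
  expect_equal(a$intensity, rev(b$intensity))

  expect_error(extract_profile(img, c(0, 0), c(50, 50)), "exits")
})

test_that("baseline correction is an opening subtraction with its invariances", {
  # constant profile -> all zeros
  flat <- new_profile(seq(0, 100, 0.5), rep(11, 201))
  expect_true(all(correct_baseline(flat)$intensity == 0))

  # offset invariance
  sim <- make_profile(3, amplitudes = c(50, 40, 30), noise_sd = 3, seed = 2)
  shifted <- sim$profile
  shifted$intensity <- shifted$intensity + 100
  expect_equal(correct_baseline(sim$profile)$intensity,
               correct_baseline(shifted)$intensity, tolerance = 1e-12)

  # Gaussian (FWHM 30, amp 100) on a ramp survives an 80 um window
  pos <- seq(0, 300, 0.5)
  x <- 0.1 * pos + 100 * exp(-(pos - 150)^2 / (2 * (30 / 2.355)^2))
  corrected <- correct_baseline(new_profile(pos, x), window_um = 80)
  expect_equal(max(corrected$intensity), 100, tolerance = 0.05)

  expect_error(correct_baseline(new_profile(c(0, 50, 100), c(1, 2, 1)),
                                window_um = 10), "fewer than 3 samples")
})

test_that("baseline opening equals the brute-force opening at every sample", {
  for (s in 1:10) {
    prof <- random_profile(s, max_samples = 600)
    dx <- prof$position_um[2] - prof$position_um[1]
    h <- round(80 / (2 * dx))
    got <- correct_baseline(prof, window_um = 80)$intensity
    expect_equal(got, prof$intensity - oracle_opening(prof$intensity, h),
                 tolerance = 1e-12)
  }
})

test_that("peak detection honours the 20-40 um width band", {
  # strictly monotone ramp has no interior maxima
  ramp <- new_profile(seq(0, 100, 0.5), seq(0, 100, 0.5))
  expect_equal(nrow(detect_peaks(ramp, peak_params(min_prominence = 0))), 0)

  # of a 30 um and a 10 um bump, only the 30 um bump is a cell edge
  pos <- seq(0, 300, 0.5)
  x <- 100 * exp(-(pos - 100)^2 / (2 * (30 / 2.355)^2)) +
    100 * exp(-(pos - 220)^2 / (2 * (10 / 2.355)^2))
  pk <- detect_peaks(new_profile(pos, x), peak_params(min_prominence = 10))
  expect_equal(nrow(pk), 1)
  expect_equal(pk$position_um, 100, tolerance = 1)
  expect_equal(pk$width_um, 30, tolerance = 1.5)

  # plateau maxima resolve to their centre sample
  y <- rep(0, 201); y[90:110] <- 5
  y <- y + 20 * exp(-((seq_along(y) - 100) * 0.5)^2 / (2 * 100))
  prof <- new_profile(seq(0, 100, 0.5), rep(0, 201))
  prof$intensity[80:120] <- 10  # flat-top plateau, 20 um wide
  pk2 <- detect_peaks(prof, peak_params(min_prominence = 1))
  expect_equal(pk2$index, 100)

  expect_error(detect_peaks(new_profile(seq(0, 10, 0.5), rep(1, 21))),
               "shorter than")
})

test_that("peak detection matches the exhaustive brute-force oracle", {
  params <- peak_params(min_prominence = 12)
  for (s in 1:50) {
    prof <- random_profile(s + 100)
    got <- detect_peaks(prof, params)
    want <- oracle_peaks(prof$position_um, prof$intensity, 20, 40, 12)
    expect_identical(got$index, as.integer(want$index))
    expect_equal(got$amplitude, want$amplitude, tolerance = 1e-12)
    expect_equal(got$prominence, want$prominence, tolerance = 1e-12)
    expect_equal(got$width_um, want$width_um, tolerance = 1e-12)
  }
})

test_that("cell-edge assignment and ratios follow their definitions", {
  pk <- tibble::tibble(position_um = c(30, 80, 130, 180),
                       amplitude = c(200, 100, 80, 60),
                       prominence = c(200, 100, 80, 60),
                       width_um = rep(30, 4), index = 1:4)
  ce <- assign_cell_edges(pk)
  expect_equal(ce$ratio, c(1, 0.5, 0.4, 0.3))

  ce_eq <- assign_cell_edges(dplyr::mutate(pk, amplitude = 70))
  expect_equal(ce_eq$ratio, rep(1, 4))

  ce2 <- assign_cell_edges(pk[1:2, ])
  expect_equal(ce2$ratio, c(1, 0.5, NA, NA))
  expect_equal(ce2$qc[1], "ok")

  ce0 <- assign_cell_edges(pk[0, ])
  expect_true(all(is.na(ce0$amplitude)))
  expect_equal(ce0$qc[1], "no_peaks")
})

test_that("ratios are invariant to intensity scale and offset", {
  sim <- make_profile(4, amplitudes = c(150, 90, 60, 45), noise_sd = 0, seed = 3)
  base <- analyze_profile(sim$profile)
  scaled <- sim$profile
  scaled$intensity <- scaled$intensity * 3.7
  offset <- sim$profile
  offset$intensity <- offset$intensity + 55
  expect_equal(analyze_profile(scaled)$ratio, base$ratio, tolerance = 1e-9)
  expect_equal(analyze_profile(offset)$ratio, base$ratio, tolerance = 1e-6)
})

test_that("aggregation averages lines within wounds, then wounds within animals", {
  lines <- tidyr::expand_grid(animal = "a1", wound = 1:2, line = 1:4) |>
    dplyr::mutate(rank = list(factor(c("margin", "cell1"),
                                     levels = c("margin", "cell1")))) |>
    tidyr::unnest("rank")
  lines$amplitude <- ifelse(lines$rank == "margin", 200, 100)
  lines$ratio <- NA_real_
  lines$ratio[lines$rank == "margin"] <- 1
  # wound 1 cell1 ratios {0.5, 0.7, 0.6, 0.6} -> 0.6; wound 2 all 0.8
  lines$ratio[lines$rank == "cell1" & lines$wound == 1] <- c(0.5, 0.7, 0.6, 0.6)
  lines$ratio[lines$rank == "cell1" & lines$wound == 2] <- 0.8
  agg <- aggregate_ratios(lines)
  expect_equal(agg$mean_ratio[agg$rank == "cell1"], mean(c(0.6, 0.8)))
  expect_equal(agg$n_wounds[1], 2)
  expect_equal(agg$n_lines[1], 8)

  # 9 lines in a wound computes but warns
  lines9 <- tidyr::expand_grid(animal = "a2", wound = 1, line = 1:9) |>
    dplyr::mutate(rank = factor("cell1", levels = c("margin", "cell1")),
                  amplitude = 90, ratio = 0.5)
  expect_warning(aggregate_ratios(lines9), "4-8")

  # an animal with no usable lines is excluded with a message
  lines_na <- dplyr::mutate(lines9, amplitude = NA_real_, ratio = NA_real_)
  both <- dplyr::bind_rows(lines, lines_na)
  expect_message(expect_warning(agg2 <- aggregate_ratios(both)),
                 "no usable lines")
  expect_false("a2" %in% agg2$animal)
})
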