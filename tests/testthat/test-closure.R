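test_that("percent-of-original follows the measurement grid and closed forms", {
  # constant area -> 100% everywhere
  sim <- make_closure_series(rate_constant_per_min = 0, n_frames = 101)
  pct <- percent_of_original(sim$series)
  expect_true(all(pct$percent_of_original == 100))
  # every-10th-frame sampling at 11 s intervals
  expect_equal(pct$frame[1:3], c(0, 10, 20))
  expect_equal(pct$time_s[1:3], c(0, 110, 220))

  # noiseless exponential halves at t = 10 min for k = ln2/10
  k <- log(2) / 10
  sim2 <- make_closure_series(rate_constant_per_min = k, n_frames = 120)
  pct2 <- percent_of_original(sim2$series)
  expect_equal(pct2$percent_of_original,
               100 * exp(-k * pct2$time_min), tolerance = 1e-12)

  # invariant under rescaling all areas
  scaled <- sim2$series
  scaled$area_mm2 <- scaled$area_mm2 * 17
  expect_equal(percent_of_original(scaled)$percent_of_original,
               pct2$percent_of_original)

  # wound expansion beyond 100% is kept
  exp_series <- tibble::tibble(frame = seq(0, 40, 10),
                               area_mm2 = c(0.05, 0.06, 0.05, 0.04, 0.03))
  expect_gt(max(percent_of_original(exp_series)$percent_of_original), 100)

  zero <- tibble::tibble(frame = c(0, 10, 20), area_mm2 = c(0, 1, 1))
  expect_error(percent_of_original(zero), "zero")
})

test_that("initial closure rate is the least-squares early slope", {
  lin <- tibble::tibble(frame = seq(0, 150, 10),
                        area_mm2 = 0.05 * (1 - 0.02 * seq(0, 150, 10) * 11 / 60))
  pct <- percent_of_original(lin)
  expect_equal(initial_closure_rate(pct), -2, tolerance = 1e-9)

  flat <- percent_of_original(tibble::tibble(frame = seq(0, 100, 10),
                                             area_mm2 = 0.04))
  expect_equal(initial_closure_rate(flat), 0)

  short <- percent_of_original(tibble::tibble(frame = c(0, 10),
                                              area_mm2 = c(0.05, 0.04)))
  expect_error(initial_closure_rate(short), ">= 3 points")

  # noisy exponential: mean estimated rate within 10% of the model slope
  k <- log(2) / 10
  true_slope <- unname(coef(lm(y ~ t, data.frame(
    t = seq(0, 10, 11 * 10 / 60), y = 100 * exp(-k * seq(0, 10, 11 * 10 / 60)))))[2])
  est <- vapply(1:20, function(s) {
    sim <- make_closure_series(rate_constant_per_min = k, n_frames = 60,
                               noise_cv = 0.05, seed = s)
    initial_closure_rate(percent_of_original(sim$series))
  }, numeric(1))
  expect_equal(mean(est), true_slope, tolerance = abs(0.1 * true_slope))
})

test_that("group summaries report mean, SEM, n and per-timepoint tests", {
  # identical series in one group -> SEM 0
  one <- simulate_curves(c(ctrl = 0.05), n_per_group = 3, seed0 = 1,
                         noise_cv = 0)
  gs <- group_closure_summary(one)
  expect_true(all(gs$sem == 0))
  expect_true(all(is.na(gs$p_value)))

  # n = 1 group: mean reported, SEM undefined
  single <- dplyr::filter(one, .data$wound_id == "ctrl_1")
  gs1 <- group_closure_summary(single)
  expect_true(all(is.na(gs1$sem)))

  # two groups with 2x different rate constants separate early (fixed seeds)
  two <- simulate_curves(c(ctrl = 0.05, fast = 0.1), n_per_group = 10,
                         seed0 = 10, n_frames = 120, noise_cv = 0.05)
  gs2 <- group_closure_summary(two)
  early <- dplyr::filter(gs2, .data$time_min > 5, .data$time_min <= 15,
                         !duplicated(.data$time_min) | TRUE)
  expect_true(any(early$p_value < 0.05))
  late_mean <- dplyr::filter(gs2, .data$time_min == max(.data$time_min))
  expect_lt(late_mean$mean[late_mean$treatment == "fast"][1],
            late_mean$mean[late_mean$treatment == "ctrl"][1])

  # three groups use one-way ANOVA at each timepoint
  three <- simulate_curves(c(a = 0.05, b = 0.05, c = 0.1), n_per_group = 4,
                           seed0 = 40, n_frames = 60, noise_cv = 0.05)
  gs3 <- group_closure_summary(three)
  expect_true(all(grepl("ANOVA", gs3$method[!is.na(gs3$method)])))
})

test_that("per-timepoint tests hold their size on null groups", {
  # two groups from the same generator: rejection rate ~ alpha
  nrep <- 400
  pvals <- vapply(seq_len(nrep), function(r) {
    d <- purrr::map_dfr(1:5, function(i) {
      purrr::map_dfr(c("a", "b"), function(trt) {
        sim <- make_closure_series(rate_constant_per_min = 0.05, n_frames = 31,
                                   noise_cv = 0.1,
                                   seed = r * 100 + i * 10 + (trt == "b"))
        pct <- percent_of_original(sim$series)
        pct <- pct[pct$time_min > 0, ]  # t = 0 is exactly 100 for all wounds
        pct$wound_id <- paste0(trt, i)
        pct$treatment <- trt
        pct
      })
    })
    gs <- group_closure_summary(d)
    gs$p_value[!duplicated(gs$time_min)]
  }, numeric(3))
  rate <- mean(pvals < 0.05)
  expect_lt(abs(rate - 0.05), 0.015)
})
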