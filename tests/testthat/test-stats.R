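test_that("t test matches its frozen reference values and trivial identities", {
  # identical groups: t = 0, p = 1
  same <- unpaired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # frozen worked example (verified against reference implementations)
  tt <- unpaired_t_test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(tt$statistic, -1.224745, tolerance = 1e-6)
  expect_equal(tt$df, 4)
  expect_equal(tt$p_value, 0.2878641, tolerance = 1e-6)

  # zero variance in both groups with equal means
  flat <- unpaired_t_test(c(2, 2), c(2, 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  expect_error(unpaired_t_test(1, c(1, 2)), "at least 2")
})

test_that("t, ANOVA and Tukey agree with the stats-package oracles on seeded fixtures", {
  set.seed(7)
  for (i in 1:100) {
    k <- sample(2:4, 1)
    ns <- sample(3:8, k, replace = TRUE)
    g <- purrr::map(ns, ~ rnorm(.x, mean = runif(1, 0, 3), sd = runif(1, 0.5, 2)))
    names(g) <- paste0("g", seq_len(k))
    df <- data.frame(value = unlist(g), group = rep(names(g), ns))

    av <- one_way_anova(g)
    ref_av <- anova(aov(value ~ group, df))
    expect_equal(av$statistic, ref_av$`F value`[1], tolerance = 1e-8)
    expect_equal(av$p_value, ref_av$`Pr(>F)`[1], tolerance = 1e-8)

    tk <- tidy(tukey_hsd(g))
    ref_tk <- as.data.frame(TukeyHSD(aov(value ~ group, df))$group)
    key <- paste(tk$group2, tk$group1, sep = "-")
    expect_equal(tk$estimate, ref_tk[key, "diff"], tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(tk$p_adj, ref_tk[key, "p adj"], tolerance = 1e-6,
                 ignore_attr = TRUE)

    tt <- unpaired_t_test(g[[1]], g[[2]])
    ref_tt <- t.test(g[[1]], g[[2]], var.equal = TRUE)
    expect_equal(tt$statistic, unname(ref_tt$statistic), tolerance = 1e-8)
    expect_equal(tt$p_value, ref_tt$p.value, tolerance = 1e-8)
    tw <- unpaired_t_test(g[[1]], g[[2]], equal_variance = FALSE)
    ref_tw <- t.test(g[[1]], g[[2]])
    expect_equal(tw$statistic, unname(ref_tw$statistic), tolerance = 1e-8)
    expect_equal(tw$df, unname(ref_tw$parameter), tolerance = 1e-8)
  }
})

test_that("two-group identities hold: F = t^2 and Tukey p = ANOVA p", {
  set.seed(11)
  x <- rnorm(6); y <- rnorm(7, 0.8)
  tt <- unpaired_t_test(x, y)
  av <- one_way_anova(list(x = x, y = y))
  expect_equal(av$statistic, tt$statistic^2, tolerance = 1e-10)
  tk <- tidy(tukey_hsd(list(x = x, y = y)))
  expect_equal(tk$p_adj, av$p_value, tolerance = 1e-6)
})

test_that("degenerate inputs give the documented boundary results", {
  av0 <- one_way_anova(list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3)))
  expect_gt(av0$p_value, 0.99)
  allsame <- one_way_anova(list(a = c(2, 2), b = c(2, 2)))
  expect_equal(allsame$statistic, 0)
  expect_equal(allsame$p_value, 1)
})

test_that("group summaries compute SEM from the sample sd", {
  s <- summarize_group(c(2, 2, 2))
  expect_equal(s$mean, 2)
  expect_equal(s$sem, 0)
  s2 <- summarize_group(c(1, 3))
  expect_equal(s2$mean, 2)
  expect_equal(s2$sem, 1)
  s3 <- summarize_group(5)
  expect_equal(s3$mean, 5)
  expect_true(is.na(s3$sem))
  expect_error(summarize_group(numeric(0)), "at least 1")
})

test_that("tidy and glance expose broom-style summaries", {
  tt <- unpaired_t_test(c(1, 2, 3), c(2, 3, 4))
  td <- tidy(tt)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$p_value, tt$p_value)
  gl <- glance(one_way_anova(list(a = 1:3, b = 2:4)))
  expect_equal(gl$df1, 1)
  expect_equal(gl$df2, 4)
})

test_that("tests hold their nominal size under null simulations", {
  set.seed(2026)
  n <- 10
  t_rej <- mean(vapply(1:2000, function(i) {
    unpaired_t_test(rnorm(n), rnorm(n))$p_value < 0.05
  }, logical(1)))
  expect_lt(abs(t_rej - 0.05), 0.015)

  a_rej <- mean(vapply(1:2000, function(i) {
    one_way_anova(list(rnorm(6), rnorm(6), rnorm(6)))$p_value < 0.05
  }, logical(1)))
  expect_lt(abs(a_rej - 0.05), 0.015)

  # family-wise error of Tukey across 3 null groups
  fwer <- mean(vapply(1:2000, function(i) {
    any(tukey_hsd(list(rnorm(6), rnorm(6), rnorm(6)))$pairs$p_adj < 0.05)
  }, logical(1)))
  expect_lte(fwer, 0.06)
})
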