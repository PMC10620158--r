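# Classical group statistics computed from their standard definitions, with
# the animal-level datapoint as the experimental unit. tidy()/glance()
# methods give broom-style access to the results.

new_htest <- function(method, statistic, df, p_value, estimate = NULL,
                      pairs = NULL) {
  structure(list(method = method, statistic = statistic, df = df,
                 p_value = p_value, estimate = estimate, pairs = pairs),
            class = "ew_htest")
}

#' @export
print.ew_htest <- function(x, ...) {
  cat(sprintf("%s\n  statistic = %.6g, df = %s, p = %.6g\n", x$method,
              x$statistic, paste(format(x$df), collapse = ", "), x$p_value))
  if (!is.null(x$pairs)) {
    cat("  pairwise:\n")
    print(as.data.frame(x$pairs), row.names = FALSE)
  }
  invisible(x)
}

#' @export
tidy.ew_htest <- function(x, ...) {
  if (!is.null(x$pairs)) return(x$pairs)
  tibble::tibble(method = x$method, statistic = x$statistic,
                 df = list(x$df), p_value = x$p_value)
}

#' @export
glance.ew_htest <- function(x, ...) {
  tibble::tibble(method = x$method, statistic = x$statistic,
                 df1 = x$df[1], df2 = if (length(x$df) > 1) x$df[2] else NA_real_,
                 p_value = x$p_value)
}

check_group <- function(x, name, min_n = 2L) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    rlang::abort(sprintf("`%s` must be finite numeric values.", name))
  }
  if (length(x) < min_n) {
    rlang::abort(sprintf("`%s` needs at least %d values, got %d.",
                         name, min_n, length(x)))
  }
  invisible(x)
}

#' Unpaired two-tailed t test
#'
#' Student's pooled-variance t test by default, mirroring the assay's
#' reporting; Welch's unequal-variance form behind `equal_variance = FALSE`.
#' When both groups have zero variance and equal means the statistic is 0
#' with p = 1.
#'
#' @param x,y Numeric vectors, one value per animal (n >= 2 each).
#' @param equal_variance Pool the variances (default `TRUE`).
#' @return An `ew_htest` with `statistic` (t), `df`, two-tailed `p_value`,
#'   and `estimate` (mean difference x - y).
#' @examples
#' unpaired_t_test(c(1, 2, 3), c(2, 3, 4))
#' @export
unpaired_t_test <- function(x, y, equal_variance = TRUE) {
  check_group(x, "x"); check_group(y, "y")
  nx <- length(x); ny <- length(y)
  mx <- mean(x); my <- mean(y)
  vx <- stats::var(x); vy <- stats::var(y)
  if (equal_variance) {
    df <- nx + ny - 2
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / df
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    method <- "Unpaired two-tailed t test (pooled variance)"
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- if (se > 0) {
      (vx / nx + vy / ny)^2 /
        ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
    } else {
      nx + ny - 2
    }
    method <- "Unpaired two-tailed t test (Welch)"
  }
  if (se == 0) {
    tstat <- if (mx == my) 0 else sign(mx - my) * Inf
    p <- if (mx == my) 1 else 0
  } else {
    tstat <- (mx - my) / se
    p <- 2 * pt(-abs(tstat), df)
  }
  new_htest(method, tstat, df, p, estimate = mx - my)
}

as_group_list <- function(groups) {
  if (is.data.frame(groups)) {
    need <- c("group", "value")
    if (!all(need %in% names(groups))) {
      rlang::abort("A data-frame input needs `group` and `value` columns.")
    }
    groups <- split(groups$value, groups$group)
  }
  if (!is.list(groups) || length(groups) < 2L) {
    rlang::abort("Need a list (or tidy data frame) of >= 2 groups.")
  }
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  purrr::iwalk(groups, function(g, nm) check_group(g, nm))
  groups
}

anova_components <- function(groups) {
  k <- length(groups)
  ns <- vapply(groups, length, integer(1))
  N <- sum(ns)
  means <- vapply(groups, mean, numeric(1))
  gm <- sum(ns * means) / N
  ss_b <- sum(ns * (means - gm)^2)
  ss_w <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  list(k = k, ns = ns, N = N, means = means,
       ms_b = ss_b / (k - 1), ms_w = ss_w / (N - k))
}

#' Ordinary one-way ANOVA
#'
#' F = MS_between / MS_within on (k - 1, N - k) degrees of freedom. When all
#' values are identical the statistic is 0 with p = 1; when groups differ but
#' the within-group variance is zero, F is infinite with p = 0.
#'
#' @param groups Named list of numeric vectors (each n >= 2), or a tidy data
#'   frame with `group` and `value` columns.
#' @return An `ew_htest` with `statistic` (F), `df = c(k - 1, N - k)`,
#'   `p_value`.
#' @export
one_way_anova <- function(groups) {
  groups <- as_group_list(groups)
  cmp <- anova_components(groups)
  f <- if (cmp$ms_w == 0) {
    if (cmp$ms_b == 0) 0 else Inf
  } else {
    cmp$ms_b / cmp$ms_w
  }
  p <- if (is.infinite(f)) 0 else if (cmp$ms_w == 0) 1 else
    pf(f, cmp$k - 1, cmp$N - cmp$k, lower.tail = FALSE)
  new_htest("Ordinary one-way ANOVA", f, c(cmp$k - 1, cmp$N - cmp$k), p)
}

#' Tukey's HSD post hoc comparisons
#'
#' Pairwise comparisons after a one-way ANOVA using the studentized range
#' distribution (Tukey-Kramer for unequal group sizes); the family-wise error
#' rate is controlled at the nominal level. With two groups the adjusted
#' p-value equals the ANOVA p-value.
#'
#' @inheritParams one_way_anova
#' @return An `ew_htest` whose `pairs` tibble holds one row per pair:
#'   `group1`, `group2`, `estimate` (mean difference), `q`, `p_adj`;
#'   `tidy()` returns this table.
#' @export
tukey_hsd <- function(groups) {
  groups <- as_group_list(groups)
  cmp <- anova_components(groups)
  nm <- names(groups)
  pairs <- utils::combn(cmp$k, 2)
  rows <- purrr::map(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    diffm <- cmp$means[i2] - cmp$means[i1]
    se <- sqrt(cmp$ms_w / 2 * (1 / cmp$ns[i1] + 1 / cmp$ns[i2]))
    q <- if (se == 0) { if (diffm == 0) 0 else Inf } else abs(diffm) / se
    p <- if (is.infinite(q)) 0 else if (se == 0) 1 else
      ptukey(q, cmp$k, cmp$N - cmp$k, lower.tail = FALSE)
    tibble::tibble(group1 = nm[i1], group2 = nm[i2],
                   estimate = unname(diffm), q = unname(q),
                   p_adj = unname(p))
  })
  tab <- dplyr::bind_rows(rows)
  new_htest("Tukey HSD (studentized range)", max(tab$q),
            c(cmp$k, cmp$N - cmp$k), min(tab$p_adj), pairs = tab)
}

#' Group mean, SEM and n
#'
#' SEM uses the sample standard deviation (n - 1 denominator) divided by
#' sqrt(n) and is reported as missing at n = 1.
#'
#' @param values Numeric vector, one value per animal (n >= 1).
#' @return One-row tibble: `mean`, `sem`, `n`.
#' @export
summarize_group <- function(values) {
  check_group(values, "values", min_n = 1L)
  n <- length(values)
  tibble::tibble(mean = mean(values),
                 sem = if (n > 1) sd(values) / sqrt(n) else NA_real_,
                 n = n)
}
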