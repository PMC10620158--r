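# Internal helpers shared across modules.

# All randomness flows from a single integer seed per call; restore the
# caller's RNG state on exit so library calls never perturb user sessions.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
      rlang::abort("`seed` must be a single finite number.")
    }
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv(), inherits = FALSE)
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    rlang::abort(sprintf("`%s` must be a single positive finite number, got %s.",
                         name, paste(format(x), collapse = ", ")))
  }
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    rlang::abort(sprintf("`%s` must be non-negative and finite.", name))
  }
  invisible(x)
}

# Robust noise scale of a 1-D signal from first differences; insensitive to
# smooth structure (peaks, ramps) because differencing removes it.
robust_noise_sd <- function(x) {
  d <- diff(x)
  stats::median(abs(d - stats::median(d))) / (0.6744898 * sqrt(2))
}
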