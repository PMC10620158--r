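# Brute-force reference implementations used as independent oracles.

# Exhaustive peak enumeration: every interior local maximum (plateaus at the
# centre sample), prominence and half-prominence width computed by direct
# scans, then filtered to the width band and prominence floor.
oracle_peaks <- function(position_um, intensity, min_width_um, max_width_um,
                         min_prominence) {
  x <- intensity
  n <- length(x)
  dx <- (position_um[n] - position_um[1]) / (n - 1)
  out <- NULL
  for (i in 2:(n - 1)) {
    l <- i; while (l > 1 && x[l - 1] == x[i]) l <- l - 1
    r <- i; while (r < n && x[r + 1] == x[i]) r <- r + 1
    if (l == 1 || r == n) next
    if (!(x[l - 1] < x[i] && x[r + 1] < x[i])) next
    if (i != floor((l + r) / 2)) next
    # left: min over the run of samples <= x[i] reaching to the first
    # strictly higher sample (or the start); tie -> index nearest the peak
    j <- i; while (j > 1 && x[j - 1] <= x[i]) j <- j - 1
    seg <- j:i
    lmin <- min(x[seg])
    lb <- max(seg[x[seg] == lmin])
    j <- i; while (j < n && x[j + 1] <= x[i]) j <- j + 1
    seg <- i:j
    rmin <- min(x[seg])
    rb <- min(seg[x[seg] == rmin])
    prom <- x[i] - max(lmin, rmin)
    if (prom < min_prominence) next
    # width at half prominence by linear interpolation, bounded by the bases
    h <- x[i] - prom / 2
    k <- i; while (k > lb && x[k] > h) k <- k - 1
    left_ip <- if (x[k] < h) k + (h - x[k]) / (x[k + 1] - x[k]) else k
    k <- i; while (k < rb && x[k] > h) k <- k + 1
    right_ip <- if (x[k] < h) k - (h - x[k]) / (x[k - 1] - x[k]) else k
    w_um <- (right_ip - left_ip) * dx
    if (w_um < min_width_um || w_um > max_width_um) next
    out <- rbind(out, c(i, x[i], prom, w_um))
  }
  if (is.null(out)) {
    return(data.frame(index = integer(0), amplitude = numeric(0),
                      prominence = numeric(0), width_um = numeric(0)))
  }
  data.frame(index = out[, 1], amplitude = out[, 2], prominence = out[, 3],
             width_um = out[, 4])
}

# Morphological opening by its definition: the pointwise maximum, over all
# (truncated) windows containing i, of the window minimum.
oracle_opening <- function(x, h) {
  n <- length(x)
  mins <- vapply(seq_len(n), function(j) min(x[max(1, j - h):min(n, j + h)]),
                 numeric(1))
  vapply(seq_len(n), function(i) {
    max(mins[max(1, i - h):min(n, i + h)])
  }, numeric(1))
}

# Random test profiles with mixed structure for the oracle-equivalence
# property: a few smooth bumps, a drifting baseline, and noise.
random_profile <- function(seed, max_samples = 2000) {
  set.seed(seed)
  n <- sample(100:max_samples, 1)
  dx <- sample(c(0.5, 1), 1)
  pos <- (seq_len(n) - 1) * dx
  x <- 20 + 0.05 * pos * sample(c(-1, 0, 1), 1)
  for (b in seq_len(sample(0:6, 1))) {
    c0 <- runif(1, 0, max(pos))
    fwhm <- runif(1, 8, 60)
    a <- runif(1, 10, 200)
    x <- x + a * exp(-(pos - c0)^2 / (2 * (fwhm / 2.355)^2))
  }
  x <- x + rnorm(n, 0, runif(1, 0, 8))
  tibble::tibble(position_um = pos, intensity = pmax(x, 0))
}

# Small helper: tidy percent curves for a set of simulated wounds.
simulate_curves <- function(k_by_treatment, n_per_group, seed0,
                            n_frames = 120, noise_cv = 0.05) {
  purrr::imap_dfr(k_by_treatment, function(k, trt) {
    purrr::map_dfr(seq_len(n_per_group), function(i) {
      sim <- make_closure_series(rate_constant_per_min = k,
                                 n_frames = n_frames, noise_cv = noise_cv,
                                 seed = seed0 + i + round(1000 * k))
      pct <- percent_of_original(sim$series)
      pct$wound_id <- paste0(trt, "_", i)
      pct$treatment <- trt
      pct
    })
  })
}
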