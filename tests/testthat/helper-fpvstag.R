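# Shared fixtures and independent oracles for the test suite.
# Everything is generated in code; no binary fixtures.

# Literal brute-force implementation of the surrounding-bin baseline
# correction: per side take the next n_adj + n_used + 1 bins, drop the
# adjacent ones, pool both sides, sort, drop the single max and min, subtract
# the mean. Written as plainly as possible, independent of the vectorized
# package code path.
oracle_baseline_correct <- function(amp, n_used = 10L, n_adj = 1L, drop_extremes = TRUE) {
  n_bins <- ncol(amp)
  cps <- n_used + as.integer(drop_extremes)
  reach <- n_adj + cps
  out <- matrix(NA_real_, nrow(amp), n_bins, dimnames = dimnames(amp))
  for (s in seq_len(nrow(amp))) {
    for (b in seq_len(n_bins)) {
      if (b - reach < 1 || b + reach > n_bins) next
      left <- (b - reach):(b - n_adj - 1L)
      right <- (b + n_adj + 1L):(b + reach)
      cand <- amp[s, c(left, right)]
      if (drop_extremes) {
        cand <- sort(cand)
        cand <- cand[-c(1L, length(cand))]
      }
      out[s, b] <- amp[s, b] - mean(cand)
    }
  }
  out
}

# Dense-grid trapezoid evaluation of the JZS integral, independent of the
# package's adaptive quadrature.
oracle_jzs_bf10 <- function(t, n, r = 0.707, grid_n = 200001L) {
  nu <- n - 1
  u <- seq(-30, 30, length.out = grid_n)
  g <- exp(u)
  q <- 1 + n * g * r^2
  logf <- -0.5 * log(q) - (nu + 1) / 2 * log1p(t^2 / (q * nu)) -
    0.5 * log(2 * pi) - 1.5 * log(g) - 1 / (2 * g) + u
  integral <- sum(exp(logf)) * (u[2] - u[1])
  integral / (1 + t^2 / nu)^(-(nu + 1) / 2)
}

# End-to-end per-subject oddball responses through the package's spectral
# path: simulate trial-averaged epochs, FFT, baseline-correct the target bin,
# extract. Returns subjects x nodes matrices for the experimental and
# baseline conditions.
cohort_oddball_responses <- function(cfg, layout, n_subjects, n_trials, seed,
                                     f_target = cfg$f_odd, subject_cv = 0) {
  node_ids <- layout$sensor_id[layout$kind == "mag"]
  scales <- if (subject_cv > 0) {
    cfg2 <- cfg
    cfg2$subject_cv <- subject_cv
    fpvstag:::cohort_subject_scales(cfg2, n_subjects, seed)
  } else {
    rep(1, n_subjects)
  }
  one <- function(s, condition) {
    ep <- simulate_trial_average(cfg, layout, condition,
                                 seed = seed * 10000L + s * 4L + (condition == "experimental"),
                                 subject_scale = scales[s], n_trials = n_trials)
    sp <- compute_spectrum(ep)
    bin <- which.min(abs(sp$freqs - f_target))
    bc <- baseline_correct(sp, bins = bin)
    bc$amplitudes[node_ids, bin]
  }
  e <- t(vapply(seq_len(n_subjects), one, numeric(length(node_ids)), condition = "experimental"))
  b <- t(vapply(seq_len(n_subjects), one, numeric(length(node_ids)), condition = "baseline"))
  colnames(e) <- colnames(b) <- node_ids
  list(exp = e, base = b)
}

# Small helmet + graph used across inference tests.
small_helmet <- function(n_sites = 12L) make_sensor_layout(n_sites = n_sites)

expect_no_adjacent_repeats <- function(tokens) {
  expect_false(any(tokens[-1] == tokens[-length(tokens)]))
}
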