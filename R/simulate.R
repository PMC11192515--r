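#' Simulation configuration for frequency-tagged epochs
#'
#' Parameters of the synthetic FPVS generator. The generated epoch is a sum of
#' (i) a steady-state response: sinusoids at harmonics of the base
#' presentation rate `f_base`, present in every condition; (ii) an oddball
#' response: sinusoids at harmonics of the oddball rate `f_odd` that are not
#' multiples of `f_base`, present only in experimental sequences; and (iii)
#' Gaussian `1/f^beta` background noise. Both responses are weighted per
#' sensor by spatially smooth unit-peak Gaussian topographies.
#'
#' The epoch covers exactly `n_cycles` base cycles, i.e. `n_cycles / f_base`
#' seconds, so that `f_base`, `f_odd` and their harmonics fall exactly on FFT
#' bins. `fs * n_cycles / f_base` must be an integer number of samples; the
#' default `fs = 600` Hz gives 16000 samples for the 160-cycle, 6 Hz design.
#'
#' @param f_base Base stimulation frequency, Hz (default 6).
#' @param f_odd Oddball frequency, Hz (default 3); must divide `f_base` with
#'   an integer ratio >= 2.
#' @param n_cycles Number of base cycles per epoch (default 160).
#' @param fs Sampling rate, Hz (default 600).
#' @param base_amplitudes Named numeric vector: amplitude per base harmonic
#'   (names are harmonic numbers, frequency = h * f_base).
#' @param odd_amplitudes Named numeric vector: amplitude per oddball harmonic
#'   (names are harmonic numbers, frequency = k * f_odd). Harmonics that
#'   coincide with base harmonics are dropped at simulation time with a warning.
#' @param base_topography,odd_topography Lists `list(center = <3-vector>,
#'   width = <meters>)`: direction of the topography peak (normalized
#'   internally) and the standard deviation of the Gaussian falloff over
#'   great-circle distance.
#' @param noise_sigma Time-domain standard deviation of the background noise
#'   (same arbitrary field units as the amplitudes; default 1).
#' @param noise_beta Spectral exponent of the `1/f^beta` noise (default 1).
#' @param subject_cv Coefficient of variation of the per-subject amplitude
#'   scaling in cohort simulation (default 0.2).
#' @param seed Default integer seed.
#' @param phase_seed Optional seed for the harmonic phases; when `NULL` the
#'   epoch seed is used. Cohort simulation sets one shared phase seed so that
#'   responses are phase-locked across trials and subjects (coherent
#'   averaging preserves the signal).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(f_base = 6, f_odd = 3, n_cycles = 160, fs = 600,
                       base_amplitudes = c("1" = 1, "2" = 0.4),
                       odd_amplitudes = c("1" = 0.5),
                       base_topography = list(center = c(0, -0.8, 0.6), width = 0.06),
                       odd_topography = list(center = c(-0.7, -0.55, 0.45), width = 0.05),
                       noise_sigma = 1, noise_beta = 1, subject_cv = 0.2,
                       seed = 1L, phase_seed = NULL) {
  stopifnot_scalar_number(f_base, "f_base", positive = TRUE)
  stopifnot_scalar_number(f_odd, "f_odd", positive = TRUE)
  stopifnot_scalar_number(n_cycles, "n_cycles", positive = TRUE)
  stopifnot_scalar_number(fs, "fs", positive = TRUE)
  ratio <- f_base / f_odd
  if (abs(ratio - round(ratio)) > 1e-9 || round(ratio) < 2) {
    stop("f_odd must divide f_base exactly with integer ratio >= 2", call. = FALSE)
  }
  duration <- n_cycles / f_base
  if (abs(duration * f_odd - round(duration * f_odd)) > 1e-9) {
    stop("epoch duration n_cycles/f_base must be an integer multiple of 1/f_odd", call. = FALSE)
  }
  n <- fs * duration
  if (abs(n - round(n)) > 1e-6) {
    stop(sprintf(
      "fs * n_cycles / f_base = %.6f is not an integer sample count; choose fs so the epoch has a whole number of samples",
      n
    ), call. = FALSE)
  }
  if (any(base_amplitudes < 0) || any(odd_amplitudes < 0)) {
    stop("amplitudes must be >= 0", call. = FALSE)
  }
  h_base <- as.numeric(names(base_amplitudes) %||% seq_along(base_amplitudes))
  k_odd <- as.numeric(names(odd_amplitudes) %||% seq_along(odd_amplitudes))
  if (anyNA(h_base) || anyNA(k_odd)) stop("amplitude names must be harmonic numbers", call. = FALSE)
  fmax <- max(c(h_base * f_base, k_odd * f_odd, 0))
  if (fs <= 2 * fmax) stop("fs must exceed twice the highest simulated frequency", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  if (subject_cv < 0) stop("subject_cv must be >= 0", call. = FALSE)

  structure(list(
    f_base = f_base, f_odd = f_odd, n_cycles = n_cycles, fs = fs,
    base_amplitudes = stats::setNames(as.numeric(base_amplitudes), as.character(h_base)),
    odd_amplitudes = stats::setNames(as.numeric(odd_amplitudes), as.character(k_odd)),
    base_topography = base_topography, odd_topography = odd_topography,
    noise_sigma = noise_sigma, noise_beta = noise_beta, subject_cv = subject_cv,
    seed = as.integer(seed), phase_seed = phase_seed,
    duration = duration, n_samples = as.integer(round(n))
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> base %g Hz, oddball %g Hz, %g cycles (%.4f s) @ %g Hz (%d samples)\n",
    x$f_base, x$f_odd, x$n_cycles, x$duration, x$fs, x$n_samples
  ))
  cat(sprintf(
    "  noise: 1/f^%g, sigma = %g; subject CV = %g\n",
    x$noise_beta, x$noise_sigma, x$subject_cv
  ))
  invisible(x)
}

# Unit-peak Gaussian topography over great-circle distance from a center
# direction; positions is a (sensor x 3) matrix.
topography_weights <- function(positions, topo) {
  ctr <- topo$center / sqrt(sum(topo$center^2))
  r <- sqrt(rowSums(positions^2))
  r[r == 0] <- 1
  u <- positions / r
  ang <- acos(pmin(1, pmax(-1, u %*% ctr)))
  d <- as.numeric(ang) * mean(r)          # great-circle distance on the helmet
  exp(-d^2 / (2 * topo$width^2))
}

# Gaussian 1/f^beta noise, n_samples x n_series, exact time-domain SD sigma,
# by frequency-domain shaping of a white complex spectrum. Each complex FFT
# column yields two independent real series (real and imaginary parts of the
# inverse transform of circular complex noise with a symmetric spectral
# envelope), halving the transform cost.
pink_noise <- function(n, n_series, fs, beta, sigma) {
  if (sigma == 0) return(matrix(0, nrow = n, ncol = n_series))
  k <- seq_len(n - 1L)
  f <- pmin(k, n - k) * fs / n
  scale <- c(0, f^(-beta / 2))            # DC carries no noise
  m <- as.integer(ceiling(n_series / 2))
  Z <- matrix(complex(real = stats::rnorm(n * m),
                      imaginary = stats::rnorm(n * m)), nrow = n, ncol = m)
  Z <- Z * scale                          # recycles along columns
  Y <- stats::mvfft(Z, inverse = TRUE) / n
  sd_expected <- sqrt(sum(scale^2)) / n
  out <- matrix(0, nrow = n, ncol = 2L * m)
  out[, seq_len(m) * 2L - 1L] <- Re(Y)
  out[, seq_len(m) * 2L] <- Im(Y)
  out[, seq_len(n_series), drop = FALSE] * (sigma / sd_expected)
}

# Harmonic frequencies actually simulated for the oddball response: harmonics
# of f_odd that are not multiples of f_base (those coincide with the
# steady-state response and carry no discrimination information).
odd_harmonic_table <- function(config, warn = TRUE) {
  k <- as.numeric(names(config$odd_amplitudes))
  f <- k * config$f_odd
  collide <- abs(f / config$f_base - round(f / config$f_base)) < 1e-9
  if (any(collide) && warn) {
    warning(sprintf(
      "dropping oddball harmonic(s) %s: coincide with base harmonics",
      paste(k[collide], collapse = ",")
    ), call. = FALSE)
  }
  list(k = k[!collide], freq = f[!collide], amp = unname(config$odd_amplitudes[!collide]))
}

draw_phases <- function(config) {
  ps <- config$phase_seed %||% config$seed
  with_seed(ps, list(
    base = stats::runif(length(config$base_amplitudes), 0, 2 * pi),
    odd = stats::runif(length(config$odd_amplitudes), 0, 2 * pi)
  ))
}

#' Simulate one frequency-tagged epoch
#'
#' Returns a single trial as a (sensor x time) matrix: steady-state sinusoids
#' at base harmonics, oddball sinusoids (experimental condition only) at
#' oddball harmonics that are not base harmonics, and `1/f^beta` noise.
#' Harmonic phases are taken from `config$phase_seed` (falling back to `seed`)
#' so repeated trials of one run are phase-locked; noise is drawn from `seed`.
#'
#' @param config A [sim_config()].
#' @param layout A [make_sensor_layout()] layout.
#' @param condition `"experimental"` (with oddball response) or `"baseline"`.
#' @param seed Integer seed for the noise draw.
#' @param subject_scale Multiplier on all signal amplitudes (default 1);
#'   cohort simulation uses it for between-subject variability.
#' @return A matrix (sensors x samples) with `dimnames` carrying sensor ids;
#'   attributes `fs`, `t0`, `condition`.
#' @export
simulate_epoch <- function(config, layout, condition = c("experimental", "baseline"),
                           seed = config$seed, subject_scale = 1) {
  condition <- match.arg(condition)
  layout <- validate_sensor_layout(layout)
  n <- config$n_samples
  t <- (seq_len(n) - 1L) / config$fs
  pos <- as.matrix(layout[, c("x", "y", "z")])
  w_base <- topography_weights(pos, config$base_topography)
  w_odd <- topography_weights(pos, config$odd_topography)
  phases <- draw_phases(config)

  # one column per simulated harmonic: sensor weights (S x H) %*% sinusoids (H x n)
  hb <- as.numeric(names(config$base_amplitudes))
  freqs <- hb * config$f_base
  phs <- phases$base
  W <- w_base %o% unname(config$base_amplitudes)
  if (condition == "experimental") {
    oh <- odd_harmonic_table(config)
    if (length(oh$k)) {
      keep <- match(as.character(oh$k), names(config$odd_amplitudes))
      freqs <- c(freqs, oh$freq)
      phs <- c(phs, phases$odd[keep])
      W <- cbind(W, w_odd %o% oh$amp)
    }
  }
  SIN <- sin(outer(2 * pi * freqs, t) + phs)   # H x n (phase recycles by row)
  sig <- (W * subject_scale) %*% SIN

  if (config$noise_sigma > 0) {
    noise <- with_seed(seed, pink_noise(n, nrow(layout), config$fs, config$noise_beta,
                                        config$noise_sigma))
    sig <- sig + t(noise)
  }
  dimnames(sig) <- list(layout$sensor_id, NULL)
  attr(sig, "fs") <- config$fs
  attr(sig, "t0") <- 0
  attr(sig, "condition") <- condition
  sig
}

#' Simulate the average of several trials in one draw
#'
#' The signal component is identical across trials of a run (phases and
#' subject scaling are fixed), so the trial average equals signal plus the
#' average of `n_trials` independent Gaussian `1/f^beta` noises — which is
#' itself Gaussian `1/f^beta` noise with standard deviation
#' `noise_sigma / sqrt(n_trials)`. This draws that average directly, which is
#' distributionally exact and `n_trials` times cheaper than simulating and
#' averaging individual trials.
#'
#' @inheritParams simulate_epoch
#' @param n_trials Number of trials the returned epoch averages over.
#' @return A (sensors x samples) matrix as from [simulate_epoch()].
#' @export
simulate_trial_average <- function(config, layout, condition = c("experimental", "baseline"),
                                   seed = config$seed, subject_scale = 1, n_trials = 1L) {
  stopifnot_scalar_number(n_trials, "n_trials", positive = TRUE)
  cfg <- config
  cfg$noise_sigma <- config$noise_sigma / sqrt(n_trials)
  simulate_epoch(cfg, layout, condition, seed = seed, subject_scale = subject_scale)
}

#' Define a simulated condition
#'
#' @param label Condition label.
#' @param type `"experimental"` (carries an oddball response scaled by
#'   `odd_gain`) or `"baseline"` (no oddball response).
#' @param odd_gain Multiplier on the configured oddball amplitudes.
#' @return A list describing the condition.
#' @export
condition_spec <- function(label, type = c("experimental", "baseline"), odd_gain = 1) {
  type <- match.arg(type)
  stopifnot_scalar_number(odd_gain, "odd_gain")
  if (odd_gain < 0) stop("odd_gain must be >= 0", call. = FALSE)
  list(label = label, type = type, odd_gain = if (type == "baseline") 0 else odd_gain)
}

#' Simulate a cohort of subjects
#'
#' Draws per-subject amplitude scalings (mean 1, coefficient of variation
#' `config$subject_cv`, truncated at 0.05), fixes one shared set of harmonic
#' phases, and simulates `trials_per_condition` epochs per subject and
#' condition. The returned manifest records every drawn parameter so any run
#' is exactly reproducible from `(config, seed)`.
#'
#' @param config A [sim_config()].
#' @param layout A sensor layout.
#' @param n_subjects Number of subjects (>= 2).
#' @param trials_per_condition Trials per subject and condition.
#' @param conditions List of [condition_spec()] entries.
#' @param seed Master seed.
#' @return `list(epoch_sets, manifest)`; `epoch_sets` is a list of
#'   `epoch_set` objects (fields `subject_id`, `condition`, `data` as a
#'   trial x sensor x time array, `fs`, `t0`, `sensor_ids`).
#' @export
simulate_cohort <- function(config, layout, n_subjects, trials_per_condition,
                            conditions, seed = config$seed) {
  stopifnot_scalar_number(n_subjects, "n_subjects", positive = TRUE)
  if (n_subjects < 2) stop("n_subjects must be >= 2", call. = FALSE)
  stopifnot_scalar_number(trials_per_condition, "trials_per_condition", positive = TRUE)
  if (!length(conditions)) stop("at least one condition is required", call. = FALSE)
  n_subjects <- as.integer(n_subjects)
  trials_per_condition <- as.integer(trials_per_condition)

  scales <- cohort_subject_scales(config, n_subjects, seed)
  phase_seed <- derive_seed(seed, 1L)
  cfg <- config
  cfg$phase_seed <- phase_seed

  sets <- list()
  idx <- 0L
  for (s in seq_len(n_subjects)) {
    for (ci in seq_along(conditions)) {
      cond <- conditions[[ci]]
      ccfg <- condition_config(cfg, cond)
      dat <- array(NA_real_,
                   dim = c(trials_per_condition, nrow(layout), cfg$n_samples),
                   dimnames = list(NULL, layout$sensor_id, NULL))
      for (tr in seq_len(trials_per_condition)) {
        ep <- simulate_epoch(ccfg, layout,
                             condition = if (cond$type == "experimental") "experimental" else "baseline",
                             seed = trial_seed(seed, s, ci, tr),
                             subject_scale = scales[s])
        dat[tr, , ] <- ep
      }
      idx <- idx + 1L
      sets[[idx]] <- structure(list(
        subject_id = sprintf("sub%02d", s), condition = cond$label,
        data = dat, fs = cfg$fs, t0 = 0, sensor_ids = layout$sensor_id
      ), class = "epoch_set")
    }
  }

  manifest <- list(
    seed = as.integer(seed), phase_seed = phase_seed,
    n_subjects = n_subjects, trials_per_condition = trials_per_condition,
    subject_scales = stats::setNames(scales, sprintf("sub%02d", seq_len(n_subjects))),
    conditions = conditions,
    config = unclass(config)[c("f_base", "f_odd", "n_cycles", "fs", "base_amplitudes",
                               "odd_amplitudes", "noise_sigma", "noise_beta", "subject_cv")],
    duration_s = config$duration, n_samples = config$n_samples
  )
  list(epoch_sets = sets, manifest = manifest)
}

cohort_subject_scales <- function(config, n_subjects, seed) {
  with_seed(derive_seed(seed, 0L),
            pmax(0.05, 1 + config$subject_cv * stats::rnorm(n_subjects)))
}

condition_config <- function(cfg, cond) {
  ccfg <- cfg
  ccfg$odd_amplitudes <- cfg$odd_amplitudes * cond$odd_gain
  ccfg
}

trial_seed <- function(seed, subject, condition_index, trial) {
  derive_seed(seed, 1000000L + subject * 10000L + condition_index * 100L + trial)
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_set> subject %s, condition '%s': %d trial(s) x %d sensors x %d samples @ %g Hz\n",
    x$subject_id, x$condition, d[1], d[2], d[3], x$fs
  ))
  invisible(x)
}
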