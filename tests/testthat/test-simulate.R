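test_that("config validation enforces the frequency-tagging constraints", {
  cfg <- sim_config()
  expect_equal(cfg$duration, 160 / 6)
  expect_equal(cfg$n_samples, 16000L)
  expect_error(sim_config(f_base = 6, f_odd = 4), "integer ratio")
  expect_error(sim_config(fs = 1000), "integer sample count")
  expect_error(sim_config(fs = 21), "twice the highest")
  expect_error(sim_config(base_amplitudes = c("1" = -1)), ">= 0")
})

test_that("noise-free spectra equal configured amplitude times topography weight", {
  lay <- small_helmet(16)
  cfg <- sim_config(noise_sigma = 0)
  pos <- as.matrix(lay[, c("x", "y", "z")])
  w_odd <- fpvstag:::topography_weights(pos, cfg$odd_topography)
  w_base <- fpvstag:::topography_weights(pos, cfg$base_topography)

  ep <- simulate_epoch(cfg, lay, "experimental", seed = 5)
  sp <- compute_spectrum(ep)
  i3 <- which.min(abs(sp$freqs - 3))
  i6 <- which.min(abs(sp$freqs - 6))
  i12 <- which.min(abs(sp$freqs - 12))
  expect_lt(max(abs(sp$amplitudes[, i3] - 0.5 * w_odd) / pmax(0.5 * w_odd, 1e-12)), 1e-10)
  expect_lt(max(abs(sp$amplitudes[, i6] - 1.0 * w_base) / pmax(w_base, 1e-12)), 1e-10)
  expect_lt(max(abs(sp$amplitudes[, i12] - 0.4 * w_base) / pmax(0.4 * w_base, 1e-12)), 1e-10)

  # baseline condition carries no energy at the oddball frequency
  ep0 <- simulate_epoch(cfg, lay, "baseline", seed = 5)
  sp0 <- compute_spectrum(ep0)
  expect_lt(max(sp0$amplitudes[, i3]), 1e-12)
  i9 <- which.min(abs(sp0$freqs - 9))
  expect_lt(max(sp0$amplitudes[, i9]), 1e-12)
})

test_that("tagged frequencies fall exactly on FFT bins", {
  cfg <- sim_config()
  sp <- compute_spectrum(simulate_epoch(cfg, small_helmet(4), "baseline", seed = 1))
  k3 <- cfg$f_odd / sp$resolution
  k6 <- cfg$f_base / sp$resolution
  expect_equal(k3, round(k3))
  expect_equal(k6, round(k6))
  expect_equal(sp$freqs[k3 + 1], cfg$f_odd)
})

test_that("oddball harmonics colliding with base harmonics are dropped with a warning", {
  lay <- small_helmet(4)
  cfg <- sim_config(noise_sigma = 0, odd_amplitudes = c("1" = 0.5, "2" = 0.3))
  expect_warning(ep <- simulate_epoch(cfg, lay, "experimental", seed = 1),
                 "coincide with base harmonics")
  sp <- compute_spectrum(ep)
  i6 <- which.min(abs(sp$freqs - 6))
  pos <- as.matrix(lay[, c("x", "y", "z")])
  w_base <- fpvstag:::topography_weights(pos, cfg$base_topography)
  # the 6 Hz bin holds only the base response, not base + dropped harmonic
  expect_lt(max(abs(sp$amplitudes[, i6] - w_base)), 1e-10)
})

test_that("1/f^beta noise has the configured spectral slope and scale", {
  set.seed(1)
  P <- 0
  for (r in 1:60) {
    nn <- fpvstag:::pink_noise(4096, 4, 600, 1, 1)
    sp <- compute_spectrum(t(nn), fs = 600)
    P <- P + colMeans(sp$amplitudes^2)
  }
  f <- sp$freqs
  sel <- f >= 1 & f <= 40
  slope <- unname(coef(lm(log(P[sel]) ~ log(f[sel])))[2])
  expect_lt(abs(slope - (-1)), 0.1)

  set.seed(2)
  nn <- fpvstag:::pink_noise(16000, 60, 600, 1, 2.5)
  expect_lt(abs(sd(as.numeric(nn)) - 2.5), 0.1)
})

test_that("simulation is deterministic and subject variability behaves", {
  lay <- small_helmet(4)
  cfg <- sim_config(n_cycles = 20, fs = 300)
  e1 <- simulate_epoch(cfg, lay, "experimental", seed = 7)
  e2 <- simulate_epoch(cfg, lay, "experimental", seed = 7)
  expect_identical(e1, e2)
  e3 <- simulate_epoch(cfg, lay, "experimental", seed = 8)
  expect_false(identical(e1, e3))

  # subject_cv = 0 and no noise: all subjects identical
  cfg0 <- sim_config(n_cycles = 20, fs = 300, noise_sigma = 0, subject_cv = 0)
  coh <- simulate_cohort(cfg0, lay, n_subjects = 3, trials_per_condition = 2,
                         conditions = list(condition_spec("exp", "experimental")), seed = 1)
  d1 <- coh$epoch_sets[[1]]$data
  expect_identical(d1, coh$epoch_sets[[2]]$data)
  expect_identical(d1[1, , ], d1[2, , ])

  coh2 <- simulate_cohort(cfg0, lay, n_subjects = 3, trials_per_condition = 2,
                          conditions = list(condition_spec("exp", "experimental")), seed = 1)
  expect_identical(coh$epoch_sets, coh2$epoch_sets)
})

test_that("cohorts have the study shape and a complete manifest", {
  lay <- small_helmet(4)
  cfg <- sim_config(n_cycles = 20, fs = 300, noise_sigma = 0.5)
  conds <- c(
    lapply(1:5, function(i) condition_spec(paste0("c", i, "_exp"), "experimental")),
    lapply(1:5, function(i) condition_spec(paste0("c", i, "_base"), "baseline"))
  )
  coh <- simulate_cohort(cfg, lay, n_subjects = 21, trials_per_condition = 6,
                         conditions = conds, seed = 2)
  expect_length(coh$epoch_sets, 21L * 10L)
  expect_true(all(vapply(coh$epoch_sets, function(s) dim(s$data)[1], numeric(1)) == 6))
  expect_true(all(vapply(coh$epoch_sets, function(s) dim(s$data)[2], numeric(1)) == nrow(lay)))
  m <- coh$manifest
  expect_length(m$subject_scales, 21L)
  expect_equal(m$n_samples, cfg$n_samples)
  expect_equal(m$seed, 2L)
  scales <- m$subject_scales
  expect_gt(sd(scales), 0)
})

test_that("trial averages match explicit per-trial simulation in distribution moments", {
  lay <- small_helmet(4)
  cfg <- sim_config(n_cycles = 20, fs = 300, noise_sigma = 2, phase_seed = 99)
  sig <- simulate_epoch(sim_config(n_cycles = 20, fs = 300, noise_sigma = 0, phase_seed = 99),
                        lay, "baseline", seed = 1)
  # the collapsed draw has noise sd sigma/sqrt(T); check against the config
  set.seed(31)
  sds <- replicate(20, {
    avg <- simulate_trial_average(cfg, lay, "baseline",
                                  seed = sample.int(1e6, 1), n_trials = 4)
    sd(as.numeric(avg - sig))
  })
  expect_lt(abs(mean(sds) - 2 / sqrt(4)), 0.05)
})
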