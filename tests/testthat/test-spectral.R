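test_that("band-pass preserves the passband and attenuates the stopband", {
  fs <- 1000
  t <- (0:(10 * fs - 1)) / fs
  x6 <- sin(2 * pi * 6 * t)
  y <- filter_and_downsample(x6, band = c(0.1, 100), fs = fs, fs_new = 250)
  sp <- compute_spectrum(y, 250)
  a6 <- sp$amplitudes[1, which.min(abs(sp$freqs - 6))]
  expect_lt(abs(a6 - 1), 0.01)

  x120 <- sin(2 * pi * 120 * t)
  y2 <- filter_and_downsample(x120, band = c(0.1, 100), fs = fs, fs_new = 250)
  sp2 <- compute_spectrum(y2, 250)
  expect_lt(max(sp2$amplitudes), 0.05)

  # integer-factor decimation scales the sample count exactly
  set.seed(4)
  wn <- matrix(rnorm(3 * 4000), nrow = 3)
  yw <- filter_and_downsample(wn, band = c(0.1, 100), fs = 1000, fs_new = 250)
  expect_equal(ncol(yw), 1000L)
  expect_equal(attr(yw, "fs"), 250)

  expect_error(filter_and_downsample(x6, c(0.1, 100), fs, fs_new = 300), "integer decimation")
  expect_error(filter_and_downsample(x6, c(100, 0.1), fs, fs_new = 250), "low < high")
  expect_error(filter_and_downsample(x6, c(0.1, 130), fs, fs_new = 250), "below fs_new / 2")
})

test_that("epoch averaging is the arithmetic trial mean", {
  tr <- array(rnorm(5 * 3 * 20), dim = c(5, 3, 20))
  avg <- average_epochs(tr)
  expect_equal(dim(avg), c(3L, 20L))
  expect_equal(avg, colMeans(tr), ignore_attr = TRUE)

  same <- array(rep(tr[1, , ], each = 4), dim = c(4, 3, 20))
  expect_equal(average_epochs(same), tr[1, , ], ignore_attr = TRUE)

  pm <- array(0, dim = c(2, 3, 20))
  pm[1, , ] <- tr[1, , ]
  pm[2, , ] <- -tr[1, , ]
  expect_equal(max(abs(average_epochs(pm))), 0)
})

test_that("averaging n noise trials shrinks variance about n-fold", {
  set.seed(11)
  ratios <- replicate(20, {
    trials <- array(rnorm(100 * 1 * 500), dim = c(100, 1, 500))
    var(as.numeric(average_epochs(trials))) / var(as.numeric(trials[1, , ]))
  })
  expect_true(all(ratios * 100 > 0.7 & ratios * 100 < 1.4))
})

test_that("spectrum normalization recovers bin-aligned sinusoid amplitudes", {
  fs <- 120
  t <- (0:(fs * 4 - 1)) / fs
  x <- 2.5 * sin(2 * pi * 3 * t)
  sp <- compute_spectrum(x, fs)
  i3 <- which.min(abs(sp$freqs - 3))
  expect_lt(abs(sp$amplitudes[1, i3] - 2.5), 1e-9)
  expect_lt(max(sp$amplitudes[1, -i3]), 1e-9)
  expect_equal(sp$resolution, 0.25)
  expect_equal(sp$freqs[1], 0)

  x2 <- sin(2 * pi * 3 * t) + 0.5 * sin(2 * pi * 6 * t)
  sp2 <- compute_spectrum(x2, fs)
  expect_lt(abs(sp2$amplitudes[1, which.min(abs(sp2$freqs - 3))] - 1), 1e-9)
  expect_lt(abs(sp2$amplitudes[1, which.min(abs(sp2$freqs - 6))] - 0.5), 1e-9)
})

test_that("the trial-length epoch has the printed frequency resolution", {
  cfg <- sim_config(noise_sigma = 0)
  sp <- compute_spectrum(simulate_epoch(cfg, small_helmet(4), "baseline", seed = 1))
  expect_equal(sp$resolution, 6 / 160)          # 0.0375 Hz = 1 / (160/6 s)
  expect_equal(round(sp$resolution, 4), 0.0375)
})

test_that("planar pairs combine by root-sum-of-squares", {
  lay <- small_helmet(3)
  gids <- lay$sensor_id[lay$kind == "grad"]
  amp <- matrix(0, nrow(lay), 4, dimnames = list(lay$sensor_id, NULL))
  amp[gids[1], 2] <- 3
  amp[gids[4], 2] <- 4   # gids[1] and gids[4] belong to the same site pair
  pair_of <- lay$pair_id[match(gids, lay$sensor_id)]
  expect_equal(pair_of[1], pair_of[4])
  sp <- structure(list(amplitudes = amp, freqs = 0:3, resolution = 1, corrected = FALSE),
                  class = "amplitude_spectrum")
  cp <- combine_planar(sp, lay)
  expect_equal(unname(cp$amplitudes[pair_of[1], 2]), 5)
  # (a, 0) -> a, and symmetry under swapping pair members
  amp2 <- amp
  amp2[gids[4], 2] <- 0
  sp2 <- structure(list(amplitudes = amp2, freqs = 0:3, resolution = 1, corrected = FALSE),
                   class = "amplitude_spectrum")
  expect_equal(unname(combine_planar(sp2, lay)$amplitudes[pair_of[1], 2]), 3)
  amp3 <- amp
  amp3[gids[1], 2] <- 4
  amp3[gids[4], 2] <- 3
  sp3 <- structure(list(amplitudes = amp3, freqs = 0:3, resolution = 1, corrected = FALSE),
                   class = "amplitude_spectrum")
  expect_equal(combine_planar(sp3, lay)$amplitudes, cp$amplitudes)
})

test_that("baseline correction matches its defining rule", {
  # constant spectrum corrects to zero at interior bins
  amp <- matrix(7, 2, 60)
  sp <- structure(list(amplitudes = amp, freqs = seq(0, by = 0.1, length.out = 60),
                       resolution = 0.1, corrected = FALSE), class = "amplitude_spectrum")
  bc <- suppressMessages(baseline_correct(sp))
  expect_true(all(abs(bc$amplitudes[, 13:48]) < 1e-12))
  expect_true(all(is.na(bc$amplitudes[, 1:12])))

  # isolated peak on a flat background keeps its full height
  amp2 <- matrix(2, 1, 60)
  amp2[1, 30] <- 2 + 1.5
  sp2 <- structure(list(amplitudes = amp2, freqs = seq(0, by = 0.1, length.out = 60),
                        resolution = 0.1, corrected = FALSE), class = "amplitude_spectrum")
  bc2 <- suppressMessages(baseline_correct(sp2))
  expect_equal(bc2$amplitudes[1, 30], 1.5)

  # frequencies and resolution unchanged; double correction refused
  expect_identical(bc2$freqs, sp2$freqs)
  expect_identical(bc2$resolution, sp2$resolution)
  expect_error(baseline_correct(bc2), "already")
})

test_that("vectorized correction equals the literal brute-force rule", {
  set.seed(21)
  for (r in 1:5) {
    amp <- matrix(rexp(3 * 200), 3, 200)
    sp <- structure(list(amplitudes = amp, freqs = seq(0, by = 0.05, length.out = 200),
                         resolution = 0.05, corrected = FALSE), class = "amplitude_spectrum")
    bc <- suppressMessages(baseline_correct(sp))
    expect_equal(bc$amplitudes, oracle_baseline_correct(amp), tolerance = 1e-12)
    # alternative configuration: no extreme-dropping, wider adjacency gap
    cfg <- baseline_config(n_used_per_side = 6, n_adjacent_excluded = 2,
                           exclude_extremes = FALSE)
    bc2 <- suppressMessages(baseline_correct(sp, cfg))
    expect_equal(bc2$amplitudes,
                 oracle_baseline_correct(amp, n_used = 6, n_adj = 2, drop_extremes = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("correction is unbiased at the oddball bin under pure 1/f noise", {
  # at the trial-length resolution (0.0375 Hz) the correction window spans
  # +-0.45 Hz around 3 Hz, where the 1/f floor is locally flat; coarser grids
  # would expose the window to the spectrum's curvature
  lay <- small_helmet(2)
  cfg <- sim_config(n_cycles = 160, fs = 300, noise_sigma = 1,
                    base_amplitudes = c("1" = 0), odd_amplitudes = c("1" = 0))
  vals <- vapply(1:200, function(r) {
    sp <- compute_spectrum(simulate_epoch(cfg, lay, "baseline", seed = 5000 + r))
    bin <- which.min(abs(sp$freqs - 3))
    mean(baseline_correct(sp, bins = bin)$amplitudes[, bin])
  }, numeric(1))
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals)), 3 * se)
})

test_that("response extraction enforces bin alignment and correction", {
  cfg <- sim_config(noise_sigma = 0)
  lay <- small_helmet(4)
  sp <- compute_spectrum(simulate_epoch(cfg, lay, "experimental", seed = 1))
  expect_error(extract_response(sp, 3), "corrected")
  bin3 <- which.min(abs(sp$freqs - 3))
  bc <- baseline_correct(sp, bins = c(bin3, bin3 + 1))
  r <- extract_response(bc, 3, subject_id = "s1", condition = "exp")
  pos <- as.matrix(lay[, c("x", "y", "z")])
  w <- fpvstag:::topography_weights(pos, cfg$odd_topography)
  expect_equal(unname(r$values), unname(0.5 * w), tolerance = 1e-6)

  # 3.02 Hz sits 0.0175 Hz from bin 3.0375 -- inside half a bin, so it maps there
  r2 <- extract_response(bc, 3.02)
  expect_equal(unname(r2$values), unname(bc$amplitudes[, bin3 + 1]))
  # beyond the spectrum range the target is rejected
  expect_error(extract_response(bc, 400), "range")
  # undefined (uncorrected) bins are refused
  expect_error(extract_response(bc, 6), "undefined")

  # baseline condition, noise-free: response is exactly zero
  sp0 <- compute_spectrum(simulate_epoch(cfg, lay, "baseline", seed = 1))
  bc0 <- baseline_correct(sp0, bins = bin3)
  expect_equal(max(abs(extract_response(bc0, 3)$values)), 0, tolerance = 1e-12)
})

test_that("doubling the injected oddball amplitude doubles the extracted response", {
  lay <- small_helmet(4)
  one <- function(a) {
    cfg <- sim_config(noise_sigma = 0, odd_amplitudes = c("1" = a), phase_seed = 7)
    sp <- compute_spectrum(simulate_epoch(cfg, lay, "experimental", seed = 1))
    bin <- which.min(abs(sp$freqs - 3))
    extract_response(baseline_correct(sp, bins = bin), 3)$values
  }
  r1 <- one(0.4)
  r2 <- one(0.8)
  expect_lt(max(abs(r2 - 2 * r1) / pmax(abs(r2), 1e-12)), 1e-9)
})
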