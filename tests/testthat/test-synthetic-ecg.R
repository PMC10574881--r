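test_that("generation is bit-reproducible from the seed", {
  cfg <- sim_config(duration_s = 15, seed = 42)
  a <- generate_ecg(cfg)
  b <- generate_ecg(cfg)
  expect_identical(a$record$signal, b$record$signal)
  expect_identical(a$truth$r_peak_indices, b$truth$r_peak_indices)
  c2 <- generate_ecg(sim_config(duration_s = 15, seed = 43))
  expect_false(identical(a$record$signal, c2$record$signal))
})

test_that("a jitter-free 60 bpm rhythm places beats exactly 1000 ms apart", {
  sim <- generate_ecg(clean_config(fs = 1000, duration_s = 10, hr = 60))
  n_beats <- length(sim$truth$r_peak_indices)
  expect_true(n_beats %in% c(10L, 11L))
  expect_true(all(sim$truth$rr_ms == 1000))
  expect_true(all(diff(sim$truth$r_peak_indices) > 0))
})

test_that("ground-truth RR mean tracks the configured heart rate", {
  sim <- generate_ecg(sim_config(duration_s = 300, mean_hr_bpm = 70,
                                 hr_sd_bpm = 5, seed = 6))
  expect_gte(length(sim$truth$rr_ms), 300)
  expect_lt(abs(mean(sim$truth$rr_ms) - 60000 / 70) / (60000 / 70), 0.01)
})

test_that("noise-free signal power equals the Gaussian template power", {
  cfg <- clean_config(fs = 1000, duration_s = 60, hr = 60, seed = 8)
  sim <- generate_ecg(cfg)
  n_beats <- length(sim$truth$r_peak_indices)
  for (ld in c("DI", "aVF", "V2")) {
    w <- cfg$wave_params[[ld]]
    # independent oracle: evaluate the five-Gaussian beat template on a
    # one-beat grid and take its energy (includes Q-R-S overlap terms)
    tt <- seq(-0.45, 0.55, by = 1e-3)
    beat <- rowSums(sapply(seq_len(nrow(w)), function(i) {
      w$amp_mv[i] * exp(-(tt - w$center_s[i])^2 / (2 * w$width_s[i]^2))
    }))
    e_template <- sum(beat^2)
    e_signal <- sum(sim$record$signal[, ld]^2) / n_beats
    expect_equal(e_signal, e_template, tolerance = 0.02)
  }
})

test_that("powerline interference lands in the configured spectral bin", {
  cfg <- sim_config(duration_s = 20, snr_db = NULL, white_sd_mv = 0,
                    baseline_wander = NULL,
                    powerline = list(amp_mv = 0.5, freq_hz = 50),
                    wave_params = lapply(default_wave_params(), function(w) {
                      w$amp_mv <- 0 * w$amp_mv; w
                    }),
                    seed = 3)
  sim <- generate_ecg(cfg)
  x <- sim$record$signal[, "DI"]
  spec <- Mod(stats::fft(x))[seq_len(length(x) / 2)]
  f <- (seq_along(spec) - 1) / length(x) * 1000
  expect_equal(f[which.max(spec)], 50, tolerance = 0.1)
})

test_that("the white-noise level realizes the requested SNR", {
  cfg <- sim_config(duration_s = 60, snr_db = 20, baseline_wander = NULL,
                    powerline = NULL, seed = 12)
  noisy <- generate_ecg(cfg)
  clean <- generate_ecg(sim_config(duration_s = 60, snr_db = NULL,
                                   white_sd_mv = 0, baseline_wander = NULL,
                                   powerline = NULL, seed = 12))
  for (ld in c("DI", "V2")) {
    p_sig <- mean(clean$record$signal[, ld]^2)
    p_noise <- mean((noisy$record$signal[, ld] - clean$record$signal[, ld])^2)
    expect_equal(10 * log10(p_sig / p_noise), 20, tolerance = 0.2)
  }
})

test_that("QRS inversion flips polarity without moving the beats", {
  base <- clean_config(fs = 500, duration_s = 10, hr = 60, seed = 4)
  inv_cfg <- base; inv_cfg$invert_qrs <- TRUE
  a <- generate_ecg(base); b <- generate_ecg(inv_cfg)
  expect_identical(a$truth$r_peak_indices, b$truth$r_peak_indices)
  r <- a$truth$r_peak_indices[3]
  expect_equal(b$record$signal[r, "V2"], -a$record$signal[r, "V2"],
               tolerance = 1e-6)
})

test_that("lead-off episodes saturate the mapped leads and set the mask", {
  cfg <- sim_config(duration_s = 10, seed = 5,
                    leadoff_episodes = list(
                      list(electrode = "RA", start_s = 3, end_s = 4),
                      list(electrode = "V2", start_s = 6, end_s = 7)))
  sim <- generate_ecg(cfg)
  m <- sim$truth$leadoff_mask
  expect_true(all(m[3002:4000, "RA"]))
  expect_false(any(m[, "LL"]))
  # RA fault rails DI and aVF but not V2
  expect_true(all(sim$record$signal[3500:3900, "DI"] == 2400))
  expect_true(all(sim$record$signal[3500:3900, "aVF"] == 2400))
  expect_false(any(sim$record$signal[3500:3900, "V2"] == 2400))
  # V2 fault rails only V2
  expect_true(all(sim$record$signal[6500:6900, "V2"] == 2400))
  expect_false(any(sim$record$signal[6500:6900, "DI"] == 2400))
})
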