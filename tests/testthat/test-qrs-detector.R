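test_that("rr_to_hr converts intervals exactly", {
  expect_equal(rr_to_hr(1000), 60)
  expect_equal(rr_to_hr(600), 100)
  expect_equal(rr_to_hr(750), 80)
  expect_error(rr_to_hr(0), "positive")
  expect_error(rr_to_hr(-10), "positive")
})

test_that("per-sample and batch drivers implement the same state machine", {
  sim <- generate_ecg(sim_config(duration_s = 20, seed = 7))
  k <- spline_wavelet(8)
  coeffs <- cwt_filter(sim$record$signal[, "DI"], k)
  batch <- detect_beats(coeffs, init_detector(1000))
  det <- init_detector(1000)
  events <- list()
  for (i in seq_along(coeffs)) {
    ev <- process_sample(det, coeffs[i], i)
    if (!is.null(ev)) events[[length(events) + 1L]] <- ev
  }
  expect_equal(vapply(events, `[[`, 0, "p1_index"), batch$p1_index)
  # hr is consistent with rr to numerical precision
  rr <- vapply(events, `[[`, 0, "rr_ms")[-1]
  hr <- vapply(events, `[[`, 0, "hr_bpm")[-1]
  expect_equal(hr, 60000 / rr, tolerance = 1e-9)
})

test_that("sample indices must increase strictly", {
  det <- init_detector(250)
  process_sample(det, 0, 1)
  expect_error(process_sample(det, 0, 1), "strictly increasing")
})

test_that("silence produces no beats and learning suppresses early detection", {
  det <- init_detector(1000, learning_s = 2)
  b <- detect_beats(numeric(5000), det)
  expect_identical(nrow(b), 0L)
  expect_gte(det$mpax, det$min_floor)     # floor fallback on a zero signal
  expect_lte(det$mpin, -det$min_floor)

  sim <- generate_ecg(clean_config(duration_s = 20, hr = 70, seed = 5))
  beats <- detect_record(sim$record, learning_s = 2)
  expect_gt(min(beats$p1_index), 2 * 1000 - spline_wavelet(8)$delay_samples)
})

test_that("learning seeds the memories at 75% of the observed extremes", {
  sim <- generate_ecg(clean_config(fs = 250, duration_s = 8, hr = 60, seed = 9))
  coeffs <- cwt_filter(sim$record$signal[, "aVF"], spline_wavelet(2))
  det <- init_detector(250, learning_s = 4)
  n_learn <- 4 * 250
  for (i in seq_len(n_learn)) process_sample(det, coeffs[i], i)
  expect_false(det$learning)
  expect_equal(det$mpax, 0.75 * max(coeffs[seq_len(n_learn)]))
  expect_equal(det$mpin, 0.75 * min(coeffs[seq_len(n_learn)]))
})

test_that("a regular 60 bpm rhythm yields RR = 1000 ms at 1000 Hz", {
  sim <- generate_ecg(clean_config(fs = 1000, duration_s = 30, hr = 60))
  beats <- detect_record(sim$record)
  rr <- beats$rr_ms[!is.na(beats$rr_ms)]
  expect_gt(length(rr), 70)  # ~26 intervals per lead
  expect_true(all(abs(rr - 1000) <= 2))
})

test_that("detection indices are invariant under signal negation", {
  sim <- generate_ecg(sim_config(duration_s = 25, seed = 13))
  rec <- sim$record
  flipped <- ecg_record(-rec$signal, rec$sampling_rate_hz, rec$leads)
  b1 <- detect_record(rec)
  b2 <- detect_record(flipped)
  expect_identical(b1$p1_index, b2$p1_index)
  expect_false(any(b1$pair_order == b2$pair_order))
})

test_that("no two beats violate the refractory period", {
  sim <- generate_ecg(sim_config(duration_s = 40, snr_db = 10, seed = 21))
  beats <- detect_record(sim$record)
  for (ld in unique(beats$lead)) {
    dp <- diff(beats$p1_index[beats$lead == ld])
    expect_true(all(dp >= 0.2 * 1000))
  }
})

test_that("threshold memories stay between the floor and the largest modulus", {
  sim <- generate_ecg(sim_config(duration_s = 30, seed = 17))
  coeffs <- cwt_filter(sim$record$signal[, "V2"], spline_wavelet(8))
  det <- init_detector(1000)
  detect_beats(coeffs, det)
  expect_gte(det$mpax, det$floor)
  expect_lte(det$mpin, -det$floor)
  expect_lte(det$mpax, max(coeffs))
  expect_gte(det$mpin, min(coeffs))
})

test_that("compensated beat indices align with ground-truth R peaks", {
  sim <- generate_ecg(sim_config(duration_s = 60, seed = 1))
  beats <- detect_record(sim$record)
  fs <- 1000
  for (ld in c("DI", "aVF", "V2")) {
    d <- beats$p1_index[beats$lead == ld]
    truth <- visible_truth(sim$truth$r_peak_indices, fs)
    offs <- vapply(truth, function(r) d[which.min(abs(d - r))] - r, 0)
    offs <- offs[abs(offs) <= 75]       # matched beats only
    expect_lt(abs(mean(offs)) / fs * 1000, 10)
  }
})

test_that("per-lead beat counts match the visible ground truth", {
  sim <- generate_ecg(sim_config(duration_s = 60, seed = 1))
  beats <- detect_record(sim$record)
  n_truth <- length(visible_truth(sim$truth$r_peak_indices, 1000))
  counts <- table(beats$lead)
  expect_identical(length(counts), 3L)
  for (ct in counts) expect_lte(abs(ct - n_truth), 1)
})

test_that("RR series agree across sampling rates on the same rhythm", {
  rrs <- lapply(c(250, 1000), function(fs) {
    sim <- generate_ecg(sim_config(sampling_rate_hz = fs, duration_s = 60,
                                   seed = 4))
    b <- detect_record(sim$record)
    b$rr_ms[b$lead == "V2"][-1]
  })
  n <- min(lengths(rrs))
  expect_gt(n, 50)
  rmse <- sqrt(mean((rrs[[1]][seq_len(n)] - rrs[[2]][seq_len(n)])^2))
  expect_lt(rmse, 8)
})

test_that("clean ECG over 500+ beats is detected with Se and P+ above 99%", {
  fs <- 250
  sim <- generate_ecg(sim_config(sampling_rate_hz = fs, duration_s = 440,
                                 seed = 2))
  beats <- detect_record(sim$record)
  truth <- visible_truth(sim$truth$r_peak_indices, fs)
  expect_gte(length(truth), 500)
  for (ld in c("DI", "aVF", "V2")) {
    m <- match_detections(truth, beats$p1_index[beats$lead == ld], fs)
    expect_gte(m$se_pct, 99)
    expect_gte(m$ppv_pct, 99)
  }
})
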