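# Synthetic 3-lead ECG with known beat ground truth.
#
# Each beat is a sum of five Gaussian waves (P, Q, R, S, T) -- the classic
# template approach -- placed at randomly jittered RR intervals, with
# white noise, baseline wander, powerline interference, optional QRS
# polarity inversion and scripted lead-off episodes. Every draw is
# reproducible from the seed.

# Lead-II-like template; per-lead amplitude scaling approximates the
# quasi-orthogonal DI / aVF / V2 set.
default_wave_params <- function() {
  base <- data.frame(
    wave = c("P", "Q", "R", "S", "T"),
    amp_mv = c(0.12, -0.10, 1.20, -0.25, 0.35),
    center_s = c(-0.18, -0.026, 0.00, 0.026, 0.25),
    width_s = c(0.025, 0.010, 0.011, 0.010, 0.055),
    stringsAsFactors = FALSE
  )
  scale_lead <- function(f) { b <- base; b$amp_mv <- b$amp_mv * f; b }
  list(DI = scale_lead(0.7), aVF = scale_lead(1.0), V2 = scale_lead(1.3))
}

#' Simulation configuration
#'
#' Parameters of the synthetic 3-lead ECG generator. Defaults describe the
#' validation condition used throughout: 5 minutes at 70 +/- 5 bpm with a
#' 20 dB white-noise floor plus mild baseline wander and powerline
#' interference.
#'
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param duration_s Recording duration in seconds.
#' @param mean_hr_bpm,hr_sd_bpm Mean heart rate and beat-to-beat standard
#'   deviation; RR intervals are drawn as
#'   `max(300 ms, Normal(60000 / mean_hr, rr_sd))` with
#'   `rr_sd = 60000 * hr_sd / mean_hr^2` (the local bpm-to-ms conversion).
#' @param wave_params Per-lead data frames of Gaussian wave parameters
#'   (columns `wave`, `amp_mv`, `center_s`, `width_s`); see
#'   `default_wave_params` in the package source.
#' @param snr_db White-noise level as signal-to-noise ratio in dB computed
#'   per lead from the clean signal power, or `NULL` to use `white_sd_mv`.
#' @param white_sd_mv Explicit white-noise standard deviation in mV
#'   (ignored when `snr_db` is given).
#' @param baseline_wander `list(amp_mv=, freq_hz=)` sinusoidal wander.
#' @param powerline `list(amp_mv=, freq_hz=)`, `freq_hz` 50 or 60.
#' @param invert_qrs If `TRUE`, Q, R and S amplitudes are negated on all
#'   leads (a polarity-inversion stress case).
#' @param leadoff_episodes List of `list(electrode=, start_s=, end_s=)`;
#'   affected leads saturate at the positive rail for the episode.
#' @param seed Integer RNG seed; the generator is bit-reproducible from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(sampling_rate_hz = 1000, duration_s = 300,
                       mean_hr_bpm = 70, hr_sd_bpm = 5,
                       wave_params = default_wave_params(),
                       snr_db = 20, white_sd_mv = 0,
                       baseline_wander = list(amp_mv = 0.05, freq_hz = 0.25),
                       powerline = list(amp_mv = 0.02, freq_hz = 60),
                       invert_qrs = FALSE, leadoff_episodes = list(),
                       seed = 1L) {
  stop_if_not_scalar_number(sampling_rate_hz, "sampling_rate_hz")
  stop_if_not_scalar_number(duration_s, "duration_s")
  stop_if_not_scalar_number(mean_hr_bpm, "mean_hr_bpm")
  if (hr_sd_bpm < 0) stop("`hr_sd_bpm` must be >= 0", call. = FALSE)
  if (!is.null(powerline) && !powerline$freq_hz %in% c(50, 60)) {
    stop("powerline frequency must be 50 or 60 Hz", call. = FALSE)
  }
  if (any(vapply(wave_params, function(w) any(w$width_s <= 0), logical(1)))) {
    stop("wave widths must be positive", call. = FALSE)
  }
  structure(
    list(sampling_rate_hz = sampling_rate_hz, duration_s = duration_s,
         mean_hr_bpm = mean_hr_bpm, hr_sd_bpm = hr_sd_bpm,
         wave_params = wave_params, snr_db = snr_db,
         white_sd_mv = white_sd_mv, baseline_wander = baseline_wander,
         powerline = powerline, invert_qrs = invert_qrs,
         leadoff_episodes = leadoff_episodes, seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Electrode fault -> affected leads (DI = LA-RA, aVF = LL-(LA+RA)/2).
LEADOFF_MAP <- list(RL = c("DI", "aVF", "V2"), LL = "aVF",
                    LA = c("DI", "aVF"), RA = c("DI", "aVF"), V2 = "V2")

render_lead <- function(beat_times_s, waves, n, fs) {
  t <- (seq_len(n) - 1) / fs
  y <- numeric(n)
  for (w in seq_len(nrow(waves))) {
    amp <- waves$amp_mv[w]; ctr <- waves$center_s[w]; wid <- waves$width_s[w]
    for (bt in beat_times_s) {
      c0 <- bt + ctr
      i1 <- max(1L, floor((c0 - 4 * wid) * fs) + 1L)
      i2 <- min(n, ceiling((c0 + 4 * wid) * fs) + 1L)
      if (i1 > i2) next
      tt <- t[i1:i2]
      y[i1:i2] <- y[i1:i2] + amp * exp(-(tt - c0)^2 / (2 * wid^2))
    }
  }
  y
}

#' Generate a synthetic 3-lead ECG with ground truth
#'
#' @param config A [sim_config()].
#' @return List with `record` (an [ecg_record()] in mV) and `truth`: a list
#'   with `r_peak_indices` (strictly increasing sample indices of the R
#'   waves, shared across leads), `rr_ms`, and `leadoff_mask` (samples x 5
#'   logical matrix over electrodes RL, LL, LA, RA, V2).
#' @examples
#' sim <- generate_ecg(sim_config(duration_s = 10, hr_sd_bpm = 0, seed = 2))
#' diff(sim$truth$r_peak_indices)  # constant RR
#' @export
generate_ecg <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  fs <- config$sampling_rate_hz
  n <- as.integer(round(config$duration_s * fs))
  leads <- names(config$wave_params)
  with_seed(config$seed, {
    # 1. RR sequence (drawn before any rate-dependent noise so that the
    #    same seed yields the same rhythm at every sampling rate)
    mean_rr <- 60000 / config$mean_hr_bpm
    rr_sd <- 60000 * config$hr_sd_bpm / config$mean_hr_bpm^2
    n_beats_max <- ceiling(config$duration_s * 1000 / 300) + 2L
    rr_draw <- pmax(300, stats::rnorm(n_beats_max, mean_rr, rr_sd))
    t0 <- 0.4                                  # first beat, seconds
    beat_times <- t0 + c(0, cumsum(rr_draw)) / 1000
    beat_times <- beat_times[beat_times < config$duration_s - 0.3]
    r_idx <- as.integer(round(beat_times * fs)) + 1L

    waves <- config$wave_params
    if (config$invert_qrs) {
      waves <- lapply(waves, function(w) {
        w$amp_mv[w$wave %in% c("Q", "R", "S")] <- -w$amp_mv[w$wave %in% c("Q", "R", "S")]
        w
      })
    }

    sig <- matrix(0, n, length(leads), dimnames = list(NULL, leads))
    for (ld in leads) {
      clean <- render_lead(beat_times, waves[[ld]], n, fs)
      sd_w <- if (!is.null(config$snr_db)) {
        sqrt(mean(clean^2) / 10^(config$snr_db / 10))
      } else config$white_sd_mv
      y <- clean
      if (sd_w > 0) y <- y + stats::rnorm(n, 0, sd_w)
      bw <- config$baseline_wander
      if (!is.null(bw) && bw$amp_mv > 0) {
        y <- y + bw$amp_mv *
          sin(2 * pi * bw$freq_hz * (seq_len(n) - 1) / fs + stats::runif(1, 0, 2 * pi))
      }
      pl <- config$powerline
      if (!is.null(pl) && pl$amp_mv > 0) {
        y <- y + pl$amp_mv *
          sin(2 * pi * pl$freq_hz * (seq_len(n) - 1) / fs + stats::runif(1, 0, 2 * pi))
      }
      sig[, ld] <- y
    }

    mask <- matrix(FALSE, n, 5L, dimnames = list(NULL, ELECTRODES))
    rail_mv <- 2400                            # +full scale at unity gain
    for (ep in config$leadoff_episodes) {
      i1 <- max(1L, as.integer(round(ep$start_s * fs)) + 1L)
      i2 <- min(n, as.integer(round(ep$end_s * fs)))
      if (i1 > i2) next
      mask[i1:i2, ep$electrode] <- TRUE
      for (ld in intersect(LEADOFF_MAP[[ep$electrode]], leads)) {
        sig[i1:i2, ld] <- rail_mv
      }
    }

    list(
      record = ecg_record(sig, fs, leads = leads, unit = "mV"),
      truth = list(r_peak_indices = r_idx,
                   rr_ms = diff(r_idx) / fs * 1000,
                   leadoff_mask = mask)
    )
  })
}

#' Piecewise-constant heart-rate trace
#'
#' Builds a per-beat bpm series from scripted segments, for exercising the
#' alarm engine's out-of-range debounce.
#'
#' @param segments Data frame with columns `bpm` and `beats`.
#' @return Numeric vector of per-beat heart rates.
#' @examples
#' generate_hr_trace(data.frame(bpm = c(75, 110, 75), beats = c(5, 5, 5)))
#' @export
generate_hr_trace <- function(segments) {
  stopifnot(is.data.frame(segments), all(c("bpm", "beats") %in% names(segments)))
  rep(segments$bpm, segments$beats)
}
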