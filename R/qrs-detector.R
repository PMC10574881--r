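# Streaming QRS detector on spline-CWT coefficients.
#
# Each QRS complex maps to a pair of CWT moduli -- a positive maximum (Pmax)
# and a negative minimum (Pmin), in either order depending on QRS
# morphology -- with a zero crossing (P1) between them at the R/S peak.
# Two adaptive threshold memories hold 75% of the running modulus
# amplitudes; a threshold excursion arms a candidate modulus, and when an
# opposite-sign modulus follows within the pairing window the beat is
# declared at the zero crossing. RR is the P1-to-P1 distance.

#' Initialize a streaming QRS detector
#'
#' Creates the detector state used by [process_sample()] and
#' [detect_beats()]. The detector starts in a learning phase during which no
#' beats are emitted and the two threshold memories are seeded at 75% of the
#' extreme positive and negative CWT values observed.
#'
#' @param sampling_rate_hz Sampling rate of the coefficient stream, Hz.
#' @param scale Integer CWT scale, or `"auto"` to pick via [select_scale()].
#'   Only used to size the startup blanking; detection itself consumes
#'   whatever coefficient stream it is fed.
#' @param learning_s Learning-phase duration in seconds (>= 1).
#' @param alpha Exponential threshold-update weight: after each beat the
#'   memories move toward 75% of the detected modulus amplitudes as
#'   `m <- (1 - alpha) * m + alpha * 0.75 * |modulus|`, adapting over ~4
#'   beats so a single ectopic amplitude cannot capture the thresholds.
#' @param refractory_ms Dead time after a declared beat during which no new
#'   modulus may be armed (physiological minimum RR; also blanks T waves).
#' @param pairing_ms Maximum separation between the two moduli of one QRS
#'   (a QRS width bound); an unpaired candidate older than this is replaced.
#' @param floor_frac Threshold floor as a fraction of the learning-phase
#'   maximum modulus, preventing collapse onto noise during flatline.
#' @param min_floor Absolute minimum threshold floor (amplitude units), the
#'   fallback when the learning window is silent.
#' @param decay_after If no beat occurs for `decay_after` times the running
#'   mean RR, thresholds are halved (a search-back surrogate for dropouts).
#' @param decay_factor Multiplier applied to the memories at each decay.
#'
#' @return An environment of class `qrs_detector`; it is mutated in place by
#'   [process_sample()].
#' @seealso [detect_record()] for the full per-lead pipeline.
#' @export
init_detector <- function(sampling_rate_hz, scale = "auto", learning_s = 2,
                          alpha = 0.25, refractory_ms = 200, pairing_ms = 120,
                          floor_frac = 0.01, min_floor = 1e-9,
                          decay_after = 1.5, decay_factor = 0.5) {
  stop_if_not_scalar_number(sampling_rate_hz, "sampling_rate_hz")
  if (learning_s < 1) stop("`learning_s` must be >= 1", call. = FALSE)
  if (identical(scale, "auto")) scale <- select_scale(sampling_rate_hz)
  e <- new.env(parent = emptyenv())
  e$fs <- sampling_rate_hz
  e$scale <- scale
  e$alpha <- alpha
  e$learn_n <- as.integer(round(learning_s * sampling_rate_hz))
  e$refr_n <- as.integer(round(refractory_ms / 1000 * sampling_rate_hz))
  e$pair_n <- as.integer(round(pairing_ms / 1000 * sampling_rate_hz))
  e$floor_frac <- floor_frac
  e$min_floor <- min_floor
  e$decay_after <- decay_after
  e$decay_factor <- decay_factor
  e$learning <- TRUE
  e$learn_max <- 0
  e$learn_min <- 0
  e$floor <- min_floor
  e$mpax <- Inf                      # disables arming until learning ends
  e$mpin <- -Inf
  e$i <- 0L                          # last processed sample index
  e$buf_n <- 2L * e$pair_n + 4L      # ring buffer of recent coefficients
  e$buf <- numeric(e$buf_n)
  e$exc_sign <- 0L                   # sign of the running threshold excursion
  e$exc_amp <- 0
  e$exc_idx <- 0L
  e$pend_sign <- 0L                  # first modulus of a candidate pair
  e$pend_amp <- 0
  e$pend_idx <- 0L
  e$last_p1 <- NA_integer_
  e$refractory_until <- 0L
  e$rr_mean <- NA_real_
  e$next_decay_at <- Inf
  class(e) <- "qrs_detector"
  e
}

#' @export
print.qrs_detector <- function(x, ...) {
  cat(sprintf(
    "<qrs_detector> fs %g Hz, scale %d, %s, thresholds [%.3g, %.3g]\n",
    x$fs, x$scale, if (x$learning) "learning" else "running",
    x$mpin, x$mpax))
  invisible(x)
}

# Advance the detector by one coefficient. Returns the accepted P1 sample
# index (in the coefficient time base) or NA. `pair_first` on the state
# records which modulus of the accepted pair came first (+1 max-first,
# -1 min-first).
step_core <- function(e, coeff) {
  i <- e$i + 1L
  e$i <- i
  e$buf[((i - 1L) %% e$buf_n) + 1L] <- coeff

  if (e$learning) {
    if (coeff > e$learn_max) e$learn_max <- coeff
    if (coeff < e$learn_min) e$learn_min <- coeff
    if (i >= e$learn_n) {
      e$learning <- FALSE
      e$floor <- max(e$floor_frac * max(e$learn_max, -e$learn_min),
                     e$min_floor)
      e$mpax <- max(0.75 * e$learn_max, e$floor)
      e$mpin <- min(0.75 * e$learn_min, -e$floor)
    }
    return(NA_integer_)
  }

  if (i >= e$next_decay_at) {
    e$mpax <- max(e$decay_factor * e$mpax, e$floor)
    e$mpin <- min(e$decay_factor * e$mpin, -e$floor)
    e$next_decay_at <- i + e$decay_after * e$rr_mean * e$fs / 1000
  }

  p1_out <- NA_integer_

  # track / finalize the running excursion beyond a threshold
  finalized <- 0L
  if (e$exc_sign == 1L) {
    if (coeff > e$exc_amp) {
      e$exc_amp <- coeff
      e$exc_idx <- i
    }
    if (coeff <= e$mpax) finalized <- 1L
  } else if (e$exc_sign == -1L) {
    if (coeff < e$exc_amp) {
      e$exc_amp <- coeff
      e$exc_idx <- i
    }
    if (coeff >= e$mpin) finalized <- -1L
  }

  if (finalized != 0L) {
    e$exc_sign <- 0L
    s <- finalized
    amp <- e$exc_amp
    idx <- e$exc_idx
    if (e$pend_sign == 0L) {
      e$pend_sign <- s; e$pend_amp <- amp; e$pend_idx <- idx
    } else if (e$pend_sign == s) {
      # same-sign successor: keep the stronger unless the old one expired
      if (idx - e$pend_idx > e$pair_n || abs(amp) >= abs(e$pend_amp)) {
        e$pend_amp <- amp; e$pend_idx <- idx
      }
    } else if (idx - e$pend_idx <= e$pair_n) {
      # opposite-sign pair within the window: locate the zero crossing P1
      i1 <- e$pend_idx
      n_seg <- idx - i1 + 1L
      seg <- e$buf[(((i1:idx) - 1L) %% e$buf_n) + 1L]
      s1 <- sign(seg[1L])
      ch <- which(sign(seg) != s1)
      p1 <- i1 + if (length(ch)) ch[1L] - 1L else n_seg %/% 2L
      if (p1 >= e$refractory_until) {
        # accepted beat: update 75% memories, refractory, RR statistics
        pos <- if (s > 0) amp else e$pend_amp
        neg <- if (s < 0) amp else e$pend_amp
        a <- e$alpha
        e$mpax <- max((1 - a) * e$mpax + a * 0.75 * pos, e$floor)
        e$mpin <- min((1 - a) * e$mpin + a * 0.75 * neg, -e$floor)
        e$refractory_until <- p1 + e$refr_n
        if (!is.na(e$last_p1)) {
          rr <- (p1 - e$last_p1) / e$fs * 1000
          e$rr_mean <- if (is.na(e$rr_mean)) rr else 0.875 * e$rr_mean + 0.125 * rr
        }
        e$last_p1 <- p1
        if (!is.na(e$rr_mean)) {
          e$next_decay_at <- p1 + e$decay_after * e$rr_mean * e$fs / 1000
        }
        e$pair_first <- e$pend_sign
        p1_out <- p1
      }
      e$pend_sign <- 0L
    } else {
      # stale candidate: this modulus starts a fresh pair
      e$pend_sign <- s; e$pend_amp <- amp; e$pend_idx <- idx
    }
  }

  # arm a new excursion (gated by refractory)
  if (e$exc_sign == 0L && i >= e$refractory_until) {
    if (coeff > e$mpax) {
      e$exc_sign <- 1L; e$exc_amp <- coeff; e$exc_idx <- i
    } else if (coeff < e$mpin) {
      e$exc_sign <- -1L; e$exc_amp <- coeff; e$exc_idx <- i
    }
  }
  p1_out
}

#' Process one CWT coefficient
#'
#' Advances the streaming detector by a single sample. Returns `NULL` or,
#' when a beat is declared at this sample, a `beat_event`: a list with
#' `p1_index` (zero-crossing sample index, in the coefficient time base),
#' `rr_ms` (`NA` for the first beat), `hr_bpm` and `pair_order`
#' (`"max-first"` or `"min-first"`).
#'
#' @param detector A `qrs_detector` (mutated in place).
#' @param coeff CWT coefficient value.
#' @param index Sample counter; must be strictly increasing across calls.
#' @return A `beat_event` list or `NULL`.
#' @export
process_sample <- function(detector, coeff, index) {
  stopifnot(inherits(detector, "qrs_detector"))
  if (!is.numeric(index) || index <= detector$i) {
    stop("`index` must be strictly increasing across calls", call. = FALSE)
  }
  prev_p1 <- detector$last_p1
  p1 <- step_core(detector, coeff)
  if (is.na(p1)) return(NULL)
  rr <- if (is.na(prev_p1)) NA_real_ else (p1 - prev_p1) / detector$fs * 1000
  structure(
    list(p1_index = p1, rr_ms = rr,
         hr_bpm = if (is.na(rr)) NA_real_ else rr_to_hr(rr),
         pair_order = if (detector$pair_first > 0) "max-first" else "min-first"),
    class = "beat_event"
  )
}

#' Convert an RR interval to heart rate
#'
#' @param rr_ms RR interval(s) in milliseconds, strictly positive.
#' @return Heart rate(s) in beats per minute, `60000 / rr_ms`.
#' @examples
#' rr_to_hr(1000)  # 60 bpm
#' @export
rr_to_hr <- function(rr_ms) {
  if (!is.numeric(rr_ms) || any(!is.na(rr_ms) & rr_ms <= 0)) {
    stop("`rr_ms` must be positive", call. = FALSE)
  }
  60000 / rr_ms
}

#' Run the streaming detector over a whole coefficient vector
#'
#' Batch driver around [process_sample()]'s state machine: feeds every
#' coefficient through the detector and collects the declared beats.
#'
#' @param coeffs Numeric vector of CWT coefficients.
#' @param detector A freshly initialized `qrs_detector`.
#' @return A data.frame with columns `p1_index` (coefficient time base),
#'   `rr_ms`, `hr_bpm`, `pair_order`.
#' @export
detect_beats <- function(coeffs, detector) {
  stopifnot(inherits(detector, "qrs_detector"))
  p1s <- integer(0)
  orders <- integer(0)
  for (c_i in coeffs) {
    p1 <- step_core(detector, c_i)
    if (!is.na(p1)) {
      p1s <- c(p1s, p1)
      orders <- c(orders, detector$pair_first)
    }
  }
  rr <- if (length(p1s)) c(NA_real_, diff(p1s) / detector$fs * 1000) else numeric(0)
  data.frame(
    p1_index = p1s,
    rr_ms = rr,
    hr_bpm = 60000 / rr,
    pair_order = ifelse(orders > 0, "max-first", "min-first"),
    stringsAsFactors = FALSE
  )
}

#' Detect beats on every lead of an ECG record
#'
#' Full chain per lead: build the wavelet kernel (scale selected from the
#' sampling rate unless given), filter the lead, run the streaming detector,
#' and compensate beat indices by the kernel group delay so that `p1_index`
#' aligns with the ECG time base (the R/S peak).
#'
#' @param record An [ecg_record()].
#' @param scale Integer CWT scale or `"auto"`.
#' @param learning_s Detector learning phase in seconds.
#' @param ... Further arguments passed to [init_detector()].
#' @return A data.frame with columns `lead`, `p1_index` (delay-compensated,
#'   ECG time base), `time_s`, `rr_ms`, `hr_bpm`, `pair_order`. The heart
#'   rate is computed independently for each lead.
#' @examples
#' sim <- generate_ecg(sim_config(duration_s = 20, seed = 1))
#' beats <- detect_record(sim$record)
#' table(beats$lead)
#' @export
detect_record <- function(record, scale = "auto", learning_s = 2, ...) {
  stopifnot(inherits(record, "ecg_record"))
  if (ncol(record$signal) == 0L) {
    return(data.frame(lead = character(0), p1_index = integer(0),
                      time_s = numeric(0), rr_ms = numeric(0),
                      hr_bpm = numeric(0), pair_order = character(0)))
  }
  fs <- record$sampling_rate_hz
  if (identical(scale, "auto")) scale <- select_scale(fs)
  kern <- spline_wavelet(scale)
  out <- lapply(record$leads, function(ld) {
    coeffs <- cwt_filter(record$signal[, ld], kern)
    det <- init_detector(fs, scale = scale, learning_s = learning_s, ...)
    b <- detect_beats(coeffs, det)
    if (nrow(b) == 0L) return(cbind(lead = character(0), b, time_s = numeric(0)))
    b$p1_index <- b$p1_index - kern$delay_samples
    data.frame(lead = ld, p1_index = b$p1_index,
               time_s = (b$p1_index - 1) / fs,
               rr_ms = b$rr_ms, hr_bpm = b$hr_bpm,
               pair_order = b$pair_order, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
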