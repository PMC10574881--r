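# Detector scoring: beat matching (Se, P+), Bland-Altman agreement of RR
# series, and lag-aligned waveform correlation.

#' Match detected beats against a reference annotation
#'
#' One-to-one matching of detected beat indices to reference indices within
#' a tolerance window (+/-75 ms by default, the common beat-matching
#' convention). Candidate pairs are accepted globally in order of increasing
#' time difference, so the matching is symmetric in the two lists. Unmatched
#' reference beats count as false negatives, unmatched detections as false
#' positives.
#'
#' @param truth_idx,detected_idx Sorted sample-index vectors.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param tol_ms Matching half-window in milliseconds.
#' @return An object of class `match_result`: `tp`, `fp`, `fn`, sensitivity
#'   `se_pct = 100 TP / (TP + FN)`, positive predictivity
#'   `ppv_pct = 100 TP / (TP + FP)`, and the detection error
#'   `error_pct = 100 (FP + FN) / (TP + FN)`.
#' @examples
#' match_detections(c(100, 300, 500), c(102, 499), 250)
#' @export
match_detections <- function(truth_idx, detected_idx, sampling_rate_hz,
                             tol_ms = 75) {
  if (is.unsorted(truth_idx) || is.unsorted(detected_idx)) {
    stop("index lists must be sorted", call. = FALSE)
  }
  stop_if_not_scalar_number(sampling_rate_hz, "sampling_rate_hz")
  tol_n <- tol_ms / 1000 * sampling_rate_hz
  nt <- length(truth_idx); nd <- length(detected_idx)
  tp <- 0L
  if (nt > 0L && nd > 0L) {
    # all candidate pairs within tolerance, greedily accepted by |diff|
    d <- abs(outer(truth_idx, detected_idx, "-"))
    cand <- which(d <= tol_n, arr.ind = TRUE)
    if (nrow(cand)) {
      cand <- cand[order(d[cand]), , drop = FALSE]
      used_t <- logical(nt); used_d <- logical(nd)
      for (r in seq_len(nrow(cand))) {
        i <- cand[r, 1L]; j <- cand[r, 2L]
        if (!used_t[i] && !used_d[j]) {
          used_t[i] <- TRUE; used_d[j] <- TRUE; tp <- tp + 1L
        }
      }
    }
  }
  fn <- nt - tp
  fp <- nd - tp
  structure(
    list(tp = tp, fp = fp, fn = fn,
         se_pct = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
         ppv_pct = if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_,
         error_pct = if (tp + fn > 0) 100 * (fp + fn) / (tp + fn) else NA_real_),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> TP %d, FP %d, FN %d | Se %.2f%%, P+ %.2f%%, error %.2f%%\n",
              x$tp, x$fp, x$fn, x$se_pct, x$ppv_pct, x$error_pct))
  invisible(x)
}

#' Bland-Altman agreement of two paired RR series
#'
#' Mean difference (bias) and limits of agreement (+/-2 standard deviations
#' of the paired differences, sample SD) between two equal-length RR series
#' in milliseconds.
#'
#' @param rr_a,rr_b Paired numeric series of equal length >= 2.
#' @return An object of class `agreement_result` with `bias_ms`, `loa_ms`
#'   (the half-width `2 * SD`), and `n`.
#' @examples
#' bland_altman(c(800, 810, 805), c(801, 811, 806))
#' @export
bland_altman <- function(rr_a, rr_b) {
  if (length(rr_a) != length(rr_b)) {
    stop("`rr_a` and `rr_b` must have equal length", call. = FALSE)
  }
  if (length(rr_a) < 2L) stop("need at least 2 paired values", call. = FALSE)
  d <- rr_a - rr_b
  structure(
    list(bias_ms = mean(d), loa_ms = 2 * stats::sd(d), n = length(d)),
    class = "agreement_result"
  )
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("<agreement_result> bias %.3f ms, limits of agreement +/-%.3f ms (n = %d)\n",
              x$bias_ms, x$loa_ms, x$n))
  invisible(x)
}

#' Align two waveforms and correlate
#'
#' Finds the lag (within `+/-max_lag` samples) maximizing the
#' cross-correlation of two equally sampled waveforms, then reports the
#' Pearson correlation over the overlap at that lag, as a percentage.
#'
#' @param x,y Numeric waveforms at the same sampling rate.
#' @param max_lag Maximum alignment shift in samples.
#' @return List with `lag_samples` (positive: `y` lags `x`) and `r_pct`.
#' @examples
#' x <- sin(seq(0, 20, by = 0.01))
#' align_and_correlate(x, c(numeric(37), x))$lag_samples  # 37
#' @export
align_and_correlate <- function(x, y, max_lag = 250) {
  lags <- seq.int(-max_lag, max_lag)
  r <- vapply(lags, function(L) {
    if (L >= 0) {
      n <- min(length(x), length(y) - L)
      if (n < 2L) return(NA_real_)
      stats::cor(x[seq_len(n)], y[seq_len(n) + L])
    } else {
      n <- min(length(x) + L, length(y))
      if (n < 2L) return(NA_real_)
      stats::cor(x[seq_len(n) - L], y[seq_len(n)])
    }
  }, numeric(1))
  if (all(is.na(r))) stop("overlap shorter than 2 samples", call. = FALSE)
  best <- which.max(abs(r))
  list(lag_samples = lags[best], r_pct = 100 * r[best])
}
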