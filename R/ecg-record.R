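#' Multi-lead ECG record
#'
#' Container for a multi-lead ECG sample stream: a numeric matrix with one
#' column per lead, the sampling rate, and the unit of the stored samples
#' (millivolts, or raw 24-bit ADC codes as read from a monitor record
#' directory).
#'
#' @param signal Numeric matrix (samples x leads) or a vector (one lead).
#' @param sampling_rate_hz Sampling rate in Hz (the monitor supports 250,
#'   500 and 1000 Hz; any positive rate is accepted here).
#' @param leads Character vector of lead labels, one per column.
#' @param unit `"mV"` for physical amplitudes or `"adc"` for raw integer
#'   converter codes.
#'
#' @return An object of class `ecg_record`: a list with elements `signal`,
#'   `sampling_rate_hz`, `leads`, `unit`.
#' @examples
#' x <- sin(2 * pi * 1.2 * seq(0, 2, by = 1 / 250))
#' rec <- ecg_record(x, 250, leads = "DI")
#' n_samples(rec)
#' @export
ecg_record <- function(signal, sampling_rate_hz,
                       leads = c("DI", "aVF", "V2"), unit = c("mV", "adc")) {
  unit <- match.arg(unit)
  if (is.vector(signal)) signal <- matrix(signal, ncol = 1L)
  if (!is.matrix(signal) || !is.numeric(signal)) {
    stop("`signal` must be a numeric matrix (samples x leads)", call. = FALSE)
  }
  stop_if_not_scalar_number(sampling_rate_hz, "sampling_rate_hz")
  if (length(leads) != ncol(signal)) {
    leads <- leads[seq_len(ncol(signal))]
    if (anyNA(leads)) stop("`leads` must name every column", call. = FALSE)
  }
  colnames(signal) <- leads
  structure(
    list(signal = signal, sampling_rate_hz = sampling_rate_hz,
         leads = leads, unit = unit),
    class = "ecg_record"
  )
}

#' @rdname ecg_record
#' @param x An `ecg_record`.
#' @export
n_samples <- function(x) nrow(x$signal)

#' @rdname ecg_record
#' @export
duration_s <- function(x) nrow(x$signal) / x$sampling_rate_hz

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %d leads (%s), %d samples @ %g Hz (%.1f s), unit %s\n",
              length(x$leads), paste(x$leads, collapse = ", "),
              nrow(x$signal), x$sampling_rate_hz,
              duration_s(x), x$unit))
  invisible(x)
}
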