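# The monitor's storage layout: a record directory named
# <subject>_<YYYYMMDD>_<HHMMSS> holding Record0000 (metadata) and
# Record0001..Record9999 (data). Data files are a sequence of 15-byte
# packets, one per sample: for each of the three channels (DI, aVF, V2),
# 3 bytes of 24-bit two's-complement ADC code followed by a 2-byte unsigned
# heart-rate word. All fields are big-endian; the HR word is bpm x 10 fixed
# point with 0 meaning "no beat yet".

PACKETS_PER_FILE <- 65536L  # 2^16 packets (~65 s at 1000 Hz) per data file

#' ADC front-end specification
#'
#' Reference voltage, programmable gain and bit depth of the monitor's
#' 24-bit converter (2.4 V reference on a 3 V supply; gains 1-12).
#'
#' @param v_ref Reference voltage in volts.
#' @param gain Programmable gain, one of 1, 2, 3, 4, 6, 8, 12.
#' @param n_bits ADC resolution in bits.
#' @return An object of class `device_spec`.
#' @examples
#' adc_resolution(device_spec())  # ~286.10 nV per code
#' @export
device_spec <- function(v_ref = 2.4, gain = 1, n_bits = 24) {
  stop_if_not_scalar_number(v_ref, "v_ref")
  if (!gain %in% c(1, 2, 3, 4, 6, 8, 12)) {
    stop("`gain` must be one of 1, 2, 3, 4, 6, 8, 12", call. = FALSE)
  }
  structure(list(v_ref = v_ref, gain = gain, n_bits = as.integer(n_bits)),
            class = "device_spec")
}

#' Record header (subject metadata)
#'
#' The contents of the Record0000 file: subject data, sampling rate and the
#' device-on timestamps bracketing the recording.
#'
#' @param subject_name,age,sex Subject data as entered on the device.
#' @param sampling_rate_hz One of 250, 500, 1000.
#' @param start_on_time,end_on_time `POSIXct` device-on timestamps.
#' @param spec A [device_spec()]; stored so raw codes can be converted.
#' @return An object of class `record_header`.
#' @export
record_header <- function(subject_name, age = NA_integer_, sex = NA_character_,
                          sampling_rate_hz = 1000,
                          start_on_time = as.POSIXct("2023-01-01 00:00:00", tz = "UTC"),
                          end_on_time = start_on_time,
                          spec = device_spec()) {
  if (!sampling_rate_hz %in% c(250, 500, 1000)) {
    stop("`sampling_rate_hz` must be 250, 500 or 1000", call. = FALSE)
  }
  structure(list(subject_name = subject_name, age = age, sex = sex,
                 sampling_rate_hz = sampling_rate_hz,
                 start_on_time = start_on_time, end_on_time = end_on_time,
                 spec = spec),
            class = "record_header")
}

check_codes <- function(code) {
  if (any(code < -2^23 | code > 2^23 - 1)) {
    stop("ADC code out of 24-bit two's-complement range", call. = FALSE)
  }
  if (any(code != round(code))) {
    stop("ADC codes must be integers", call. = FALSE)
  }
  invisible(code)
}

# codes: n x 3 matrix of 24-bit codes; hr_words: n x 3 of [0, 65535].
# Returns the raw byte stream (15 bytes per sample, channel-major).
packets_to_raw <- function(codes, hr_words) {
  check_codes(codes)
  if (any(hr_words < 0 | hr_words > 65535) || any(hr_words != round(hr_words))) {
    stop("`hr_words` must be integers in [0, 65535]", call. = FALSE)
  }
  n <- nrow(codes)
  u <- codes %% 2^24                      # two's complement as unsigned
  bytes <- matrix(0L, nrow = 15L, ncol = n)
  for (ch in 1:3) {
    r <- (ch - 1L) * 5L
    bytes[r + 1L, ] <- u[, ch] %/% 65536
    bytes[r + 2L, ] <- (u[, ch] %/% 256) %% 256
    bytes[r + 3L, ] <- u[, ch] %% 256
    bytes[r + 4L, ] <- hr_words[, ch] %/% 256
    bytes[r + 5L, ] <- hr_words[, ch] %% 256
  }
  as.raw(bytes)
}

raw_to_packets <- function(block) {
  if (length(block) %% 15L != 0L) {
    stop("packet stream length must be a multiple of 15 bytes", call. = FALSE)
  }
  n <- length(block) %/% 15L
  bytes <- matrix(as.integer(block), nrow = 15L, ncol = n)
  codes <- matrix(0, nrow = n, ncol = 3L)
  hr_words <- matrix(0, nrow = n, ncol = 3L)
  for (ch in 1:3) {
    r <- (ch - 1L) * 5L
    u <- bytes[r + 1L, ] * 65536 + bytes[r + 2L, ] * 256 + bytes[r + 3L, ]
    codes[, ch] <- ifelse(u >= 2^23, u - 2^24, u)
    hr_words[, ch] <- bytes[r + 4L, ] * 256 + bytes[r + 5L, ]
  }
  list(codes = codes, hr_words = hr_words)
}

#' Encode / decode one 15-byte sample packet
#'
#' One sample of the monitor's stream: per channel (DI, aVF, V2) a 24-bit
#' two's-complement ADC code (3 bytes, big-endian) and a 16-bit unsigned
#' heart-rate word (2 bytes, big-endian).
#'
#' @param adc_codes Integer vector of length 3, each in `[-2^23, 2^23 - 1]`.
#' @param hr_words Integer vector of length 3, each in `[0, 65535]`.
#' @return `encode_packet()`: a raw vector of exactly 15 bytes.
#' @examples
#' blk <- encode_packet(c(-1, 0, 1), c(0, 0, 723))
#' decode_packet(blk)
#' @export
encode_packet <- function(adc_codes, hr_words = c(0L, 0L, 0L)) {
  if (length(adc_codes) != 3L || length(hr_words) != 3L) {
    stop("a packet has exactly 3 channels", call. = FALSE)
  }
  packets_to_raw(matrix(adc_codes, 1L), matrix(hr_words, 1L))
}

#' @rdname encode_packet
#' @param block A raw vector of exactly 15 bytes.
#' @return `decode_packet()`: list with `adc_codes` and `hr_words`, each
#'   length 3.
#' @export
decode_packet <- function(block) {
  if (!is.raw(block) || length(block) != 15L) {
    stop("`block` must be exactly 15 bytes", call. = FALSE)
  }
  p <- raw_to_packets(block)
  list(adc_codes = as.vector(p$codes), hr_words = as.vector(p$hr_words))
}

#' Convert ADC codes to volts
#'
#' One least-significant bit spans `(2 * v_ref / gain) / (2^n - 1)` volts
#' (about 286.10 nV at gain 1), so `volts = code * resolution`.
#'
#' @param code Integer ADC code(s) in two's-complement range.
#' @param spec A [device_spec()].
#' @return Voltage(s) in volts.
#' @export
adc_code_to_volts <- function(code, spec = device_spec()) {
  check_codes(code)
  code * adc_resolution(spec)
}

#' @rdname adc_code_to_volts
#' @param volts Voltage(s) to quantize to the nearest code (clamped to
#'   full scale).
#' @export
volts_to_adc_code <- function(volts, spec = device_spec()) {
  code <- round(volts / adc_resolution(spec))
  pmin(pmax(code, -2^23), 2^23 - 1)
}

#' Minimum storage for a recording
#'
#' Every sample stores one 15-byte packet, so the minimum capacity is
#' `15 * Fm * t` bytes for sampling rate `Fm` and duration `t` seconds
#' (about 1.21 GiB for 24 h at 1000 Hz).
#'
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param duration_s Recording duration in seconds.
#' @return List with `bytes` and `gib` (`bytes / 2^30`).
#' @examples
#' storage_requirement(1000, 86400)$gib  # ~1.21
#' @export
storage_requirement <- function(sampling_rate_hz, duration_s) {
  stop_if_not_scalar_number(sampling_rate_hz, "sampling_rate_hz")
  if (duration_s < 0) stop("`duration_s` must be >= 0", call. = FALSE)
  bytes <- 15 * sampling_rate_hz * duration_s
  list(bytes = bytes, gib = bytes / 2^30)
}

#' Record directory name
#'
#' Deterministic sanitized directory name for a recording:
#' `<subject>_<YYYYMMDD>_<HHMMSS>`.
#'
#' @param subject Non-empty subject name; characters outside
#'   `[A-Za-z0-9_-]` are replaced by `_`.
#' @param start Recording start time (`POSIXct` or parseable string).
#' @return The directory name as a string.
#' @examples
#' directory_name("Ana", as.POSIXct("2023-10-08 09:30:00", tz = "UTC"))
#' @export
directory_name <- function(subject, start) {
  if (!is.character(subject) || length(subject) != 1L || !nzchar(subject)) {
    stop("`subject` must be a non-empty string", call. = FALSE)
  }
  if (!inherits(start, "POSIXt")) start <- as.POSIXct(start, tz = "UTC")
  clean <- gsub("[^A-Za-z0-9_-]", "_", subject)
  sprintf("%s_%s", clean, format(start, "%Y%m%d_%H%M%S"))
}

header_to_lines <- function(header) {
  c(sprintf("subject_name: %s", header$subject_name),
    sprintf("age: %s", header$age),
    sprintf("sex: %s", header$sex),
    sprintf("sampling_rate_hz: %d", as.integer(header$sampling_rate_hz)),
    sprintf("start_on_time: %s", format(header$start_on_time, "%Y-%m-%d %H:%M:%S", tz = "UTC")),
    sprintf("end_on_time: %s", format(header$end_on_time, "%Y-%m-%d %H:%M:%S", tz = "UTC")),
    sprintf("v_ref: %g", header$spec$v_ref),
    sprintf("gain: %g", header$spec$gain),
    sprintf("n_bits: %d", header$spec$n_bits))
}

lines_to_header <- function(lines) {
  kv <- regmatches(lines, regexpr(": ", lines), invert = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  g <- function(k) vals[match(k, keys)]
  record_header(
    subject_name = g("subject_name"),
    age = suppressWarnings(as.integer(g("age"))),
    sex = g("sex"),
    sampling_rate_hz = as.numeric(g("sampling_rate_hz")),
    start_on_time = as.POSIXct(g("start_on_time"), tz = "UTC"),
    end_on_time = as.POSIXct(g("end_on_time"), tz = "UTC"),
    spec = device_spec(v_ref = as.numeric(g("v_ref")),
                       gain = as.numeric(g("gain")),
                       n_bits = as.numeric(g("n_bits")))
  )
}

#' Write / read a monitor record directory
#'
#' `write_record()` lays a 3-lead record out exactly as the monitor does: a
#' directory named from the subject and start time containing `Record0000`
#' (UTF-8 key-value metadata) and `Record0001`, `Record0002`, ... data files
#' of 15-byte packets (at most 2^16 packets per file, so every data file's
#' size is `15 * samples_in_file` bytes). `read_record()` is its exact
#' inverse on codes, HR words and header fields.
#'
#' @param record A 3-lead [ecg_record()]. With `unit = "adc"` the signal
#'   matrix must hold integer codes, stored bit-exactly; with `unit = "mV"`
#'   samples are quantized through [volts_to_adc_code()] first (lossy at the
#'   sub-LSB level).
#' @param hr_bpm Optional numeric matrix (samples x 3) of the most recent
#'   per-lead heart rate at each sample; encoded as unsigned bpm x 10 fixed
#'   point (0 = no beat yet). `NULL` writes zeros.
#' @param header A [record_header()].
#' @param path Parent directory into which the record directory is created.
#' @return `write_record()`: the record directory path, invisibly.
#' @examples
#' codes <- matrix(sample(-2^23:(2^23 - 1), 30), ncol = 3)
#' rec <- ecg_record(codes, 1000, unit = "adc")
#' dir <- write_record(rec, header = record_header("demo"), path = tempdir())
#' back <- read_record(dir)
#' all(back$record$signal == codes)
#' @export
write_record <- function(record, hr_bpm = NULL, header, path = ".") {
  stopifnot(inherits(record, "ecg_record"), inherits(header, "record_header"))
  if (ncol(record$signal) != 3L) {
    stop("the monitor format stores exactly 3 leads", call. = FALSE)
  }
  n <- nrow(record$signal)
  codes <- if (record$unit == "adc") record$signal
           else volts_to_adc_code(record$signal / 1000, header$spec)
  if (is.null(hr_bpm)) hr_bpm <- matrix(0, n, 3L)
  if (!is.matrix(hr_bpm) || nrow(hr_bpm) != n || ncol(hr_bpm) != 3L) {
    stop("`hr_bpm` must be a samples x 3 matrix aligned with the record",
         call. = FALSE)
  }
  hr_words <- pmin(pmax(round(ifelse(is.na(hr_bpm), 0, hr_bpm) * 10), 0), 65535)

  dir <- file.path(path, directory_name(header$subject_name, header$start_on_time))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(header_to_lines(header), file.path(dir, "Record0000"),
             useBytes = TRUE)
  starts <- seq.int(1L, n, by = PACKETS_PER_FILE)
  for (fi in seq_along(starts)) {
    if (fi > 9999L) stop("record exceeds 9999 data files", call. = FALSE)
    idx <- starts[fi]:min(starts[fi] + PACKETS_PER_FILE - 1L, n)
    blk <- packets_to_raw(codes[idx, , drop = FALSE],
                          hr_words[idx, , drop = FALSE])
    writeBin(blk, file.path(dir, sprintf("Record%04d", fi)))
  }
  invisible(dir)
}

#' @rdname write_record
#' @param dir A record directory written by `write_record()` (or the device).
#' @return `read_record()`: list with `record` (an `ecg_record` in `"adc"`
#'   units), `hr_bpm` (samples x 3 matrix, `NA` where no beat had occurred)
#'   and `header`.
#' @export
read_record <- function(dir) {
  meta <- file.path(dir, "Record0000")
  if (!file.exists(meta)) {
    stop("not a record directory: missing Record0000", call. = FALSE)
  }
  header <- lines_to_header(readLines(meta, encoding = "UTF-8"))
  files <- sort(list.files(dir, pattern = "^Record[0-9]{4}$", full.names = TRUE))
  files <- files[basename(files) != "Record0000"]
  codes <- NULL
  hr_words <- NULL
  for (f in files) {
    sz <- file.size(f)
    if (sz %% 15 != 0) {
      stop(sprintf("corrupt data file %s: size not a multiple of 15 bytes",
                   basename(f)), call. = FALSE)
    }
    p <- raw_to_packets(readBin(f, "raw", n = sz))
    codes <- rbind(codes, p$codes)
    hr_words <- rbind(hr_words, p$hr_words)
  }
  if (is.null(codes)) codes <- matrix(0, 0L, 3L)
  if (is.null(hr_words)) hr_words <- matrix(0, 0L, 3L)
  hr_bpm <- hr_words / 10
  hr_bpm[hr_words == 0] <- NA_real_
  rec <- ecg_record(codes, header$sampling_rate_hz, unit = "adc")
  list(record = rec, hr_bpm = hr_bpm, header = header)
}
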