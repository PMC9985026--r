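#' Construct a dual-channel PPG recording
#'
#' A `ppg_recording` holds timestamped red and infrared photoplethysmogram
#' sample streams as produced by a chest-worn optical sensor: unsigned ADC
#' counts at a nominal 50 Hz (20 ms step). Every pipeline stage consumes this
#' container.
#'
#' @param timestamp_s Numeric vector of sample times in seconds, strictly
#'   increasing.
#' @param red,ir Numeric vectors of ADC counts, same length as `timestamp_s`,
#'   within `[0, 2^adc_bits - 1]`.
#' @param rate_hz Nominal sampling rate in Hz (default 50).
#' @param adc_bits ADC depth used for the range check (default 18).
#' @param meta Optional named list of free-form source/subject labels.
#' @return An object of class `ppg_recording`: a list with elements
#'   `timestamp_s`, `red`, `ir`, `rate_hz`, `adc_bits`, `meta`.
#' @examples
#' rec <- ppg_recording(seq(0, 0.98, by = 0.02), red = rep(1000, 50),
#'                      ir = rep(2000, 50))
#' rec
#' @export
ppg_recording <- function(timestamp_s, red, ir, rate_hz = 50, adc_bits = 18,
                          meta = list()) {
  n <- length(timestamp_s)
  if (length(red) != n || length(ir) != n) {
    stop_arg("channel lengths differ: timestamps %d, red %d, ir %d",
             n, length(red), length(ir))
  }
  if (n > 1L && any(diff(timestamp_s) <= 0)) {
    bad <- which(diff(timestamp_s) <= 0)[1L] + 1L
    stop_arg("timestamps not strictly increasing at sample %d", bad)
  }
  assert_scalar_num(rate_hz, "rate_hz", lo = 1e-9)
  assert_scalar_num(adc_bits, "adc_bits", lo = 1, hi = 64)
  cmax <- 2^adc_bits - 1
  for (ch in c("red", "ir")) {
    v <- get(ch)
    if (n > 0L && (any(!is.finite(v)) || any(v < 0) || any(v > cmax))) {
      bad <- which(!is.finite(v) | v < 0 | v > cmax)[1L]
      stop_arg("%s counts out of ADC range [0, %d] at sample %d",
               ch, as.integer(cmax), bad)
    }
  }
  structure(
    list(timestamp_s = as.numeric(timestamp_s), red = as.numeric(red),
         ir = as.numeric(ir), rate_hz = rate_hz, adc_bits = adc_bits,
         meta = meta),
    class = "ppg_recording"
  )
}

#' @export
print.ppg_recording <- function(x, ...) {
  n <- length(x$timestamp_s)
  dur <- if (n > 0L) x$timestamp_s[n] - x$timestamp_s[1L] else 0
  cat(sprintf("<ppg_recording> %d samples, %.1f s @ %g Hz nominal\n",
              n, dur, x$rate_hz))
  if (n > 0L) {
    cat(sprintf("  red: [%g, %g]  ir: [%g, %g] counts\n",
                min(x$red), max(x$red), min(x$ir), max(x$ir)))
  }
  invisible(x)
}

#' @export
length.ppg_recording <- function(x) length(x$timestamp_s)

#' Read a PPG recording from CSV
#'
#' Parses the device CSV dialect: a header line `timestamp_s,red,ir`,
#' comma-separated, decimal point, UTF-8. Timestamps are seconds relative to
#' recording start; counts are unsigned integers. The sampling rate is
#' inferred from the median timestamp step and checked against the nominal
#' rate (50 Hz by default) to within 10%.
#'
#' @param path Path to the CSV file.
#' @param nominal_rate_hz Expected sampling rate for the consistency check.
#' @param adc_bits ADC depth for the count range check.
#' @return A [ppg_recording].
#' @seealso [write_recording_csv()]
#' @export
read_recording_csv <- function(path, nominal_rate_hz = 50, adc_bits = 18) {
  if (!file.exists(path)) stop_arg("file not found: %s", path)
  header <- readLines(path, n = 1L)
  if (!identical(trimws(header), "timestamp_s,red,ir")) {
    stop_arg("line 1: expected header 'timestamp_s,red,ir', got '%s'", header)
  }
  df <- utils::read.csv(path, colClasses = "numeric",
                        fileEncoding = "UTF-8")
  if (!identical(names(df), c("timestamp_s", "red", "ir"))) {
    stop_arg("line 1: missing or misordered columns, need timestamp_s,red,ir")
  }
  n <- nrow(df)
  # line numbers reported are 1-based file lines (header is line 1)
  if (n > 1L) {
    bad <- which(diff(df$timestamp_s) <= 0)
    if (length(bad)) {
      stop_arg("line %d: timestamp not increasing", bad[1L] + 2L)
    }
  }
  cmax <- 2^adc_bits - 1
  for (ch in c("red", "ir")) {
    bad <- which(!is.finite(df[[ch]]) | df[[ch]] < 0 | df[[ch]] > cmax)
    if (length(bad)) {
      stop_arg("line %d: %s count outside [0, %d]",
               bad[1L] + 1L, ch, as.integer(cmax))
    }
  }
  rate <- nominal_rate_hz
  if (n > 1L) {
    steps <- diff(df$timestamp_s)
    rate <- 1 / stats::median(steps)
    if (abs(rate - nominal_rate_hz) > 0.1 * nominal_rate_hz) {
      stop_arg("inferred rate %.2f Hz outside 10%% of nominal %g Hz",
               rate, nominal_rate_hz)
    }
    gaps <- which(steps > 1)
    if (length(gaps)) {
      warning(sprintf("%d gap(s) longer than 1 s (first after line %d)",
                      length(gaps), gaps[1L] + 1L), call. = FALSE)
    }
  }
  ppg_recording(df$timestamp_s, df$red, df$ir, rate_hz = rate,
                adc_bits = adc_bits, meta = list(source = path))
}

#' Write a PPG recording to CSV
#'
#' Writes the device CSV dialect used by [read_recording_csv()]: header
#' `timestamp_s,red,ir`, timestamps with 3 decimal places (1 ms resolution,
#' finer than the 20 ms sample step), counts as integers.
#'
#' @param recording A [ppg_recording].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(recording, path) {
  stopifnot(inherits(recording, "ppg_recording"))
  lines <- c("timestamp_s,red,ir",
             sprintf("%.3f,%d,%d", recording$timestamp_s,
                     as.integer(round(recording$red)),
                     as.integer(round(recording$ir))))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
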