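#' Recording session container
#'
#' A `recording_session` bundles a raw multi-channel EMG recording with the
#' acquisition metadata needed to segment it: the ordered movement list, the
#' number of repetitions per movement and the instructed contraction/rest
#' durations.  The recording convention follows the usual guided protocol:
#' for each movement in listed order, repetitions alternate contraction and
#' rest, and movements are concatenated.
#'
#' @param signal numeric matrix, samples x channels (volts or normalized ADC
#'   units).
#' @param sampling_rate_hz positive scalar, sampling frequency in Hz.
#' @param movements character vector of unique movement names, in recording
#'   order.
#' @param n_repetitions positive integer, repetitions per movement.
#' @param contraction_s positive scalar, instructed contraction duration in
#'   seconds.
#' @param rest_s nonnegative scalar, rest duration between contractions in
#'   seconds.
#' @param channel_names optional character vector of channel names; defaults
#'   to `ch1, ch2, ...`.
#' @param adc_bits optional integer, ADC resolution of the acquisition
#'   hardware (metadata only).
#'
#' @return An object of class `recording_session`.
#' @seealso [session_layout()], [read_session()], [write_session()]
#' @export
recording_session <- function(signal, sampling_rate_hz, movements,
                              n_repetitions, contraction_s, rest_s,
                              channel_names = NULL, adc_bits = NULL) {
  signal <- as.matrix(signal)
  storage.mode(signal) <- "double"
  if (is.null(channel_names)) {
    channel_names <- paste0("ch", seq_len(ncol(signal)))
  }
  if (length(channel_names) == ncol(signal)) {
    colnames(signal) <- channel_names
    rownames(signal) <- NULL
  }
  s <- structure(
    list(
      signal = signal,
      sampling_rate_hz = as.numeric(sampling_rate_hz),
      movements = as.character(movements),
      n_repetitions = as.integer(n_repetitions),
      contraction_s = as.numeric(contraction_s),
      rest_s = as.numeric(rest_s),
      channel_names = as.character(channel_names),
      adc_bits = if (is.null(adc_bits)) NULL else as.integer(adc_bits)
    ),
    class = "recording_session"
  )
  validate_session(s)
  s
}

#' Validate a recording session
#'
#' Checks the structural invariants: unique movement names, at least one
#' repetition, channel-name/column agreement, and that the signal length is
#' consistent with `sampling_rate_hz * n_repetitions * n_movements *
#' (contraction_s + rest_s)` within one sample per segment boundary.
#'
#' @param s a `recording_session`.
#' @return `s`, invisibly; errors with "malformed session" or
#'   "inconsistent session" otherwise.
#' @export
validate_session <- function(s) {
  if (!inherits(s, "recording_session")) {
    stop("malformed session: not a recording_session object")
  }
  need <- c("signal", "sampling_rate_hz", "movements", "n_repetitions",
            "contraction_s", "rest_s", "channel_names")
  miss <- setdiff(need, names(s))
  if (length(miss)) {
    stop("malformed session: missing field(s) ", paste(miss, collapse = ", "))
  }
  if (length(s$movements) < 1L || anyDuplicated(s$movements)) {
    stop("malformed session: movement names must be non-empty and unique")
  }
  if (is.na(s$n_repetitions) || s$n_repetitions < 1L) {
    stop("malformed session: n_repetitions must be >= 1")
  }
  if (!is.finite(s$sampling_rate_hz) || s$sampling_rate_hz <= 0) {
    stop("malformed session: sampling_rate_hz must be positive")
  }
  if (s$contraction_s <= 0 || s$rest_s < 0) {
    stop("malformed session: contraction_s must be > 0 and rest_s >= 0")
  }
  if (length(s$channel_names) != ncol(s$signal)) {
    stop("inconsistent session: ", length(s$channel_names),
         " channel names but ", ncol(s$signal), " signal columns")
  }
  n_seg <- length(s$movements) * s$n_repetitions
  expected <- s$sampling_rate_hz * n_seg * (s$contraction_s + s$rest_s)
  # one sample of rounding slack per segment boundary (2 boundaries/segment)
  if (abs(nrow(s$signal) - expected) > 2 * n_seg) {
    stop("inconsistent session: signal has ", nrow(s$signal),
         " rows, metadata implies ~", round(expected))
  }
  invisible(s)
}

#' @export
print.recording_session <- function(x, ...) {
  cat("recording_session:", nrow(x$signal), "samples x",
      ncol(x$signal), "channels @", x$sampling_rate_hz, "Hz\n")
  cat("  movements (", length(x$movements), "): ",
      paste(x$movements, collapse = ", "), "\n", sep = "")
  cat("  repetitions:", x$n_repetitions,
      " contraction:", x$contraction_s, "s  rest:", x$rest_s, "s\n")
  invisible(x)
}

# round half away from zero (R's round() is banker's rounding)
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Segment layout of a recording session
#'
#' Computes, for every (movement, repetition), the half-open 0-based sample
#' interval `[start, end)` of its contraction.  Repetitions alternate
#' contraction then rest; movements are concatenated in listed order.
#'
#' @param s a `recording_session`.
#' @return A data.frame with columns `movement`, `repetition`, `start`,
#'   `end` (0-based, half-open), sorted by position.
#' @export
session_layout <- function(s) {
  validate_session(s)
  nc <- round_half_away(s$sampling_rate_hz * s$contraction_s)
  nr <- round_half_away(s$sampling_rate_hz * s$rest_s)
  seg <- nc + nr
  grid <- expand.grid(repetition = seq_len(s$n_repetitions),
                      movement = s$movements,
                      KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  idx <- (match(grid$movement, s$movements) - 1L) * s$n_repetitions +
    (grid$repetition - 1L)
  start <- idx * seg
  out <- data.frame(movement = grid$movement,
                    repetition = grid$repetition,
                    start = start, end = start + nc,
                    stringsAsFactors = FALSE)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  if (max(out$end) > nrow(s$signal)) {
    stop("inconsistent session: layout extends past signal end")
  }
  out
}
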