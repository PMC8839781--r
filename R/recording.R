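#' Construct a raw EEG recording
#'
#' The unit of I/O for the pipeline: a channels-by-time matrix of EEG samples
#' in microvolts, its sampling rate, channel names, and a table of events
#' (keypress responses) with onsets in seconds.
#'
#' @param samples Numeric matrix, channels x time, in microvolts.
#' @param fs Sampling rate in Hz (the recording system here runs at 256 Hz).
#' @param channel_names Character vector of unique channel names
#'   (10-20 montage labels such as `"Fz"`).
#' @param events Tibble with columns `onset_s` (numeric, seconds from the
#'   start of the recording) and `label` (character). Defaults to no events.
#'
#' @return An object of class `eeg_recording`: a list with elements
#'   `samples`, `fs`, `channel_names`, `events`.
#' @export
#' @examples
#' rec <- eeg_recording(matrix(rnorm(2 * 512), 2), fs = 256,
#'                      channel_names = c("Fz", "Cz"))
#' rec
eeg_recording <- function(samples, fs, channel_names,
                          events = tibble::tibble(onset_s = numeric(),
                                                  label = character())) {
  if (!is.matrix(samples) || !is.numeric(samples)) {
    abort("`samples` must be a numeric channels x time matrix.")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    abort("`fs` must be a single positive number (Hz).")
  }
  channel_names <- as.character(channel_names)
  if (length(channel_names) != nrow(samples)) {
    abort(sprintf(
      "%d channel names supplied for %d signal rows.",
      length(channel_names), nrow(samples)))
  }
  if (anyDuplicated(channel_names)) {
    abort("`channel_names` must be unique.")
  }
  events <- as_tibble(events)
  if (!all(c("onset_s", "label") %in% names(events))) {
    abort("`events` must have columns `onset_s` and `label`.")
  }
  dur <- ncol(samples) / fs
  if (nrow(events) && (any(events$onset_s < 0) || any(events$onset_s > dur))) {
    abort(sprintf(
      "event onsets must lie within [0, %.3f] s (recording duration).", dur))
  }
  structure(
    list(samples = samples, fs = fs, channel_names = channel_names,
         events = events),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
              nrow(x$samples), ncol(x$samples), x$fs,
              ncol(x$samples) / x$fs, nrow(x$events)))
  cat("channels:", paste(x$channel_names, collapse = " "), "\n")
  invisible(x)
}

#' @export
#' @rdname eeg_recording
#' @param x An `eeg_recording`.
recording_duration <- function(x) {
  stopifnot(inherits(x, "eeg_recording"))
  ncol(x$samples) / x$fs
}

# Locate a channel row index by name, with a clear error.
channel_index <- function(rec, channel) {
  i <- match(channel, rec$channel_names)
  if (is.na(i)) {
    abort(sprintf("channel '%s' not present (have: %s)", channel,
                  paste(rec$channel_names, collapse = ", ")))
  }
  i
}
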