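#' Read and write recordings
#'
#' Recordings are stored either as EDF (16-bit, one-second data records) or
#' as a plain layout: a TSV matrix of samples (rows = time, columns =
#' channels) plus a small JSON metadata sidecar holding the sampling rate.
#' In both formats events live in a `<stem>_events.tsv` sidecar with
#' columns `onset_s` and `label`; a missing sidecar yields an empty event
#' table with a warning.
#'
#' @param rec An [eeg_recording()].
#' @param path File path. For `format = "plain"` this is the matrix TSV;
#'   metadata and events sidecars are derived from its stem.
#' @param format `"edf"` or `"plain"`. Default guesses from the extension.
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   returns an [eeg_recording()].
#' @export
write_recording <- function(rec, path, format = c("auto", "edf", "plain")) {
  format <- resolve_format(match.arg(format), path)
  stopifnot(inherits(rec, "eeg_recording"))
  if (format == "edf") {
    write_edf(rec, path)
  } else {
    df <- as.data.frame(t(rec$samples))
    names(df) <- rec$channel_names
    readr::write_tsv(df, path, progress = FALSE)
    jsonlite::write_json(list(fs = rec$fs), meta_path(path), auto_unbox = TRUE)
  }
  readr::write_tsv(rec$events, events_path(path), progress = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path, format = c("auto", "edf", "plain")) {
  format <- resolve_format(match.arg(format), path)
  if (!file.exists(path)) abort(sprintf("'%s' does not exist.", path))
  if (format == "edf") {
    rec <- read_edf(path)
  } else {
    mp <- meta_path(path)
    if (!file.exists(mp)) {
      abort(sprintf("plain layout metadata sidecar '%s' is missing (field fs).", mp))
    }
    meta <- jsonlite::read_json(mp)
    if (is.null(meta$fs)) abort(sprintf("'%s': missing field 'fs'.", mp))
    df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    rec <- eeg_recording(t(as.matrix(df)), fs = as.numeric(meta$fs),
                         channel_names = names(df))
  }
  ep <- events_path(path)
  if (file.exists(ep)) {
    ev <- readr::read_tsv(ep, show_col_types = FALSE, progress = FALSE,
                          col_types = readr::cols(
                            onset_s = readr::col_double(),
                            label = readr::col_character()))
    rec <- eeg_recording(rec$samples, rec$fs, rec$channel_names, events = ev)
  } else {
    warn(sprintf("no event sidecar '%s'; returning an empty event table.", ep))
  }
  rec
}

resolve_format <- function(format, path) {
  if (format != "auto") return(format)
  if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "plain"
}

events_path <- function(path) {
  paste0(sub("\\.[A-Za-z0-9]+$", "", path), "_events.tsv")
}

meta_path <- function(path) {
  paste0(sub("\\.[A-Za-z0-9]+$", "", path), "_meta.json")
}
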