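#' Extract keypress-locked epochs
#'
#' Cuts fixed-length windows around each keypress event on one analysis
#' channel (default `"Fz"`, the clinical recording site for tinnitus).
#' The window spans 500 ms before to 1 s after the press: sample indices
#' `[round(onset*fs) - round(0.5*fs), round(onset*fs) + round(1.0*fs))`,
#' half-open, so at 256 Hz each epoch has exactly 128 + 256 = 384 samples.
#' Events whose window leaves the recording, or overlaps a burst mask
#' attached by [reject_burst_segments()], are dropped and counted.
#'
#' @param rec An [eeg_recording()] with events.
#' @param channel Analysis channel name.
#' @param tmin,tmax Window limits relative to the keypress, s.
#' @return An `epoch_set`: list with `epochs` (epochs x time matrix), `fs`,
#'   `t_axis` (s, `t = 0` at the keypress sample), `labels`, and
#'   `n_dropped`.
#' @export
extract_epochs <- function(rec, channel = "Fz", tmin = -0.5, tmax = 1.0) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$events) == 0) abort("recording has no events to epoch.")
  ch <- channel_index(rec, channel)
  fs <- rec$fs
  n <- ncol(rec$samples)
  n_pre <- as.integer(round(-tmin * fs))
  n_post <- as.integer(round(tmax * fs))
  len <- n_pre + n_post
  mask <- attr(rec, "burst_mask")

  x <- rec$samples[ch, ]
  rows <- list(); labels <- character(); dropped <- 0L
  for (e in seq_len(nrow(rec$events))) {
    c0 <- as.integer(round(rec$events$onset_s[e] * fs))   # 0-based event sample
    from <- c0 - n_pre + 1L                               # 1-based window start
    to <- c0 + n_post
    if (from < 1L || to > n || (!is.null(mask) && any(mask[from:to]))) {
      dropped <- dropped + 1L
      next
    }
    rows[[length(rows) + 1L]] <- x[from:to]
    labels <- c(labels, rec$events$label[e])
  }
  if (length(rows) == 0) {
    abort("zero usable events after boundary/burst-mask exclusion.")
  }
  structure(
    list(epochs = do.call(rbind, rows), fs = fs,
         t_axis = (seq_len(len) - n_pre - 1L) / fs,
         labels = labels, n_dropped = dropped),
    class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs x %d samples @ %g Hz, t in [%.3f, %.3f] s (%d dropped)\n",
              nrow(x$epochs), ncol(x$epochs), x$fs,
              min(x$t_axis), max(x$t_axis), x$n_dropped))
  invisible(x)
}
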