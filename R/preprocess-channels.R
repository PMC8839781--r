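#' Detect bad channels
#'
#' Screens every channel against the three rejection criteria used before
#' epoching: (1) *flat*: any constant run longer than `flat_s` seconds;
#' (2) *high-frequency noise*: the standard deviation of the channel's
#' 15-30 Hz component, expressed as a robust z-score against the
#' median/MAD of that statistic across channels, exceeding `hf_sd`;
#' (3) *low correlation*: maximum absolute Pearson correlation with the
#' other channels below `min_corr`. A channel is flagged iff at least one
#' criterion fires.
#'
#' The correlation neighborhood is all other channels; pass a named list
#' of neighbor vectors via `neighbors` to restrict it to a montage map.
#'
#' @param rec An [eeg_recording()] (at least two channels).
#' @param flat_s Maximum tolerated constant run, s (default 5).
#' @param hf_sd High-frequency noise threshold in robust z units (default 4).
#' @param min_corr Minimum acceptable correlation with nearby channels
#'   (default 0.8).
#' @param hf_band Band, Hz, whose component defines "high-frequency" noise.
#' @param neighbors Optional named list: `neighbors[["Fz"]]` gives the
#'   channels `"Fz"` is compared against.
#' @return A tibble, one row per channel: the three supporting statistics
#'   (`flat_run_s`, `hf_z`, `max_neighbor_corr`), the per-criterion flags,
#'   and `bad = ` their union.
#' @export
detect_bad_channels <- function(rec, flat_s = 5, hf_sd = 4, min_corr = 0.8,
                                hf_band = c(15, 30), neighbors = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  nchan <- nrow(rec$samples)
  if (nchan < 2) {
    abort("correlation criterion needs at least 2 channels.")
  }
  fs <- rec$fs

  flat_run <- vapply(seq_len(nchan), function(ch) {
    r <- rle(c(TRUE, abs(diff(rec$samples[ch, ])) < 1e-12))
    max(r$lengths[r$values]) / fs
  }, 0)

  # SD of the 15-30 Hz component per channel (FFT band selection), robust
  # z-scored across channels
  hf_sd_ch <- vapply(seq_len(nchan), function(ch) {
    x <- rec$samples[ch, ]
    n <- length(x)
    X <- fft(x - mean(x))
    f <- (seq_len(n) - 1) * fs / n
    f <- pmin(f, fs - f)
    keep <- f >= hf_band[1] & f <= hf_band[2]
    sd(Re(fft(X * keep, inverse = TRUE)) / n)
  }, 0)
  med <- median(hf_sd_ch)
  scale <- mad(hf_sd_ch)
  if (scale < 1e-12) scale <- max(med, 1e-12)
  hf_z <- (hf_sd_ch - med) / scale

  cm <- abs(suppressWarnings(cor(t(rec$samples))))
  diag(cm) <- NA
  max_corr <- vapply(seq_len(nchan), function(ch) {
    others <- if (is.null(neighbors)) seq_len(nchan)[-ch] else {
      match(neighbors[[rec$channel_names[ch]]], rec$channel_names)
    }
    m <- suppressWarnings(max(cm[ch, others], na.rm = TRUE))
    if (is.finite(m)) m else 0
  }, 0)

  tibble(
    channel = rec$channel_names,
    flat_run_s = flat_run,
    hf_z = hf_z,
    max_neighbor_corr = max_corr,
    flat = flat_run > flat_s,
    hf_noise = hf_z > hf_sd,
    low_correlation = max_corr < min_corr
  ) |>
    dplyr::mutate(bad = .data$flat | .data$hf_noise | .data$low_correlation)
}

#' Reject high-amplitude burst segments
#'
#' A windowed large-amplitude artifact rejector: the recording is cut into
#' non-overlapping windows of `window_s` seconds, a per-channel calibration
#' SD is taken over the quietest quartile of windows (lowest RMS), and any
#' window whose RMS strictly exceeds `k` times the calibration SD on any
#' channel is masked. Masked periods are excluded from epoching.
#'
#' @param rec An [eeg_recording()] of at least one window.
#' @param k Threshold multiplier on the calibration SD (default 20).
#' @param window_s Window length, s.
#' @return A list: `recording` (unchanged signal, with the mask attached as
#'   attribute `"burst_mask"`), and `mask` — a list with the per-sample
#'   logical `mask`, per-channel `calibration_sd`, and `k`.
#' @export
reject_burst_segments <- function(rec, k = 20, window_s = 0.5) {
  stopifnot(inherits(rec, "eeg_recording"))
  n <- ncol(rec$samples)
  win <- as.integer(round(window_s * rec$fs))
  if (win < 1 || n < win) abort("recording shorter than one window.")
  n_win <- n %/% win
  nchan <- nrow(rec$samples)

  rms <- matrix(0, nchan, n_win)
  for (w in seq_len(n_win)) {
    idx <- ((w - 1) * win + 1):(w * win)
    rms[, w] <- sqrt(rowMeans(rec$samples[, idx, drop = FALSE]^2))
  }
  # calibration: per channel, SD over the quietest quartile of windows
  calib <- vapply(seq_len(nchan), function(ch) {
    q <- quantile(rms[ch, ], 0.25)
    quiet <- which(rms[ch, ] <= q)
    idx <- unlist(lapply(quiet, function(w) ((w - 1) * win + 1):(w * win)))
    sd(rec$samples[ch, idx])
  }, 0)
  if (all(calib < 1e-12)) abort("no calibratable data: all channels flat.")

  bad_win <- colSums(rms > k * calib) > 0        # strict: "exceeded k times"
  if (all(bad_win)) abort("no calibratable data: every window exceeds threshold.")
  mask <- rep(FALSE, n)
  for (w in which(bad_win)) mask[((w - 1) * win + 1):(w * win)] <- TRUE

  out <- rec
  attr(out, "burst_mask") <- mask
  list(recording = out,
       mask = list(mask = mask, calibration_sd = calib, k = k,
                   window_s = window_s))
}
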