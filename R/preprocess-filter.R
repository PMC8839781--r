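# Butterworth design as cascaded second-order sections from the closed-form
# analog prototype. At the 0.1 Hz highpass edge (normalized cutoff ~8e-4 at
# 256 Hz) the expanded transfer-function polynomial is numerically
# ill-conditioned, so the filter is kept factored: each conjugate pole pair
# becomes one biquad via the bilinear transform and sections are applied in
# cascade, which stays stable at arbitrary cutoffs.

butter_sos <- function(order, fc, fs, type = c("low", "high")) {
  type <- match.arg(type)
  if (order %% 2 != 0) abort("even filter order required for biquad pairing.")
  wc <- 2 * fs * tan(pi * fc / fs)                 # prewarped cutoff, rad/s
  k <- seq_len(order)
  p0 <- exp(1i * (pi * (2 * k - 1) / (2 * order) + pi / 2))  # unit LP poles
  p <- if (type == "low") wc * p0 else wc / p0
  fs2 <- 2 * fs
  pz <- (fs2 + p) / (fs2 - p)                      # bilinear transform
  z0 <- if (type == "low") -1 else 1               # zeros map to z = -1 / +1
  used <- rep(FALSE, order)
  sos <- list()
  for (i in seq_len(order)) {
    if (used[i]) next
    j <- which(!used & seq_len(order) != i &
                 abs(pz - Conj(pz[i])) < 1e-8)[1]
    used[c(i, j)] <- TRUE
    a <- Re(c(1, -(pz[i] + pz[j]), pz[i] * pz[j]))
    b <- c(1, -2 * z0, 1)
    sos[[length(sos) + 1L]] <- list(b = b, a = a)
  }
  # normalize unity gain at DC (lowpass) / Nyquist (highpass)
  zr <- if (type == "low") 1 + 0i else -1 + 0i
  g <- prod(vapply(sos, function(s) {
    Mod(sum(s$b * zr^(0:2)) / sum(s$a * zr^(0:2)))
  }, 0))
  sos[[1]]$b <- sos[[1]]$b / g
  sos
}

# apply biquads in cascade with steady-state initial conditions for a
# constant input x[1] (Gustafsson-style edge handling): without this the
# sub-Hz highpass transient decays over tens of seconds
sos_apply <- function(sos, x) {
  for (s in sos) {
    g1 <- sum(s$b) / sum(s$a)          # DC gain of this section
    x <- as.numeric(signal::filter(signal::Arma(b = s$b, a = s$a), x,
                                   init.x = rep(x[1], 2),
                                   init.y = rep(g1 * x[1], 2)))
  }
  x
}

# zero-phase (forward-backward) cascade with odd reflective padding
sos_filtfilt <- function(sos, x, padlen) {
  n <- length(x)
  padlen <- min(padlen, n - 1L)
  pre <- 2 * x[1] - x[(padlen + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - padlen)]
  y <- sos_apply(sos, c(pre, x, post))
  y <- rev(sos_apply(sos, rev(y)))
  y[(padlen + 1):(padlen + n)]
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies the recording-level pre-processing filter: an order-`order`
#' Butterworth band-pass (default 0.1-30 Hz) applied forward and backward
#' for zero phase distortion, per channel. Implemented as a cascade of an
#' order-`order` highpass and an order-`order` lowpass in second-order
#' sections; the effective magnitude response is the squared Butterworth
#' response.
#'
#' @param rec An [eeg_recording()].
#' @param low,high Cutoff frequencies, Hz; need `0 < low < high < fs/2`.
#' @param order Filter order of each Butterworth section (default 6).
#' @return The filtered recording (same length; events untouched).
#' @export
bandpass_filter <- function(rec, low = 0.1, high = 30, order = 6) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!(low > 0 && low < high && high < rec$fs / 2)) {
    abort(sprintf("cutoffs must satisfy 0 < low < high < fs/2 = %g.", rec$fs / 2))
  }
  hp <- butter_sos(order, low, rec$fs, "high")
  lp <- butter_sos(order, high, rec$fs, "low")
  # pad past the slowest transient of each section (~1 cycle of the cutoff)
  pad_hp <- max(3L * order, as.integer(ceiling(rec$fs / low)))
  pad_lp <- max(3L * order, as.integer(ceiling(rec$fs / high)))
  out <- rec$samples
  for (ch in seq_len(nrow(out))) {
    out[ch, ] <- sos_filtfilt(lp, sos_filtfilt(hp, out[ch, ], pad_hp), pad_lp)
  }
  eeg_recording(out, rec$fs, rec$channel_names, events = rec$events)
}
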