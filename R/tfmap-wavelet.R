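#' Complex Gaussian mother wavelet
#'
#' The analysis wavelet is the p-th derivative of the complex Gaussian
#' `f(x) = C_p exp(-ix) exp(-x^2)`, with the normalization constant `C_p`
#' chosen so the p-th derivative has unit L2 norm. The derivative is
#' computed exactly through the polynomial recurrence
#' `q_{k+1}(x) = q_k'(x) - (i + 2x) q_k(x)` with
#' `f^{(k)}(x) = q_k(x) exp(-ix - x^2)`, then normalized numerically
#' (trapezoidal L2) on the sampling grid.
#'
#' @param p Positive integer derivative order (1-8 supported; default 4
#'   balances time and frequency localization).
#' @param support Half-width of the sampling grid `[-support, support]`;
#'   8 comfortably contains the Gaussian tail.
#' @param n_points Grid points.
#' @return A `cgau_wavelet`: list with `p`, `x` (grid), `values` (complex,
#'   unit L2 norm), `C_p`, `center_frequency` (cycles per x-unit, from the
#'   spectral peak of the sampled wavelet), `l2_norm` (numerical check).
#' @export
#' @examples
#' w <- make_cgau_wavelet(4)
#' w$l2_norm          # 1 to ~1e-9
make_cgau_wavelet <- function(p = 4, support = 8, n_points = 2^14) {
  if (length(p) != 1 || !is.numeric(p) || p < 1 || p != round(p)) {
    abort("`p` must be a positive integer.")
  }
  p <- as.integer(p)
  x <- seq(-support, support, length.out = n_points)
  dx <- x[2] - x[1]

  q <- cgau_poly(p)
  poly <- vapply(x, function(xi) sum(q * xi^(seq_along(q) - 1)), 0i)
  vals <- poly * exp(-1i * x - x^2)

  nrm2 <- sum(Mod(vals)^2) * dx -
    0.5 * (Mod(vals[1])^2 + Mod(vals[n_points])^2) * dx   # trapezoid
  C_p <- 1 / sqrt(nrm2)
  vals <- vals * C_p

  # spectral peak from a zero-padded FFT of the sampled wavelet; the
  # wavelet is anti-analytic (energy at negative frequency), so search
  # the full signed axis and take the magnitude of the peak location
  nfft <- 2^18
  spec <- Mod(fft(c(vals, rep(0i, nfft - n_points))))
  fgrid <- (seq_len(nfft) - 1) / (nfft * dx)              # cycles per x-unit
  fgrid[fgrid > 1 / (2 * dx)] <- fgrid[fgrid > 1 / (2 * dx)] - 1 / dx
  fc <- abs(fgrid[which.max(spec)])

  l2 <- sqrt(sum(Mod(vals)^2) * dx -
               0.5 * (Mod(vals[1])^2 + Mod(vals[n_points])^2) * dx)
  structure(
    list(p = p, x = x, values = vals, C_p = C_p,
         center_frequency = fc, l2_norm = l2),
    class = "cgau_wavelet")
}

#' @export
print.cgau_wavelet <- function(x, ...) {
  cat(sprintf("<cgau_wavelet> p = %d, center frequency %.4f cycles/unit, ||f^(p)||_2 = %.8f\n",
              x$p, x$center_frequency, x$l2_norm))
  invisible(x)
}

# polynomial q_p (ascending complex coefficients) with
# d^p/dx^p [e^{-ix-x^2}] = q_p(x) e^{-ix-x^2}, via
# q_{k+1} = q_k' - (i + 2x) q_k
cgau_poly <- function(p) {
  q <- c(1 + 0i)
  for (k in seq_len(p)) {
    L <- length(q)
    dq <- if (L > 1) q[-1] * seq_len(L - 1) else complex(0)
    q <- c(dq, 0i, 0i)[seq_len(L + 1)] -      # q'
      1i * c(q, 0i) -                          # -i q
      2 * c(0i, q)                             # -2x q
  }
  q
}

# evaluate the (normalized) wavelet at arbitrary points
cgau_eval <- function(wavelet, x) {
  q <- cgau_poly(wavelet$p)
  poly <- vapply(x, function(xi) sum(q * xi^(seq_along(q) - 1)), 0i)
  wavelet$C_p * poly * exp(-1i * x - x^2)
}

#' Continuous wavelet transform of one epoch
#'
#' Convolves a single-channel epoch with scaled copies of the complex
#' Gaussian wavelet. The scale for each target frequency comes from the
#' wavelet's numerically determined spectral-peak (center) frequency:
#' `scale = center_frequency / f`. Epoch edges are handled by symmetric
#' reflective padding up to one wavelet support (capped at the epoch
#' length).
#'
#' @param x Numeric vector, one epoch.
#' @param freqs Target frequencies, Hz, within `(0, fs/2]`.
#' @param wavelet A [make_cgau_wavelet()].
#' @param fs Sampling rate, Hz.
#' @return Complex matrix, `length(x)` rows x `length(freqs)` columns.
#' @export
cwt_epoch <- function(x, freqs, wavelet, fs) {
  if (length(freqs) == 0) abort("empty frequency list.")
  if (any(freqs <= 0 | freqs > fs / 2)) {
    abort("frequencies must lie in (0, fs/2].")
  }
  stopifnot(inherits(wavelet, "cgau_wavelet"))
  n <- length(x)
  dt <- 1 / fs
  support <- max(abs(wavelet$x))
  out <- matrix(0i, n, length(freqs))
  for (j in seq_along(freqs)) {
    a <- wavelet$center_frequency / freqs[j]
    half <- ceiling(support * a / dt)
    tk <- (-half:half) * dt
    kern <- Conj(cgau_eval(wavelet, tk / a)) * dt / a   # L1 norm: flat sinusoid response across scales
    pad <- min(half, n - 1L)
    xp <- c(x[(pad + 1):2], x, x[(n - 1):(n - pad)])   # symmetric reflection
    # correlation with the kernel = convolution with its reversal;
    # sample b of the padded signal lands at y[b + half]
    y <- conv_complex(xp, rev(kern))
    out[, j] <- y[pad + half + seq_len(n)]
  }
  out
}

# complex full convolution via FFT
conv_complex <- function(x, k) {
  nx <- length(x); nk <- length(k)
  nfft <- stats::nextn(nx + nk - 1, 2)
  X <- fft(c(x, rep(0, nfft - nx)))
  K <- fft(c(k, rep(0i, nfft - nk)))
  fft(X * K, inverse = TRUE)[seq_len(nx + nk - 1)] / nfft
}
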