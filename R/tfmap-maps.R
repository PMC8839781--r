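#' ERD/ERS time-frequency map from per-epoch CWT coefficients
#'
#' Collapses a stack of per-epoch complex coefficient matrices into one
#' real, non-negative power map. The default mode averages the complex
#' coefficients across epochs and then takes the absolute value
#' (phase-locked, "evoked" emphasis); `abs_then_average` rectifies each
#' epoch first (induced power). With a single epoch, or identical epochs,
#' the two modes coincide.
#'
#' @param coef_list List of complex time x frequency matrices of identical
#'   shape (one per epoch), e.g. from [cwt_epoch()].
#' @param freqs,t_axis Frequency (Hz) and time (s) axes of the maps.
#' @param mode `"average_then_abs"` (default) or `"abs_then_average"`.
#' @return A `tf_map`: list with `P` (time x frequency, real,
#'   non-negative), `freqs`, `t_axis`, `corrected = FALSE`, `mode`,
#'   `n_epochs`.
#' @export
average_and_rectify <- function(coef_list, freqs, t_axis,
                                mode = c("average_then_abs",
                                         "abs_then_average")) {
  mode <- match.arg(mode)
  if (length(coef_list) < 1) abort("need at least one epoch.")
  dims <- unique(lapply(coef_list, dim))
  if (length(dims) != 1) abort("epoch coefficient matrices differ in shape.")
  if (mode == "average_then_abs") {
    P <- Mod(Reduce(`+`, coef_list) / length(coef_list))
  } else {
    P <- Reduce(`+`, lapply(coef_list, Mod)) / length(coef_list)
  }
  structure(
    list(P = P, freqs = freqs, t_axis = t_axis, corrected = FALSE,
         baseline = NULL, mode = mode, n_epochs = length(coef_list)),
    class = "tf_map")
}

#' Baseline-correct a time-frequency map
#'
#' Subtracts, at each frequency, the mean power over the pre-event
#' reference window (default -400 to -100 ms before the keypress):
#' `BC(t, f) = P(t, f) - Rbar(f)`. Window endpoints are converted to
#' samples by rounding and both endpoint samples are included. After
#' correction the per-frequency mean over the window is zero.
#'
#' @param map A `tf_map` (uncorrected).
#' @param window Reference window `c(from, to)` in seconds.
#' @return The corrected `tf_map`, with `baseline` holding `Rbar(f)` and
#'   `corrected = TRUE`. Correcting twice is an error.
#' @export
baseline_correct <- function(map, window = c(-0.4, -0.1)) {
  stopifnot(inherits(map, "tf_map"))
  if (isTRUE(map$corrected)) abort("map is already baseline-corrected.")
  dt <- map$t_axis[2] - map$t_axis[1]
  s <- round(map$t_axis / dt)               # integer sample offsets
  keep <- s >= round(window[1] / dt) & s <= round(window[2] / dt)
  if (!any(keep)) abort("baseline window lies outside the epoch time axis.")
  rbar <- colMeans(map$P[keep, , drop = FALSE])
  map$P <- sweep(map$P, 2, rbar)
  map$baseline <- rbar
  map$corrected <- TRUE
  map
}

#' @export
print.tf_map <- function(x, ...) {
  cat(sprintf("<tf_map> %d time x %d frequency, %s, %scorrected (%d epochs)\n",
              nrow(x$P), ncol(x$P), x$mode,
              if (isTRUE(x$corrected)) "baseline-" else "un", x$n_epochs))
  invisible(x)
}

#' Mean map power inside a time x frequency window
#'
#' Convenience accessor used by the ERS-recovery checks: the mean of
#' `P(t, f)` over `t` in `t_window` and `f` in `f_window`.
#'
#' @param map A `tf_map`.
#' @param f_window,t_window Bands `c(from, to)` in Hz and s.
#' @return A single number.
#' @export
band_power <- function(map, f_window, t_window) {
  stopifnot(inherits(map, "tf_map"))
  fi <- map$freqs >= f_window[1] & map$freqs <= f_window[2]
  ti <- map$t_axis >= t_window[1] & map$t_axis <= t_window[2]
  if (!any(fi) || !any(ti)) abort("window selects no map cells.")
  mean(map$P[ti, fi])
}

#' Heat map of a time-frequency map
#'
#' @param object A `tf_map`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.tf_map <- function(object, ...) {
  df <- tibble(t = rep(object$t_axis, times = length(object$freqs)),
               f = rep(object$freqs, each = length(object$t_axis)),
               power = as.vector(object$P))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$f,
                                   fill = .data$power)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "time relative to keypress (s)", y = "frequency (Hz)",
                  fill = "power") +
    ggplot2::theme_minimal()
}

#' Default analysis frequency grid
#'
#' 60 log-spaced frequencies in `[0.5, 30]` Hz (default), or a linear grid
#' reaching down to 0.1 Hz. At 1.5 s epochs, frequencies below roughly
#' 0.7 Hz are under-resolved by the wavelet support; they are kept, not
#' truncated, and the limitation is documented.
#'
#' @param n Number of frequencies.
#' @param range Frequency range, Hz.
#' @param spacing `"log"` or `"linear"`.
#' @return Numeric vector of frequencies, Hz.
#' @export
analysis_freqs <- function(n = 60, range = c(0.5, 30),
                           spacing = c("log", "linear")) {
  spacing <- match.arg(spacing)
  if (spacing == "log") exp(seq(log(range[1]), log(range[2]), length.out = n))
  else seq(range[1], range[2], length.out = n)
}
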