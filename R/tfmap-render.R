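#' Render a time-frequency map as a scalogram image
#'
#' Writes a deterministic color-mapped PNG of the map at canvas size
#' (default 1200 x 900, the native scalogram figure size) plus a resized
#' copy (default 160 x 160, the backbone input size), and a JSON sidecar
#' recording the value-to-color scaling so images remain interpretable.
#'
#' @param map A `tf_map` with finite values.
#' @param path Output PNG path for the canvas image; the resized copy gets
#'   suffix `_resized`, the sidecar `.json`.
#' @param canvas `c(width, height)` in pixels.
#' @param out_size `c(width, height)` of the resized copy.
#' @param colormap Name of a `grDevices::hcl.colors` palette (fixed
#'   default `"viridis"`; the palette choice affects downstream features
#'   and is therefore recorded in the sidecar).
#' @return Invisibly, a list of the three paths written.
#' @export
render_scalogram <- function(map, path, canvas = c(1200, 900),
                             out_size = c(160, 160), colormap = "viridis") {
  stopifnot(inherits(map, "tf_map"))
  if (!all(is.finite(map$P))) abort("map contains non-finite values.")
  vmin <- min(map$P); vmax <- max(map$P)
  v <- if (vmax - vmin < 1e-300) {
    matrix(0.5, nrow(map$P), ncol(map$P))
  } else {
    (map$P - vmin) / (vmax - vmin)
  }
  pal <- grDevices::hcl.colors(256, colormap)
  rgb <- grDevices::col2rgb(pal) / 255
  idx <- pmin(255L, pmax(0L, as.integer(round(v * 255)))) + 1L
  # image rows = frequency (highest on top), columns = time
  nf <- ncol(map$P); nt <- nrow(map$P)
  ord <- rev(seq_len(nf))
  img <- array(0, c(nf, nt, 3))
  for (ch in 1:3) {
    img[, , ch] <- t(matrix(rgb[ch, idx], nt, nf))[ord, ]
  }
  big <- resize_image(img, canvas[1], canvas[2])
  png::writePNG(big, path)
  small <- resize_image(big, out_size[1], out_size[2])
  resized_path <- sub("\\.png$", "_resized.png", path)
  png::writePNG(small, resized_path)
  meta_path <- sub("\\.png$", ".json", path)
  jsonlite::write_json(
    list(vmin = vmin, vmax = vmax, colormap = colormap,
         canvas = canvas, out_size = out_size,
         corrected = isTRUE(map$corrected), mode = map$mode),
    meta_path, auto_unbox = TRUE, digits = NA)
  invisible(list(canvas = path, resized = resized_path, meta = meta_path))
}

# bilinear resize of an H x W x 3 array to width w, height h
resize_image <- function(img, w, h) {
  ebi <- EBImage::Image(aperm(img, c(2, 1, 3)), colormode = "Color")
  out <- EBImage::resize(ebi, w = w, h = h, filter = "bilinear")
  arr <- aperm(as.array(out), c(2, 1, 3))
  pmin(pmax(arr, 0), 1)
}

#' Compute an ERD/ERS map from an epoch set
#'
#' Pipeline convenience: runs the complex Gaussian CWT over every epoch,
#' collapses the stack with [average_and_rectify()], and (by default)
#' applies [baseline_correct()]. Set `per_epoch = TRUE` to instead obtain
#' one rectified map per epoch (the per-scalogram route feeding the deep
#' feature extractor).
#'
#' @param epochs An `epoch_set` from [extract_epochs()].
#' @param freqs Frequency grid, Hz (default [analysis_freqs()]).
#' @param p Wavelet derivative order, 1-8.
#' @param mode Rectification mode, see [average_and_rectify()].
#' @param baseline Baseline window in s, or `NULL` to skip correction.
#' @param per_epoch Return a list of per-epoch maps instead of one
#'   averaged map.
#' @return A `tf_map`, or a list of them when `per_epoch = TRUE`.
#' @export
erd_map <- function(epochs, freqs = analysis_freqs(), p = 4,
                    mode = "average_then_abs", baseline = c(-0.4, -0.1),
                    per_epoch = FALSE) {
  stopifnot(inherits(epochs, "epoch_set"))
  w <- make_cgau_wavelet(p)
  coefs <- lapply(seq_len(nrow(epochs$epochs)), function(e) {
    cwt_epoch(epochs$epochs[e, ], freqs, w, epochs$fs)
  })
  finish <- function(map) {
    if (is.null(baseline)) map else baseline_correct(map, baseline)
  }
  if (per_epoch) {
    lapply(coefs, function(cf) {
      finish(average_and_rectify(list(cf), freqs, epochs$t_axis, mode))
    })
  } else {
    finish(average_and_rectify(coefs, freqs, epochs$t_axis, mode))
  }
}
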