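#' Generate labeled scalogram-image fixtures
#'
#' Produces a four-class image dataset with the class structure of the
#' study's scalogram corpus: tinnitus before/after and control
#' before/after treatment, with default class sizes 801/667/500/500
#' (2468 images in total). Each class carries a distinct spatial
#' band-pattern (a smooth time-frequency blob at class-specific
#' coordinates) whose contrast against the pixel noise is scaled by
#' `separation`; at `separation = 0` the classes are statistically
#' indistinguishable.
#'
#' Images are written as 8-bit RGB PNGs together with a CSV manifest
#' (`file`, `class`, `group`, `session`).
#'
#' @param dir Output directory (created if missing).
#' @param n_per_class Named integer vector over classes `tinnitus_S1`,
#'   `tinnitus_S2`, `control_S1`, `control_S2`.
#' @param image_size Side of the square images, pixels.
#' @param separation Non-negative effect size scaling between-class contrast.
#' @param seed RNG seed.
#' @return The manifest tibble, invisibly; also written to
#'   `file.path(dir, "manifest.csv")`.
#' @export
generate_scalogram_fixtures <- function(dir,
                                        n_per_class = c(tinnitus_S1 = 801,
                                                        tinnitus_S2 = 667,
                                                        control_S1 = 500,
                                                        control_S2 = 500),
                                        image_size = 160,
                                        separation = 1,
                                        seed = 1L) {
  classes <- c("tinnitus_S1", "tinnitus_S2", "control_S1", "control_S2")
  if (!all(classes %in% names(n_per_class))) {
    abort(sprintf("n_per_class must name all of: %s.",
                  paste(classes, collapse = ", ")))
  }
  if (any(n_per_class[classes] < 1)) abort("all class sizes must be >= 1.")
  if (image_size < 8) abort("image_size too small.")
  if (separation < 0) abort("separation must be >= 0.")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  # class-specific blob centers in (time, frequency) image coordinates,
  # echoing the ERS patterns the cohort generator injects
  blob <- list(
    tinnitus_S1 = c(x = 0.75, y = 0.80, w = 0.12, h = 0.08),  # late, high band
    tinnitus_S2 = c(x = 0.30, y = 0.30, w = 0.15, h = 0.10),  # early alpha
    control_S1  = c(x = 0.35, y = 0.38, w = 0.15, h = 0.10),
    control_S2  = c(x = 0.42, y = 0.34, w = 0.15, h = 0.10))

  gx <- seq(0, 1, length.out = image_size)
  rows <- with_seed(seed, {
    purrr::map(classes, function(cl) {
      b <- blob[[cl]]
      pattern <- outer(exp(-(gx - b["y"])^2 / (2 * b["h"]^2)),
                       exp(-(gx - b["x"])^2 / (2 * b["w"]^2)))
      gs <- strsplit(cl, "_")[[1]]
      purrr::map(seq_len(n_per_class[[cl]]), function(i) {
        img <- 0.35 + 0.35 * separation * pattern +
          matrix(rnorm(image_size^2, sd = 0.12), image_size)
        img <- pmin(pmax(img, 0), 1)
        arr <- array(img, c(image_size, image_size, 3))
        fn <- sprintf("%s_%04d.png", cl, i)
        png::writePNG(arr, file.path(dir, fn))
        tibble(file = fn, class = cl, group = gs[1], session = gs[2])
      })
    })
  })
  manifest <- dplyr::bind_rows(rows)
  readr::write_csv(manifest, file.path(dir, "manifest.csv"), progress = FALSE)
  invisible(manifest)
}

#' Load a scalogram image as a [0, 255] array
#'
#' @param path PNG path.
#' @return H x W x 3 numeric array with values in `[0, 255]`, the pixel
#'   range [preprocess_image()] expects.
#' @export
load_scalogram_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(img, c(dim(img), 3))
  if (dim(img)[3] == 4) img <- img[, , 1:3]
  img * 255
}
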