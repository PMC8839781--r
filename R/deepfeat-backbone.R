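#' Image preprocessing for the feature backbone
#'
#' Bilinearly resizes a 3-channel image to the backbone input size and
#' linearly rescales pixel values from `[0, 255]` to `[-1, 1]`
#' (`v/127.5 - 1`). An already correctly sized input is passed through
#' without resampling.
#'
#' @param img H x W x 3 numeric array, pixel range `[0, 255]`.
#' @param size Target side length, pixels (default 160).
#' @return `size` x `size` x 3 array in `[-1, 1]`.
#' @export
preprocess_image <- function(img, size = 160) {
  d <- dim(img)
  if (length(d) != 3 || d[3] != 3) {
    abort("expected an H x W x 3 image array.")
  }
  if (d[1] != size || d[2] != size) {
    img <- resize_image(img / 255, size, size) * 255
  }
  img / 127.5 - 1
}

relu6 <- function(x) pmin(pmax(x, 0), 6)

pad_hw <- function(x, p = 1L) {
  d <- dim(x)
  out <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3]))
  out[(p + 1):(p + d[1]), (p + 1):(p + d[2]), ] <- x
  out
}

dwconv3 <- function(x, k, stride = 1L) {
  d <- dim(x)
  Ho <- if (stride == 1L) d[1] else d[1] %/% 2L
  Wo <- if (stride == 1L) d[2] else d[2] %/% 2L
  P <- pad_hw(x)
  out <- array(0, c(Ho, Wo, d[3]))
  n <- Ho * Wo
  for (dy in 1:3) for (dx in 1:3) {
    rows <- seq.int(dy, by = stride, length.out = Ho)
    cols <- seq.int(dx, by = stride, length.out = Wo)
    out <- out + P[rows, cols, , drop = FALSE] * rep(k[dy, dx, ], each = n)
  }
  out
}

pwconv <- function(x, w, b) {
  d <- dim(x)
  m <- sweep(matrix(x, d[1] * d[2], d[3]) %*% w, 2, b, "+")
  array(m, c(d[1], d[2], ncol(w)))
}

conv3 <- function(x, w, b, stride = 2L) {
  d <- dim(x)
  Ho <- d[1] %/% stride; Wo <- d[2] %/% stride
  P <- pad_hw(x)
  cols <- matrix(0, Ho * Wo, 9 * d[3])
  j <- 0L
  for (dy in 1:3) for (dx in 1:3) for (c in seq_len(d[3])) {
    j <- j + 1L
    cols[, j] <- P[seq.int(dy, by = stride, length.out = Ho),
                   seq.int(dx, by = stride, length.out = Wo), c]
  }
  array(sweep(cols %*% w, 2, b, "+"), c(Ho, Wo, ncol(w)))
}

#' MobileNet-V2-style feature backbone
#'
#' A depthwise-separable convolutional feature extractor with output
#' stride 32 and final width 1280: a strided 3 x 3 stem followed by
#' inverted-residual blocks (1 x 1 expansion, 3 x 3 depthwise, 1 x 1
#' projection, residual add where shapes permit; ReLU6 activations),
#' closed by a 1 x 1 convolution to 1280 channels. At 160 x 160 x 3
#' input the output block is 5 x 5 x 1280; at 224 x 224, 7 x 7 x 1280.
#'
#' Weights are He-scaled Gaussian draws from `seed`, giving a
#' deterministic random-projection feature extractor suitable for
#' download-free testing; `weights` accepts a previously saved weight
#' list (e.g. converted pretrained weights) as a drop-in replacement.
#'
#' @param seed Seed for the random weights.
#' @param widths Output channels of the inverted-residual blocks.
#' @param strides Stride (1 or 2) of each block; with the stem the product
#'   of all strides must be 32.
#' @param expansion Expansion factor of each block.
#' @param out_channels Width of the final feature block (1280).
#' @param weights Optional weight list from a previous `mobilenet_v2_backbone()`.
#' @return A `backbone` object (list of layer weights plus metadata).
#' @export
mobilenet_v2_backbone <- function(seed = 1L,
                                  widths = c(16, 24, 24, 32, 64, 96),
                                  strides = c(1, 2, 1, 2, 2, 2),
                                  expansion = c(1, 6, 6, 6, 6, 6),
                                  out_channels = 1280,
                                  weights = NULL) {
  if (!is.null(weights)) {
    stopifnot(inherits(weights, "backbone"))
    return(weights)
  }
  stopifnot(length(widths) == length(strides),
            length(widths) == length(expansion))
  he <- function(n, fan) rnorm(n, sd = sqrt(2 / fan))
  with_seed(as.integer(seed), {
    stem_c <- 16L
    W <- list(stem = list(w = matrix(he(27 * stem_c, 27), 27, stem_c),
                          b = numeric(stem_c)))
    cin <- stem_c
    blocks <- list()
    for (i in seq_along(widths)) {
      cmid <- cin * expansion[i]
      blk <- list(stride = strides[i], cin = cin, cout = widths[i],
                  expansion = expansion[i])
      if (expansion[i] > 1) {
        blk$we <- matrix(he(cin * cmid, cin), cin, cmid)
      }
      blk$kd <- array(he(9 * cmid, 9), c(3, 3, cmid))
      blk$wp <- matrix(he(cmid * widths[i], cmid), cmid, widths[i])
      blocks[[i]] <- blk
      cin <- widths[i]
    }
    W$blocks <- blocks
    W$head <- list(w = matrix(he(cin * out_channels, cin), cin, out_channels),
                   b = numeric(out_channels))
    structure(c(W, list(out_channels = out_channels, stride = 32L,
                        seed = as.integer(seed))),
              class = "backbone")
  })
}

#' @export
print.backbone <- function(x, ...) {
  cat(sprintf("<backbone> MobileNet-V2-style, stride %d, %d blocks, final width %d (seed %d)\n",
              x$stride, length(x$blocks), x$out_channels, x$seed))
  invisible(x)
}

#' Run the backbone over a preprocessed image
#'
#' @param img Output of [preprocess_image()]: side divisible by the
#'   backbone stride (32).
#' @param backbone A [mobilenet_v2_backbone()].
#' @return h x w x 1280 feature block (5 x 5 x 1280 at 160 x 160 input).
#' @export
extract_feature_block <- function(img, backbone) {
  stopifnot(inherits(backbone, "backbone"))
  d <- dim(img)
  if (length(d) != 3 || d[3] != 3) abort("expected an H x W x 3 array.")
  if (d[1] %% backbone$stride != 0 || d[2] %% backbone$stride != 0) {
    abort(sprintf("input size %dx%d is not divisible by the stride (%d).",
                  d[1], d[2], backbone$stride))
  }
  h <- relu6(conv3(img, backbone$stem$w, backbone$stem$b, 2L))
  for (blk in backbone$blocks) {
    inp <- h
    if (blk$expansion > 1) {
      h <- relu6(pwconv(h, blk$we, numeric(ncol(blk$we))))
    }
    h <- relu6(dwconv3(h, blk$kd, blk$stride))
    h <- pwconv(h, blk$wp, numeric(blk$cout))
    if (blk$stride == 1L && blk$cin == blk$cout) h <- h + inp
  }
  relu6(pwconv(h, backbone$head$w, backbone$head$b))
}

#' Global average pooling
#'
#' Spatial mean per channel: reduces an h x w x c feature block to a
#' c-vector (the deep-spectrum feature vector when c = 1280).
#'
#' @param block h x w x c numeric array, h, w >= 1.
#' @return Numeric c-vector.
#' @export
global_average_pool <- function(block) {
  d <- dim(block)
  if (length(d) != 3 || any(d == 0)) abort("expected a non-empty h x w x c block.")
  colMeans(matrix(block, d[1] * d[2], d[3]))
}

#' Deep-spectrum features of a set of images
#'
#' Maps each image through [preprocess_image()], the backbone and
#' [global_average_pool()], returning a [feature_set()] tibble.
#'
#' @param images List of H x W x 3 arrays in `[0, 255]`, or a character
#'   vector of PNG paths.
#' @param backbone A [mobilenet_v2_backbone()].
#' @param subject,group,session Label vectors recycled over the images.
#' @return A `feature_set` tibble with `length(images)` rows.
#' @export
deep_features <- function(images, backbone, subject = "s1",
                          group = "tinnitus", session = "S1") {
  if (is.character(images)) images <- lapply(images, load_scalogram_image)
  vecs <- purrr::map(images, function(img) {
    global_average_pool(extract_feature_block(preprocess_image(img), backbone))
  })
  feature_set(do.call(rbind, vecs), subject, group, session)
}
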