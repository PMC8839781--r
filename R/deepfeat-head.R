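#' Training configuration for the classifier head
#'
#' The study's training recipe: Adam with learning rate 1e-4, dropout 0.2
#' between pooling and the dense layer, batch size 32, 25 epochs, 80/20
#' stratified train/validation split.
#'
#' @param learning_rate Adam step size.
#' @param dropout Input dropout probability in `[0, 1)`, training only.
#' @param batch_size Minibatch size.
#' @param epochs Training epochs, >= 1.
#' @param val_fraction Validation share of the split (default 0.2).
#' @param standardize Z-score features with training-split statistics
#'   before fitting (recommended with a random-weight backbone).
#' @param seed Seed controlling split, shuffling, and dropout masks.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, dropout = 0.2,
                         batch_size = 32, epochs = 25, val_fraction = 0.2,
                         standardize = TRUE, seed = 1L) {
  if (learning_rate <= 0) abort("learning_rate must be positive.")
  if (dropout < 0 || dropout >= 1) abort("dropout must be in [0, 1).")
  if (epochs < 1) abort("epochs must be >= 1.")
  structure(list(learning_rate = learning_rate, dropout = dropout,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 val_fraction = val_fraction,
                 standardize = isTRUE(standardize),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Train the dense classifier head
#'
#' Fits the single dense layer on top of pooled deep-spectrum features:
#' one logit per image, binary cross-entropy loss, Adam optimizer, the
#' backbone untouched (only the 1280 weights + 1 bias = 1281 parameters
#' train). Class coding follows the sign convention: positive logits
#' predict class 1 (control), negative class 0 (tinnitus).
#'
#' @param features A [feature_set()] tibble or a numeric matrix
#'   (rows = instances).
#' @param labels Integer 0 (tinnitus) / 1 (control) per row. If missing
#'   and `features` has a `group` column, derived from it.
#' @param cfg A [train_config()].
#' @return A `classifier_head`: `weights`, `bias`, `trained`, `history`
#'   (tibble with per-epoch `train_acc`, `val_acc`), plus the
#'   standardization statistics used.
#' @export
train_head <- function(features, labels = NULL, cfg = train_config()) {
  X <- if (is.matrix(features)) features else feature_matrix(features)
  if (is.null(labels)) {
    if (is.null(features$group)) abort("supply `labels` or a `group` column.")
    labels <- as.integer(features$group == "control")
  }
  y <- as.integer(labels)
  if (nrow(X) == 0) abort("empty training input.")
  if (length(unique(y)) < 2) abort("both classes must be present.")

  with_seed(cfg$seed, {
    # stratified split
    val_idx <- unlist(lapply(unique(y), function(cl) {
      i <- which(y == cl)
      sample(i, max(1L, round(cfg$val_fraction * length(i))))
    }))
    tr_idx <- setdiff(seq_len(nrow(X)), val_idx)

    mu <- if (cfg$standardize) colMeans(X[tr_idx, , drop = FALSE]) else 0
    sg <- if (cfg$standardize) {
      s <- apply(X[tr_idx, , drop = FALSE], 2, sd)
      ifelse(s < 1e-12, 1, s)
    } else 1
    Z <- sweep(sweep(X, 2, mu), 2, sg, "/")

    d <- ncol(Z)
    w <- numeric(d); b <- 0
    mw <- vw <- numeric(d); mb <- vb <- 0
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t <- 0
    hist <- vector("list", cfg$epochs)
    acc <- function(idx) {
      mean((as.numeric(Z[idx, , drop = FALSE] %*% w + b) > 0) == (y[idx] == 1))
    }
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(tr_idx)
      for (start in seq(1, length(ord), by = cfg$batch_size)) {
        bi <- ord[start:min(start + cfg$batch_size - 1, length(ord))]
        Zb <- Z[bi, , drop = FALSE]
        if (cfg$dropout > 0) {
          mask <- matrix(stats::rbinom(length(Zb), 1, 1 - cfg$dropout),
                         nrow(Zb)) / (1 - cfg$dropout)
          Zb <- Zb * mask
        }
        z <- as.numeric(Zb %*% w + b)
        pr <- 1 / (1 + exp(-z))
        g <- pr - y[bi]                       # d(BCE)/d(logit)
        gw <- as.numeric(crossprod(Zb, g)) / length(bi)
        gb <- mean(g)
        t <- t + 1
        mw <- beta1 * mw + (1 - beta1) * gw; vw <- beta2 * vw + (1 - beta2) * gw^2
        mb <- beta1 * mb + (1 - beta1) * gb; vb <- beta2 * vb + (1 - beta2) * gb^2
        w <- w - cfg$learning_rate * (mw / (1 - beta1^t)) /
          (sqrt(vw / (1 - beta2^t)) + eps)
        b <- b - cfg$learning_rate * (mb / (1 - beta1^t)) /
          (sqrt(vb / (1 - beta2^t)) + eps)
      }
      hist[[ep]] <- tibble(epoch = ep, train_acc = acc(tr_idx),
                           val_acc = acc(val_idx))
    }
    structure(
      list(weights = w, bias = b, trained = TRUE,
           history = dplyr::bind_rows(hist),
           mu = mu, sigma = sg, cfg = cfg,
           n_parameters = d + 1L),
      class = "classifier_head")
  })
}

#' @export
print.classifier_head <- function(x, ...) {
  last <- tail(x$history, 1)
  cat(sprintf("<classifier_head> %d parameters, %d epochs; final train %.3f / val %.3f\n",
              x$n_parameters, nrow(x$history), last$train_acc, last$val_acc))
  invisible(x)
}

#' Predict from a trained head
#'
#' @param object A trained `classifier_head`.
#' @param newdata Feature vector, matrix, or [feature_set()] tibble.
#' @param ... Ignored.
#' @return A tibble with `logit` and `class` (1 = control iff logit > 0,
#'   else 0 = tinnitus).
#' @export
predict.classifier_head <- function(object, newdata, ...) {
  if (!isTRUE(object$trained)) abort("head is not trained.")
  X <- if (is.matrix(newdata)) newdata
  else if (is.numeric(newdata)) matrix(newdata, nrow = 1)
  else feature_matrix(newdata)
  Z <- sweep(sweep(X, 2, object$mu), 2, object$sigma, "/")
  logit <- as.numeric(Z %*% object$weights + object$bias)
  tibble(logit = logit, class = as.integer(logit > 0))
}

#' @exportS3Method generics::tidy
tidy.classifier_head <- function(x, ...) {
  tibble(term = c(sprintf("f%04d", seq_along(x$weights)), "(bias)"),
         estimate = c(x$weights, x$bias))
}

#' @exportS3Method generics::glance
glance.classifier_head <- function(x, ...) {
  last <- tail(x$history, 1)
  tibble(n_parameters = x$n_parameters, epochs = nrow(x$history),
         train_accuracy = last$train_acc, val_accuracy = last$val_acc)
}
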