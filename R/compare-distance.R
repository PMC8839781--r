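#' Centroid of a group/session cell
#'
#' Coordinate-wise mean of the deep-spectrum vectors of one cell:
#' `C_i = (1/p) * sum_j x_ij` over the cell's p scalograms.
#'
#' @param features A [feature_set()].
#' @param group,session Optional filters selecting the cell; `NULL` keeps
#'   all rows.
#' @return A `centroid`: list with `C` (numeric vector), `group`,
#'   `session`, `p` (instances used).
#' @export
centroid <- function(features, group = NULL, session = NULL) {
  sel <- rep(TRUE, nrow(features))
  if (!is.null(group)) sel <- sel & features$group == group
  if (!is.null(session)) sel <- sel & features$session == session
  X <- feature_matrix(features[sel, ])
  if (nrow(X) == 0) {
    abort(sprintf("no instances in cell %s %s.",
                  group %||% "*", session %||% "*"))
  }
  structure(list(C = colMeans(X), group = group, session = session,
                 p = nrow(X)),
            class = "centroid")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Euclidean distances to a reference centroid
#'
#' Per-instance Euclidean distance `D_u = ||x_u - C||`, summarized by the
#' mean and the *population* standard deviation (denominator N, not
#' N - 1), matching the distance-summary convention of the comparison
#' analysis.
#'
#' @param features A [feature_set()] (or numeric matrix of instances).
#' @param ref A [centroid()] (or numeric vector) of matching dimension.
#' @return A list: `distances`, `mean`, `sd` (population), `n`.
#' @export
distance_summary <- function(features, ref) {
  X <- if (is.matrix(features)) features else feature_matrix(features)
  C <- if (inherits(ref, "centroid")) ref$C else as.numeric(ref)
  if (ncol(X) != length(C)) {
    abort(sprintf("dimension mismatch: instances have %d coordinates, centroid %d.",
                  ncol(X), length(C)))
  }
  D <- sqrt(rowSums(sweep(X, 2, C)^2))
  m <- mean(D)
  list(distances = D, mean = m,
       sd = sqrt(mean((D - m)^2)),   # population form, denominator N
       n = length(D))
}

#' Instance-to-centroid distance table
#'
#' The five pairings of the closeness analysis — each row summarizes the
#' Euclidean distances from the first cell's instances to the second
#' cell's centroid: Tinnitus S1/S2 against the Control S1 and S2
#' centroids, plus Control S1 against the Control S2 centroid. A
#' shrinking Tinnitus-S2-to-control distance relative to Tinnitus S1 is
#' the signature of post-treatment convergence toward the control group.
#'
#' @param features A [feature_set()] with all four cells.
#' @param per_subject Split the tinnitus rows by subject (the study
#'   reports one column per patient).
#' @return A tibble with `pairing` (and optionally `subject`),
#'   `mean`, `sd`, `n`.
#' @export
distance_table <- function(features, per_subject = FALSE) {
  pairings <- list(
    c("tinnitus", "S1", "control", "S1"),
    c("tinnitus", "S2", "control", "S1"),
    c("tinnitus", "S1", "control", "S2"),
    c("tinnitus", "S2", "control", "S2"),
    c("control", "S1", "control", "S2"))
  purrr::map_dfr(pairings, function(pr) {
    inst <- features[features$group == pr[1] & features$session == pr[2], ]
    if (nrow(inst) == 0) {
      abort(sprintf("empty cell: %s %s.", pr[1], pr[2]))
    }
    ref <- centroid(features, group = pr[3], session = pr[4])
    label <- sprintf("%s %s—%s %s", tools::toTitleCase(pr[1]), pr[2],
                     tools::toTitleCase(pr[3]), pr[4])
    if (per_subject && pr[1] == "tinnitus") {
      purrr::map_dfr(sort(unique(inst$subject)), function(sj) {
        ds <- distance_summary(inst[inst$subject == sj, ], ref)
        tibble(pairing = label, subject = as.character(sj),
               mean = ds$mean, sd = ds$sd, n = ds$n)
      })
    } else {
      ds <- distance_summary(inst, ref)
      out <- tibble(pairing = label, mean = ds$mean, sd = ds$sd, n = ds$n)
      if (per_subject) out <- dplyr::mutate(out, subject = "all", .after = 1)
      out
    }
  })
}

#' Five-number summaries per group/session cell
#'
#' Min, lower quartile, median, upper quartile, and max of the scalar
#' outcome in each of the four cells (T-S1, T-S2, C-S1, C-S2), with the
#' linear-interpolation quartile rule (`stats::quantile` type 7).
#'
#' @param features A [feature_set()].
#' @param outcome Passed to [scalar_outcome()].
#' @return A tibble with `cell`, `min`, `q1`, `median`, `q3`, `max`, `n`.
#' @export
boxplot_summary <- function(features, outcome = "mean_of_features") {
  features <- scalar_outcome(features, outcome)
  cells <- cell_split(features)
  order <- c("tinnitus.S1", "tinnitus.S2", "control.S1", "control.S2")
  short <- c(tinnitus.S1 = "T-S1", tinnitus.S2 = "T-S2",
             control.S1 = "C-S1", control.S2 = "C-S2")
  purrr::map_dfr(intersect(order, names(cells)), function(key) {
    y <- cells[[key]]
    q <- quantile(y, c(0, 0.25, 0.5, 0.75, 1), type = 7, names = FALSE)
    tibble(cell = unname(short[key]), min = q[1], q1 = q[2], median = q[3],
           q3 = q[4], max = q[5], n = length(y))
  })
}

#' Box plots of the scalar outcome per cell
#'
#' @inheritParams boxplot_summary
#' @return A ggplot object.
#' @export
plot_cell_boxplots <- function(features, outcome = "mean_of_features") {
  features <- scalar_outcome(features, outcome)
  df <- tibble(
    cell = factor(paste0(ifelse(features$group == "tinnitus", "T-", "C-"),
                         features$session),
                  levels = c("T-S1", "T-S2", "C-S1", "C-S2")),
    Y = features$Y)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cell, y = .data$Y)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(x = NULL, y = "scalar outcome") +
    ggplot2::theme_minimal()
}
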