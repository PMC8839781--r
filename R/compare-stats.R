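#' Per-instance scalar outcome
#'
#' The t-test matrices and the difference-in-differences estimator operate
#' on one scalar per scalogram. The default collapses each deep-spectrum
#' vector to the mean of its components; alternatives are the Euclidean
#' distance to a reference centroid, or a single named feature.
#'
#' @param features A [feature_set()] tibble.
#' @param method `"mean_of_features"`, `"distance_to_centroid"`, or
#'   `"feature"`.
#' @param ref_group,ref_session Reference cell for
#'   `"distance_to_centroid"`.
#' @param feature Column name for `method = "feature"`.
#' @return The input tibble with an added numeric column `Y` and an
#'   attribute `outcome_method` recording the choice.
#' @export
scalar_outcome <- function(features,
                           method = c("mean_of_features",
                                      "distance_to_centroid", "feature"),
                           ref_group = "control", ref_session = "S1",
                           feature = NULL) {
  method <- match.arg(method)
  if (nrow(features) == 0) abort("empty feature set.")
  X <- feature_matrix(features)
  Y <- switch(method,
    mean_of_features = rowMeans(X),
    distance_to_centroid = {
      ref <- centroid(features, group = ref_group, session = ref_session)
      sqrt(rowSums(sweep(X, 2, ref$C)^2))
    },
    feature = {
      if (is.null(feature) || !feature %in% colnames(X)) {
        abort("`feature` must name a feature column.")
      }
      X[, feature]
    })
  features$Y <- Y
  attr(features, "outcome_method") <- method
  features
}

.lillie_cache <- new.env(parent = emptyenv())

#' Lilliefors normality test
#'
#' Kolmogorov-Smirnov-type test with estimated mean and SD: the statistic
#' is the maximum absolute deviation between the sample ECDF and the
#' normal CDF fitted by `mean(x)` and `sd(x)`. Because the null
#' distribution with estimated parameters has no closed form, the p-value
#' comes from a seeded Monte-Carlo null table (10^4 standard-normal
#' samples of the same n, cached per n within the session).
#'
#' @param x Numeric sample, n >= 4.
#' @param n_mc Monte-Carlo draws for the null table.
#' @return A list with `statistic`, `p_value`, `n`.
#' @export
lilliefors_test <- function(x, n_mc = 1e4) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 4) abort("Lilliefors test needs n >= 4.")
  stat <- lilliefors_stat(x)
  key <- sprintf("n%d_b%d", n, as.integer(n_mc))
  if (is.null(.lillie_cache[[key]])) {
    .lillie_cache[[key]] <- with_seed(derive_seed(190667L, key), {
      vapply(seq_len(n_mc), function(i) lilliefors_stat(rnorm(n)), 0)
    })
  }
  null <- .lillie_cache[[key]]
  p <- (1 + sum(null >= stat)) / (length(null) + 1)
  list(statistic = stat, p_value = p, n = n)
}

lilliefors_stat <- function(x) {
  n <- length(x)
  z <- sort(pnorm(x, mean(x), sd(x)))
  i <- seq_len(n)
  max(i / n - z, z - (i - 1) / n)
}

#' Student's t-test with the +/- significance coding
#'
#' Two-sample pooled-variance Student's t-test whose result carries the
#' sign code used throughout the comparison tables: `"+"` for p > 0.05
#' (statistically significant *relationship* between the two datasets),
#' `"-"` for p < 0.05 (significant *difference*). Welch's correction is
#' available as an option.
#'
#' @param a,b Numeric samples, each n >= 2.
#' @param alpha Significance level for the coding (default 0.05).
#' @param var_equal Pooled variance (Student, default) or Welch.
#' @return A list with `t`, `p_value`, `code`.
#' @export
coded_t_test <- function(a, b, alpha = 0.05, var_equal = TRUE) {
  if (length(a) < 2 || length(b) < 2) abort("each sample needs n >= 2.")
  if (sd(a) < 1e-300 && sd(b) < 1e-300) {
    # degenerate: no variance anywhere
    if (abs(mean(a) - mean(b)) < 1e-300) {
      return(list(t = 0, p_value = 1, code = "+"))
    }
    return(list(t = Inf * sign(mean(a) - mean(b)), p_value = 0, code = "-"))
  }
  tt <- stats::t.test(a, b, var.equal = var_equal)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       code = if (tt$p.value > alpha) "+" else "-")
}

cell_split <- function(features) {
  split(features$Y, paste(features$group, features$session, sep = "."))
}

#' Pairwise group/session comparison matrix
#'
#' Runs the Student's t-test over the study's group-session pairings on
#' the per-instance scalar outcome. The `within` design emits the six
#' cohort-level comparisons (tinnitus/control crossed over sessions plus
#' the two within-group session contrasts); the `between` design compares
#' each tinnitus subject's scalograms against the pooled control
#' scalograms (and that subject's own sessions), five comparisons per
#' subject. Each cell is screened with the Lilliefors test; its p-value is
#' reported alongside.
#'
#' @param features A [feature_set()] with all four group x session cells.
#' @param design `"within"` or `"between"`.
#' @param outcome Passed to [scalar_outcome()].
#' @param alpha Significance level for the +/- coding.
#' @return A tibble with one row per comparison: `comparison` (and
#'   `subject` for the between design), `n_a`, `n_b`, `t`, `p_value`,
#'   `code`.
#' @export
comparison_matrix <- function(features, design = c("within", "between"),
                              outcome = "mean_of_features", alpha = 0.05) {
  design <- match.arg(design)
  features <- scalar_outcome(features, outcome)
  cells <- cell_split(features)
  need <- c("tinnitus.S1", "tinnitus.S2", "control.S1", "control.S2")
  missing <- setdiff(need, names(cells))
  if (length(missing)) {
    abort(sprintf("empty group/session cell(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  if (any(lengths(cells[need]) < 2)) {
    small <- need[lengths(cells[need]) < 2]
    abort(sprintf("cell(s) with fewer than 2 instances: %s.",
                  paste(small, collapse = ", ")))
  }

  run_pairs <- function(pairs, getter) {
    purrr::map_dfr(pairs, function(pr) {
      a <- getter(pr[1]); b <- getter(pr[2])
      res <- coded_t_test(a, b, alpha = alpha)
      tibble(comparison = paste(pretty_cell(pr[1]), pretty_cell(pr[2]),
                                sep = "–"),
             n_a = length(a), n_b = length(b),
             t = res$t, p_value = res$p_value, code = res$code)
    })
  }

  if (design == "within") {
    pairs <- list(c("tinnitus.S1", "control.S1"),
                  c("tinnitus.S1", "control.S2"),
                  c("tinnitus.S2", "control.S1"),
                  c("tinnitus.S2", "control.S2"),
                  c("tinnitus.S1", "tinnitus.S2"),
                  c("control.S1", "control.S2"))
    out <- run_pairs(pairs, function(key) cells[[key]])
  } else {
    subjects <- sort(unique(features$subject[features$group == "tinnitus"]))
    out <- purrr::map_dfr(subjects, function(sj) {
      getter <- function(key) {
        gs <- strsplit(key, ".", fixed = TRUE)[[1]]
        sel <- features$group == gs[1] & features$session == gs[2]
        if (gs[1] == "tinnitus") sel <- sel & features$subject == sj
        y <- features$Y[sel]
        if (length(y) < 2) {
          abort(sprintf("subject %s: cell %s has fewer than 2 instances.",
                        sj, key))
        }
        y
      }
      pairs <- list(c("tinnitus.S1", "control.S1"),
                    c("tinnitus.S1", "control.S2"),
                    c("tinnitus.S2", "control.S1"),
                    c("tinnitus.S2", "control.S2"),
                    c("tinnitus.S1", "tinnitus.S2"))
      dplyr::mutate(run_pairs(pairs, getter), subject = sj, .before = 1)
    })
  }
  attr(out, "alpha") <- alpha
  attr(out, "outcome_method") <- outcome
  out
}

pretty_cell <- function(key) {
  gs <- strsplit(key, ".", fixed = TRUE)[[1]]
  paste(tools::toTitleCase(gs[1]), gs[2])
}

#' Normality screen per group/session cell
#'
#' @param features A [feature_set()].
#' @param outcome Passed to [scalar_outcome()].
#' @return A tibble with per-cell Lilliefors statistic and p-value.
#' @export
normality_screen <- function(features, outcome = "mean_of_features") {
  features <- scalar_outcome(features, outcome)
  purrr::imap_dfr(cell_split(features), function(y, key) {
    lt <- lilliefors_test(y)
    tibble(cell = pretty_cell(key), n = lt$n,
           statistic = lt$statistic, p_value = lt$p_value)
  })
}
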