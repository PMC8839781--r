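#' Difference-in-differences treatment-effect estimator
#'
#' Fits `Y = b0 + b1*Time + b2*Intervention + b3*(Time x Intervention) + e`
#' by ordinary least squares, where `Time` is 0 for the pre-treatment
#' session (S1) and 1 post (S2), and `Intervention` is 0 for controls and
#' 1 for the tinnitus (treated) group. `b0` is the baseline average, `b1`
#' the time trend in controls, `b2` the pre-intervention group difference,
#' and `b3` — the DID estimator — the difference in changes over time,
#' identical to the closed form
#' `(mean_T,S2 - mean_T,S1) - (mean_C,S2 - mean_C,S1)`. A positive `b3` is
#' labeled a positive treatment effect.
#'
#' @param y Numeric outcome per instance.
#' @param time 0 (S1) / 1 (S2) per instance.
#' @param group 0 (control) / 1 (tinnitus) per instance.
#' @return A `did_result`: coefficients `beta0..beta3`, `effect`
#'   (`"Positive effect"`/`"Negative effect"`), cell means, and the
#'   underlying `lm` fit.
#' @export
#' @examples
#' r <- did_estimate(c(0, 0, .5, .5, 1, 1, 2, 2),
#'                   time = c(0, 0, 1, 1, 0, 0, 1, 1),
#'                   group = c(0, 0, 0, 0, 1, 1, 1, 1))
#' tidy(r)
did_estimate <- function(y, time, group) {
  time <- as.numeric(time); group <- as.numeric(group)
  if (!all(time %in% c(0, 1)) || !all(group %in% c(0, 1))) {
    abort("`time` and `group` must be 0/1 indicators.")
  }
  cells <- table(time, group)
  if (length(cells) < 4 || any(cells == 0)) {
    abort("all four time x group cells must be non-empty.")
  }
  fit <- lm(y ~ time + group + time:group)
  beta <- coef(fit)
  if (anyNA(beta)) abort("degenerate (collinear) design.")
  means <- tapply(y, list(time = time, group = group), mean)
  b3 <- unname(beta["time:group"])
  structure(
    list(beta0 = unname(beta["(Intercept)"]),
         beta1 = unname(beta["time"]),
         beta2 = unname(beta["group"]),
         beta3 = b3,
         effect = if (b3 > 0) "Positive effect" else "Negative effect",
         cell_means = means, n = length(y), fit = fit),
    class = "did_result")
}

#' @export
print.did_result <- function(x, ...) {
  cat(sprintf("<did_result> DID estimator b3 = %.4f (%s); b0 = %.4f, b1 = %.4f, b2 = %.4f, n = %d\n",
              x$beta3, x$effect, x$beta0, x$beta1, x$beta2, x$n))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.did_result <- function(x, ...) {
  tibble(term = c("beta0 (baseline)", "beta1 (time trend, control)",
                  "beta2 (pre-intervention gap)", "beta3 (DID)"),
         estimate = c(x$beta0, x$beta1, x$beta2, x$beta3))
}

#' @exportS3Method generics::glance
glance.did_result <- function(x, ...) {
  tibble(did = x$beta3, effect = x$effect, n = x$n)
}

#' DID table over a feature set
#'
#' Mirrors the study's DID summary: one estimator per tinnitus subject
#' (that subject's scalograms versus all controls) plus a pooled
#' all-patients row, each with its qualitative effect label.
#'
#' @param features A [feature_set()] with all four group x session cells.
#' @param outcome Passed to [scalar_outcome()].
#' @return A tibble with `subject`, `did`, `effect`.
#' @export
did_table <- function(features, outcome = "mean_of_features") {
  features <- scalar_outcome(features, outcome)
  ctrl <- features[features$group == "control", ]
  tins <- features[features$group == "tinnitus", ]
  if (nrow(ctrl) == 0 || nrow(tins) == 0) abort("both groups required.")
  one <- function(sub) {
    d <- rbind(if (is.null(sub)) tins else tins[tins$subject == sub, ], ctrl)
    r <- did_estimate(d$Y, as.numeric(d$session == "S2"),
                      as.numeric(d$group == "tinnitus"))
    tibble(subject = if (is.null(sub)) "All tinnitus patients" else sub,
           did = r$beta3, effect = r$effect)
  }
  subs <- sort(unique(tins$subject))
  dplyr::bind_rows(c(purrr::map(subs, one), list(one(NULL))))
}
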