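test_that("scalar outcome defaults to the feature mean and is linear", {
  fs <- feature_set(matrix(1, 3, 8), "s", "tinnitus", "S1")
  expect_equal(scalar_outcome(fs)$Y, rep(1, 3))
  withr::with_seed(3, X <- matrix(rnorm(5 * 32), 5))
  f1 <- feature_set(X, "s", "control", "S1")
  f2 <- feature_set(X + 2.5, "s", "control", "S1")
  expect_equal(scalar_outcome(f2)$Y, scalar_outcome(f1)$Y + 2.5)
  oracle <- vapply(1:5, function(i) sum(X[i, ]) / 32, 0)
  expect_lt(max(abs(scalar_outcome(f1)$Y - oracle)), 1e-12)
  expect_error(scalar_outcome(f1, "nope"))
  # named-feature and distance outcomes
  expect_equal(scalar_outcome(f1, "feature", feature = "f0002")$Y, X[, 2])
  d <- scalar_outcome(f1, "distance_to_centroid", ref_group = "control",
                      ref_session = "S1")$Y
  expect_equal(d, sqrt(rowSums(sweep(X, 2, colMeans(X))^2)))
})

test_that("Lilliefors statistic matches a hand-rolled ECDF computation", {
  x <- c(1, 2, 3, 4, 5)
  z <- pnorm(sort(x), mean(x), sd(x))
  manual <- max(pmax((1:5) / 5 - z, z - (0:4) / 5))
  res <- lilliefors_test(x)
  expect_lt(abs(res$statistic - manual), 1e-10)
  expect_error(lilliefors_test(c(1, 2, 3)), "n >= 4")
})

test_that("Lilliefors statistic agrees with the nortest implementation", {
  withr::with_seed(7, x <- rexp(40))
  expect_equal(lilliefors_test(x)$statistic,
               unname(nortest::lillie.test(x)$statistic), tolerance = 1e-10)
})

test_that("Lilliefors Monte-Carlo p-values reject non-normal data and hold the level", {
  withr::with_seed(11, u <- runif(1000))
  expect_lt(lilliefors_test(u)$p_value, 0.05)
  # empirical type-I rate at alpha = 0.05 for n = 50 normals
  rejections <- withr::with_seed(13, {
    vapply(1:1000, function(i) {
      lilliefors_test(rnorm(50))$p_value < 0.05
    }, TRUE)
  })
  expect_gte(mean(rejections), 0.03)
  expect_lte(mean(rejections), 0.07)
})

test_that("coded t-test follows the +/- convention of the comparison tables", {
  a <- c(1, 2, 3)
  same <- coded_t_test(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  expect_equal(same$code, "+")

  far <- coded_t_test(a, c(101, 102, 103))
  expect_lt(far$p_value, 1e-6)
  expect_equal(far$code, "-")
  # closed-form check: pooled t with 4 df
  sp <- sqrt((2 * var(a) + 2 * var(c(101, 102, 103))) / 4)
  expect_equal(far$t, (mean(a) - 102) / (sp * sqrt(2 / 3)), tolerance = 1e-12)

  swap <- coded_t_test(c(101, 102, 103), a)
  expect_equal(swap$t, -far$t)
  expect_equal(swap$p_value, far$p_value)

  flat <- coded_t_test(c(2, 2), c(2, 2))
  expect_equal(flat$p_value, 1)
  expect_error(coded_t_test(1, a), "n >= 2")
})

test_that("within-design matrix emits the six study pairings and detects shifts", {
  feats <- simulate_feature_cohort(n_per_cell = 25, seed = 19)
  cm <- comparison_matrix(feats, "within")
  expect_equal(nrow(cm), 6)
  expect_equal(cm$comparison[1], "Tinnitus S1–Control S1")
  expect_equal(cm$comparison[6], "Control S1–Control S2")
  expect_true(all(cm$code %in% c("+", "-")))

  # shift both tinnitus cells far away: all tinnitus-vs-control rows flag "-"
  shifted <- feats
  fc <- feature_cols(shifted)
  tin <- shifted$group == "tinnitus"
  shifted[tin, fc] <- shifted[tin, fc] + 10
  cs <- comparison_matrix(shifted, "within")
  expect_equal(cs$code[1:4], rep("-", 4))
  expect_equal(cs$code[5], "+")             # tinnitus S1 vs S2 unshifted pair
})

test_that("between-design matrix compares each tinnitus subject to pooled controls", {
  feats <- simulate_feature_cohort(n_per_cell = 20, seed = 23)
  cm <- comparison_matrix(feats, "between")
  subs <- unique(feats$subject[feats$group == "tinnitus"])
  expect_equal(nrow(cm), 5 * length(subs))
  expect_equal(unique(table(cm$subject)), 5L)
  # control sample sizes pool the whole control cell
  expect_true(all(cm$n_b[grepl("Control", cm$comparison)] == 20))
})

test_that("missing or degenerate cells raise explicit errors", {
  feats <- simulate_feature_cohort(n_per_cell = 10, seed = 29)
  expect_error(comparison_matrix(feats[feats$group != "control", ], "within"),
               "control")
  one <- dplyr::bind_rows(
    feats[feats$group == "control", ],
    feats[feats$group == "tinnitus" & feats$session == "S2", ],
    feats[feats$group == "tinnitus" & feats$session == "S1", ][1, ])
  expect_error(comparison_matrix(one, "within"), "fewer than 2")
})

test_that("DID coefficients reproduce the closed-form cell-mean arithmetic", {
  # cell means: C,S1 = 0; C,S2 = 0.5; T,S1 = 1.0; T,S2 = 2.0
  mk <- function(m, t, g, n = 4) {
    tibble::tibble(y = m + seq(-0.3, 0.3, length.out = n), time = t, group = g)
  }
  d <- dplyr::bind_rows(mk(0, 0, 0), mk(0.5, 1, 0), mk(1, 0, 1), mk(2, 1, 1))
  r <- did_estimate(d$y, d$time, d$group)
  expect_equal(r$beta0, 0, tolerance = 1e-12)
  expect_equal(r$beta1, 0.5, tolerance = 1e-12)
  expect_equal(r$beta2, 1.0, tolerance = 1e-12)
  expect_equal(r$beta3, 0.5, tolerance = 1e-12)
  expect_equal(r$effect, "Positive effect")
  expect_equal(glance(r)$did, 0.5, tolerance = 1e-12)
  expect_equal(nrow(tidy(r)), 4)
})

test_that("effect labels follow the sign of the DID estimator", {
  mk <- function(shift) {
    d <- simulate_feature_cohort(n_per_cell = 40, dim = 4, delta = shift,
                                 sd = 1e-6, seed = 31)
    d <- scalar_outcome(d)
    did_estimate(d$Y, as.numeric(d$session == "S2"),
                 as.numeric(d$group == "tinnitus"))
  }
  pos <- mk(0.0327)
  expect_equal(pos$beta3, 0.0327, tolerance = 1e-3)
  expect_equal(pos$effect, "Positive effect")
  neg <- mk(-0.0018)
  expect_equal(neg$beta3, -0.0018, tolerance = 1e-3)
  expect_equal(neg$effect, "Negative effect")
})

test_that("DID validates its design matrix", {
  expect_error(did_estimate(1:4, c(0, 0, 1, 1), c(0, 0, 0, 0)), "non-empty")
  expect_error(did_estimate(1:4, c(0, 0, 0.5, 1), c(0, 1, 0, 1)), "indicators")
})

test_that("did_table reports one row per tinnitus subject plus the pooled cohort", {
  feats <- simulate_feature_cohort(n_per_cell = 100, delta = 0.4, sd = 0.2,
                                   seed = 37)
  tb <- did_table(feats)
  expect_equal(nrow(tb), 3)                  # two subjects + pooled row
  expect_equal(tb$subject[3], "All tinnitus patients")
  expect_true(all(tb$effect[tb$did > 0] == "Positive effect"))
  expect_equal(tb$did[3], 0.4, tolerance = 0.2)
})

test_that("centroids are coordinate-wise means", {
  fs <- feature_set(rbind(c(0, 0), c(2, 2)), "s", "control", "S1")
  expect_equal(centroid(fs)$C, c(f0001 = 1, f0002 = 1))
  one <- feature_set(rbind(c(3, 7)), "s", "tinnitus", "S2")
  expect_equal(unname(centroid(one)$C), c(3, 7))
  withr::with_seed(41, X <- matrix(rnorm(100 * 12), 100))
  f <- feature_set(X, "s", "control", "S2")
  oracle <- vapply(1:12, function(j) {
    s <- 0
    for (i in 1:100) s <- s + X[i, j]
    s / 100
  }, 0)
  expect_lt(max(abs(centroid(f)$C - oracle)), 1e-12)
  expect_equal(centroid(f)$p, 100)
  expect_error(centroid(f, group = "tinnitus"), "no instances")
})

test_that("distance summaries use Euclidean distance and the population SD", {
  fs <- feature_set(rbind(c(3, 4)), "s", "tinnitus", "S1")
  ds <- distance_summary(fs, c(0, 0))
  expect_equal(ds$distances, 5)
  ds0 <- distance_summary(matrix(c(1, 2), 1), c(1, 2))
  expect_equal(ds0$distances, 0)
  # distances {1, 3}: mean 2, population SD 1 (denominator N)
  m <- matrix(c(1, 3), 2, 1)
  ds2 <- distance_summary(m, 0)
  expect_equal(ds2$mean, 2)
  expect_equal(ds2$sd, 1)
  expect_lt(ds2$sd, sd(ds2$distances))       # strictly below the N-1 form
  expect_error(distance_summary(m, c(0, 0)), "dimension")
})

test_that("distance summaries are translation-invariant and scale linearly", {
  withr::with_seed(43, {
    X <- matrix(rnorm(30 * 6), 30)
    shift <- rnorm(6)
  })
  C <- colMeans(X)
  a <- distance_summary(X, C)
  b <- distance_summary(sweep(X, 2, -shift), C + shift)
  expect_equal(a$distances, b$distances, tolerance = 1e-10)
  sc <- distance_summary(3 * X, 3 * C)
  expect_equal(sc$distances, 3 * a$distances, tolerance = 1e-10)
  expect_equal(sc$sd, 3 * a$sd, tolerance = 1e-10)
})

test_that("distance table covers the five pairings against control centroids", {
  feats <- simulate_feature_cohort(n_per_cell = 15, seed = 47)
  tb <- distance_table(feats)
  expect_equal(nrow(tb), 5)
  expect_equal(tb$pairing[1], "Tinnitus S1—Control S1")
  expect_equal(tb$pairing[5], "Control S1—Control S2")
  expect_true(all(tb$mean >= 0) && all(tb$sd >= 0))

  # all cells identical point masses: every distance is zero
  pm <- feature_set(matrix(1, 40, 3),
                    subject = "s",
                    group = rep(c("tinnitus", "control"), each = 20),
                    session = rep(c("S1", "S2"), 20))
  expect_equal(distance_table(pm)$mean, rep(0, 5))

  # constructed convergence: tinnitus S2 sits nearer the control centroid
  conv <- feats
  fc <- feature_cols(conv)
  ts2 <- conv$group == "tinnitus" & conv$session == "S2"
  ts1 <- conv$group == "tinnitus" & conv$session == "S1"
  conv[ts1, fc] <- conv[ts1, fc] + 5
  tbc <- distance_table(conv)
  expect_lt(tbc$mean[tbc$pairing == "Tinnitus S2—Control S1"],
            tbc$mean[tbc$pairing == "Tinnitus S1—Control S1"])
  expect_error(distance_table(feats[feats$session != "S2", ]), "empty cell")
})

test_that("box-plot summaries use linear-interpolation quartiles", {
  fs <- feature_set(matrix(c(1:5, rep(2, 5), rep(3, 5), rep(4, 5))),
                    subject = "s",
                    group = rep(c("tinnitus", "tinnitus", "control", "control"),
                                each = 5),
                    session = rep(c("S1", "S2", "S1", "S2"), each = 5))
  tb <- boxplot_summary(fs)
  expect_equal(tb$cell, c("T-S1", "T-S2", "C-S1", "C-S2"))
  expect_equal(tb$median[1], 3)
  expect_equal(tb$q1[1], 2)                  # type-7 quartile of 1..5
  expect_equal(tb$q3[1], 4)
  # degenerate constant cell collapses the box
  expect_equal(unlist(tb[2, c("min", "q1", "median", "q3", "max")]),
               rep(2, 5), ignore_attr = TRUE)
  # quartiles match a sort-and-interpolate oracle
  withr::with_seed(53, y <- rnorm(17))
  fs2 <- feature_set(matrix(rep(y, 4)), "s",
                     rep(c("tinnitus", "tinnitus", "control", "control"),
                         each = 17),
                     rep(c("S1", "S2", "S1", "S2"), each = 17))
  s <- sort(y)
  h <- (17 - 1) * 0.25 + 1
  oracle_q1 <- s[floor(h)] + (h - floor(h)) * (s[floor(h) + 1] - s[floor(h)])
  expect_equal(boxplot_summary(fs2)$q1[1], oracle_q1, tolerance = 1e-12)
  p <- plot_cell_boxplots(fs2)
  expect_s3_class(p, "ggplot")
})
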