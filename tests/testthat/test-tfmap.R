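test_that("epoch windows use exact half-open sample arithmetic at 256 Hz", {
  fs <- 256
  sig <- matrix(seq_len(fs * 20), 1)             # ramp encodes sample index
  rec <- eeg_recording(sig, fs, "Fz",
                       events = tibble::tibble(onset_s = 10, label = "k"))
  ep <- extract_epochs(rec)
  expect_equal(ncol(ep$epochs), 384)             # 128 pre + 256 post
  # first sample of the window is 0-based index 2432 -> 1-based 2433
  expect_equal(ep$epochs[1, 1], 2433)
  expect_equal(ep$epochs[1, 384], 2816)
  expect_equal(ep$t_axis[129], 0)                # t = 0 at the keypress sample
})

test_that("events too close to the edge or under a burst mask are dropped", {
  fs <- 256
  rec <- eeg_recording(matrix(rnorm(fs * 10), 1), fs, "Fz",
                       events = tibble::tibble(onset_s = c(0.1, 5, 9.9),
                                               label = c("a", "b", "c")))
  ep <- extract_epochs(rec)
  expect_equal(nrow(ep$epochs), 1)
  expect_equal(ep$n_dropped, 2)
  # a burst mask over the surviving event removes it too
  mask <- rep(FALSE, fs * 10); mask[5 * fs] <- TRUE
  attr(rec, "burst_mask") <- mask
  expect_error(extract_epochs(rec), "zero usable")
})

test_that("a full-protocol recording epochs into 250 windows", {
  cfg <- cohort_config(seed = 12)
  rec <- generate_recording(cfg, "control", "S1")$recording
  ep <- extract_epochs(rec)
  expect_equal(nrow(ep$epochs) + ep$n_dropped, 250)
  expect_equal(ep$n_dropped, 0)
})

test_that("complex Gaussian wavelet is unit-norm for p = 1..8", {
  for (p in 1:8) {
    w <- make_cgau_wavelet(p)
    expect_lt(abs(w$l2_norm - 1), 1e-6)
  }
  expect_error(make_cgau_wavelet(0), "positive integer")
  expect_error(make_cgau_wavelet(2.5), "positive integer")
})

test_that("wavelet derivative matches a finite-difference oracle", {
  w <- make_cgau_wavelet(1)
  x <- seq(-3, 3, length.out = 2001)
  h <- x[2] - x[1]
  f0 <- exp(-1i * x - x^2)
  fd <- (f0[3:2001] - f0[1:1999]) / (2 * h)      # derivative of the base
  expect_lt(max(Mod(w$C_p * fd - cgau_eval(w, x[2:2000]))), 1e-4)
})

test_that("wavelet parity follows differentiation: f^(p)(-x) = (-1)^p conj(f^(p)(x))", {
  x <- seq(0.1, 2.5, length.out = 40)
  for (p in c(1, 2, 5)) {
    w <- make_cgau_wavelet(p)
    lhs <- cgau_eval(w, -x)
    rhs <- (-1)^p * Conj(cgau_eval(w, x))
    expect_lt(max(Mod(lhs - rhs)), 1e-10)
  }
})

test_that("CWT is linear, nulls zero input, and peaks at the input frequency", {
  fs <- 256
  t <- (0:383) / fs
  w <- make_cgau_wavelet(4)
  fr <- analysis_freqs()
  x <- sin(2 * pi * 10 * t)
  W <- cwt_epoch(x, fr, w, fs)
  expect_equal(dim(W), c(384, 60))
  expect_lt(max(Mod(cwt_epoch(2 * x, fr, w, fs) - 2 * W)), 1e-10)
  expect_equal(max(Mod(cwt_epoch(rep(0, 384), fr, w, fs))), 0)
  for (f0 in c(5, 10, 25)) {
    Wf <- cwt_epoch(sin(2 * pi * f0 * t), fr, w, fs)
    expect_equal(which.max(colMeans(Mod(Wf))), which.min(abs(fr - f0)))
  }
  expect_error(cwt_epoch(x, numeric(), w, fs), "empty")
  expect_error(cwt_epoch(x, 500, w, fs), "fs/2")
})

test_that("CWT agrees with a direct-convolution oracle", {
  fs <- 256; n <- 384
  withr::with_seed(23, x <- rnorm(n))
  w <- make_cgau_wavelet(4)
  for (f in c(4, 10, 22)) {
    a <- w$center_frequency / f
    half <- ceiling(max(abs(w$x)) * a * fs)
    kern <- Conj(cgau_eval(w, ((-half:half) / fs) / a)) / fs / a
    pad <- min(half, n - 1L)
    xp <- c(x[(pad + 1):2], x, x[(n - 1):(n - pad)])
    oracle <- vapply(c(100, 192, 300), function(b) {
      idx <- b + pad + (-half:half)
      ok <- idx >= 1 & idx <= length(xp)
      sum(xp[idx[ok]] * kern[which(ok)])
    }, 0i)
    W <- cwt_epoch(x, f, w, fs)
    expect_lt(max(Mod(W[c(100, 192, 300)] - oracle)), 1e-10)
  }
})

test_that("time-averaged squared CWT magnitude scales quadratically with amplitude", {
  fs <- 256; t <- (0:383) / fs
  w <- make_cgau_wavelet(4)
  f0 <- 10
  amps <- c(1, 2, 4)
  pw <- vapply(amps, function(a) {
    mean(Mod(cwt_epoch(a * sin(2 * pi * f0 * t), f0, w, fs))^2)
  }, 0)
  slopes <- diff(log(pw)) / diff(log(amps))
  expect_true(all(abs(slopes - 2) < 0.05))
})

test_that("rectification modes agree on identical epochs and diverge under random phase", {
  fs <- 256; t <- (0:383) / fs
  w <- make_cgau_wavelet(4)
  fr <- c(8, 10, 12)
  W1 <- cwt_epoch(sin(2 * pi * 10 * t), fr, w, fs)
  same <- average_and_rectify(list(W1, W1, W1), fr, t)
  same2 <- average_and_rectify(list(W1, W1, W1), fr, t, "abs_then_average")
  expect_equal(same$P, same2$P, tolerance = 1e-12)
  single <- average_and_rectify(list(W1), fr, t)
  expect_equal(single$P, Mod(W1), ignore_attr = TRUE)

  # random phase: rectify-first keeps induced power, average-first cancels
  withr::with_seed(29, {
    coefs <- lapply(1:40, function(i) {
      cwt_epoch(sin(2 * pi * 10 * t + runif(1, 0, 2 * pi)), fr, w, fs)
    })
  })
  ata <- average_and_rectify(coefs, fr, t, "average_then_abs")
  aba <- average_and_rectify(coefs, fr, t, "abs_then_average")
  mid <- 100:284
  expect_gt(mean(aba$P[mid, 2]), 2 * mean(ata$P[mid, 2]))
  expect_error(average_and_rectify(list(W1, W1[1:10, ]), fr, t), "shape")
})

test_that("baseline correction subtracts the per-frequency reference mean", {
  # hand-computed toy: 3 time points x 2 frequencies, full-axis baseline
  P <- matrix(c(1, 2, 3, 10, 20, 30), 3, 2)
  m <- structure(list(P = P, freqs = c(1, 2), t_axis = c(-0.4, -0.2, 0.4),
                      corrected = FALSE, baseline = NULL, mode = "x",
                      n_epochs = 1), class = "tf_map")
  bc <- baseline_correct(m, window = c(-0.4, -0.2))
  expect_equal(bc$P, P - rep(c(1.5, 15), each = 3), ignore_attr = TRUE)
  expect_error(baseline_correct(bc), "already")

  # constant-in-time map corrects to identically zero
  mc <- structure(list(P = matrix(5, 10, 3), freqs = 1:3,
                       t_axis = seq(-0.5, 0.4, by = 0.1), corrected = FALSE,
                       baseline = NULL, mode = "x", n_epochs = 1),
                  class = "tf_map")
  expect_equal(max(abs(baseline_correct(mc)$P)), 0)

  # on a real map the baseline-window mean is zero per frequency
  fs <- 256; t <- (0:383 - 128) / fs
  w <- make_cgau_wavelet(4)
  withr::with_seed(31, x <- rnorm(384))
  W <- cwt_epoch(x, c(5, 10), w, fs)
  map <- baseline_correct(average_and_rectify(list(W), c(5, 10), t))
  s <- round(map$t_axis * fs)
  win <- s >= round(-0.4 * fs) & s <= round(-0.1 * fs)
  expect_equal(sum(win), 77)                     # samples -102..-26 inclusive
  expect_lt(max(abs(colMeans(map$P[win, ]))), 1e-9)
})

test_that("scalogram rendering is deterministic with the contracted sizes", {
  fs <- 256; t <- (0:99 - 30) / fs
  withr::with_seed(37, {
    m <- average_and_rectify(list(matrix(complex(real = rnorm(100 * 8),
                                                 imaginary = rnorm(100 * 8)),
                                         100, 8)),
                             freqs = seq(2, 30, length.out = 8), t_axis = t)
  })
  p1 <- file.path(tempdir(), "scal1.png")
  out <- render_scalogram(m, p1)
  big <- png::readPNG(out$canvas)
  expect_equal(dim(big), c(900, 1200, 3))
  small <- png::readPNG(out$resized)
  expect_equal(dim(small), c(160, 160, 3))
  meta <- jsonlite::read_json(out$meta)
  expect_equal(meta$colormap, "viridis")
  # byte-identical on re-render
  p2 <- file.path(tempdir(), "scal2.png")
  render_scalogram(m, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  # constant map renders a uniform color
  mc <- m; mc$P[] <- 3
  outc <- render_scalogram(mc, file.path(tempdir(), "scal3.png"))
  u <- png::readPNG(outc$canvas)
  expect_equal(length(unique(as.vector(u[, , 1]))), 1)
  mb <- m; mb$P[1, 1] <- NaN
  expect_error(render_scalogram(mb, tempfile(fileext = ".png")), "finite")
})

test_that("injected alpha ERS shows up in the corrected map where injected", {
  mk_map <- function(amp, seed) {
    cfg <- cohort_config(n_subjects_per_group = 1, n_stimuli = 1,
                         reps_per_stimulus = 8, isi_range = c(0.3, 0.8),
                         ers_bands = alpha_profile(amp), seed = seed)
    rec <- generate_recording(cfg, "tinnitus", "S1")$recording
    erd_map(extract_epochs(rec), freqs = analysis_freqs(30),
            mode = "abs_then_average")
  }
  eff <- mk_map(6, 41)
  null <- mk_map(0, 41)
  expect_gt(band_power(eff, c(8, 13), c(0, 0.5)),
            band_power(null, c(8, 13), c(0, 0.5)))
})
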