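# Small study-shaped configurations used across tests. Sizes are scaled
# down from the full protocol (5 stimuli x 50 repetitions) so suites stay
# fast; the full-size defaults are exercised where the test is about them.

tiny_cohort_config <- function(...) {
  cohort_config(n_subjects_per_group = 1, n_stimuli = 2, reps_per_stimulus = 3,
                isi_range = c(0.3, 0.8), ...)
}

# single-band profile helpers
alpha_profile <- function(amplitude = 5) {
  band <- data.frame(f_low = 8, f_high = 13, amplitude = amplitude,
                     onset = 0.05, duration = 0.5)
  list(tinnitus.S1 = band, tinnitus.S2 = band,
       control.S1 = band, control.S2 = band)
}

# synthetic deep-feature cohort at the feature level: four cells of
# Gaussian vectors; `delta` shifts the tinnitus post-treatment cell
# (added to every coordinate, so the mean-of-features outcome shifts by
# delta). Used by the DID-recovery and null-calibration checks.
simulate_feature_cohort <- function(n_per_cell = 30, dim = 8, delta = 0,
                                    sd = 1, seed = 1) {
  withr::with_seed(seed, {
    cells <- list(c("tinnitus", "S1", 0), c("tinnitus", "S2", delta),
                  c("control", "S1", 0), c("control", "S2", 0))
    dplyr::bind_rows(lapply(cells, function(cl) {
      X <- matrix(rnorm(n_per_cell * dim, sd = sd), n_per_cell) +
        as.numeric(cl[[3]])
      feature_set(X, subject = sprintf("%s_%02d", substr(cl[[1]], 1, 1),
                                       rep(1:2, length.out = n_per_cell)),
                  group = cl[[1]], session = cl[[2]])
    }))
  })
}

small_fixture_dir <- function(n = 10, separation = 3, seed = 7,
                              image_size = 64) {
  dir <- tempfile("fixtures")
  generate_scalogram_fixtures(
    dir,
    n_per_class = c(tinnitus_S1 = n, tinnitus_S2 = n,
                    control_S1 = n, control_S2 = n),
    image_size = image_size, separation = separation, seed = seed)
  dir
}
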