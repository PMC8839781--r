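#' Configuration of a synthetic EEG cohort
#'
#' Describes the study-shaped simulation: two groups (tinnitus/control) by
#' two monitoring sessions (S1 before, S2 after an 8-week sound-based
#' treatment), 16-channel 10-20 montage recordings at 256 Hz, five auditory
#' stimuli of 1 s repeated 50 times at a random rate, a keypress response
#' per repetition, and event-locked band-limited power modulations riding
#' on 1/f background noise.
#'
#' The default effect profile follows the qualitative pattern the analysis
#' is meant to detect: controls show an alpha (8-13 Hz) event-related
#' synchronization in both sessions; tinnitus patients lack it before
#' treatment and instead show late 25-30 Hz activity after 500 ms, then
#' regain the alpha response after treatment. Reaction times are broad
#' (uniform 0-1 s) in S1 and narrow (uniform 0-0.5 s) in S2.
#'
#' @param n_subjects_per_group Subjects per group (the study enrolled 11).
#' @param fs Sampling rate, Hz.
#' @param channel_names 10-20 montage labels; must include the analysis
#'   channel `"Fz"`.
#' @param n_stimuli,reps_per_stimulus Stimuli per soundscape and
#'   repetitions of each.
#' @param stimulus_duration Stimulus length, s.
#' @param isi_range Uniform range of the silent gap between consecutive
#'   stimuli, s (the study reports only "a random rate").
#' @param reaction_time Named list `S1`/`S2` of uniform `c(lo, hi)` keypress
#'   latency ranges, s.
#' @param ers_bands Named list `<group>.<session>` of burst tables; each a
#'   data frame with columns `f_low`, `f_high` (Hz), `amplitude` (uV),
#'   `onset` (s after keypress), `duration` (s).
#' @param noise_exponent Slope of the 1/f^a background noise spectrum.
#' @param noise_scale Background noise standard deviation, uV.
#' @param line_noise Optional `list(freq =, amplitude =)` mains component.
#' @param duration Recording length, s, or `NULL` to fit the event train.
#' @param seed Master seed; every recording derives its own stream from it.
#' @return A `cohort_config` list, validated.
#' @export
cohort_config <- function(n_subjects_per_group = 11,
                          fs = 256,
                          channel_names = montage_10_20(),
                          n_stimuli = 5,
                          reps_per_stimulus = 50,
                          stimulus_duration = 1.0,
                          isi_range = c(0.5, 1.5),
                          reaction_time = list(S1 = c(0, 1), S2 = c(0, 0.5)),
                          ers_bands = default_ers_profile(),
                          noise_exponent = 1.0,
                          noise_scale = 10,
                          line_noise = NULL,
                          duration = NULL,
                          seed = 1L) {
  cfg <- list(n_subjects_per_group = n_subjects_per_group, fs = fs,
              channel_names = as.character(channel_names),
              n_stimuli = n_stimuli, reps_per_stimulus = reps_per_stimulus,
              stimulus_duration = stimulus_duration, isi_range = isi_range,
              reaction_time = reaction_time, ers_bands = ers_bands,
              noise_exponent = noise_exponent, noise_scale = noise_scale,
              line_noise = line_noise, duration = duration,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  if (cfg$fs <= 0) abort("fs must be positive.")
  if (cfg$reps_per_stimulus < 1) abort("reps_per_stimulus must be >= 1.")
  if (cfg$n_stimuli < 1) abort("n_stimuli must be >= 1.")
  if (cfg$noise_scale < 0) abort("noise_scale must be >= 0.")
  for (nm in names(cfg$ers_bands)) {
    b <- cfg$ers_bands[[nm]]
    if (is.null(b) || nrow(as.data.frame(b)) == 0) next
    b <- as.data.frame(b)
    ok <- b$f_low > 0 & b$f_low < b$f_high & b$f_high <= cfg$fs / 2
    if (!all(ok)) {
      abort(sprintf("invalid ERS band in '%s': need 0 < f_low < f_high <= fs/2.", nm))
    }
    if (any(b$amplitude < 0)) abort("ERS amplitudes must be >= 0.")
  }
  invisible(cfg)
}

#' @rdname cohort_config
#' @export
montage_10_20 <- function() {
  c("FP1", "FP2", "F7", "F3", "Fz", "F4", "F8",
    "T3", "T4", "T5", "T6", "C3", "C4", "Pz", "O1", "O2")
}

#' @rdname cohort_config
#' @export
default_ers_profile <- function() {
  alpha <- data.frame(f_low = 8, f_high = 13, amplitude = 5,
                      onset = 0.05, duration = 0.5)
  late_beta <- data.frame(f_low = 25, f_high = 30, amplitude = 5,
                          onset = 0.5, duration = 0.5)
  none <- alpha[0, ]
  list(tinnitus.S1 = late_beta,
       tinnitus.S2 = alpha,
       control.S1 = alpha,
       control.S2 = alpha)
}

# 1/f^a noise by spectral shaping of white noise; unit SD, length n.
pink_noise <- function(n, exponent) {
  w <- rnorm(n)
  W <- fft(w)
  f <- c(1, seq_len(n - 1))            # avoid dividing the DC bin by zero
  f <- pmin(f, n - f + 1)              # symmetric frequency index
  W <- W / f^(exponent / 2)
  W[1] <- 0
  x <- Re(fft(W, inverse = TRUE)) / n
  x / sd(x)
}

hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

#' Generate one synthetic recording
#'
#' Simulates one subject-session: pink-noise background on every channel
#' plus, time-locked to each keypress, Hann-windowed sinusoidal bursts at
#' the configured bands. Returns the recording together with the ground
#' truth of every injected burst, for recovery tests downstream.
#'
#' @inheritParams write_recording
#' @param config A [cohort_config()].
#' @param group `"tinnitus"` or `"control"`.
#' @param session `"S1"` or `"S2"`.
#' @param subject Subject index within the group (selects the RNG stream).
#' @return A list with elements `recording` ([eeg_recording()]) and
#'   `truth` (tibble of injected bursts; one row per event x band).
#' @export
generate_recording <- function(config, group = c("tinnitus", "control"),
                               session = c("S1", "S2"), subject = 1L) {
  group <- match.arg(group)
  session <- match.arg(session)
  validate_cohort_config(config)
  seed <- derive_seed(config$seed, paste(group, session, subject, sep = "/"))
  with_seed(seed, generate_recording_impl(config, group, session, subject))
}

generate_recording_impl <- function(config, group, session, subject) {
  fs <- config$fs
  n_events <- config$n_stimuli * config$reps_per_stimulus
  rt_range <- config$reaction_time[[session]]

  # stimulus train: 1 s stimuli at a random rate, randomly interleaved labels
  gaps <- runif(n_events, config$isi_range[1], config$isi_range[2])
  onsets <- 2 + cumsum(c(0, head(config$stimulus_duration + gaps, -1)))
  labels <- sample(rep(sprintf("stim%d", seq_len(config$n_stimuli)),
                       config$reps_per_stimulus))
  rt <- runif(n_events, rt_range[1], rt_range[2])
  press <- onsets + rt

  needed <- max(press) + 1.5            # room for the +1 s epoch window
  dur <- if (is.null(config$duration)) needed else config$duration
  if (dur < needed) {
    abort(sprintf(
      "duration %.1f s too short: %d events need %.1f s.", dur, n_events, needed))
  }
  n <- as.integer(round(dur * fs))
  nchan <- length(config$channel_names)

  sig <- matrix(0, nchan, n)
  for (ch in seq_len(nchan)) {
    sig[ch, ] <- config$noise_scale * pink_noise(n, config$noise_exponent)
  }
  if (!is.null(config$line_noise)) {
    t <- (seq_len(n) - 1) / fs
    sig <- sig + matrix(config$line_noise$amplitude *
                          sin(2 * pi * config$line_noise$freq * t),
                        nchan, n, byrow = TRUE)
  }

  bands <- as.data.frame(config$ers_bands[[paste(group, session, sep = ".")]])
  truth_rows <- list()
  if (!is.null(bands) && nrow(bands)) {
    for (b in seq_len(nrow(bands))) {
      fc <- (bands$f_low[b] + bands$f_high[b]) / 2
      nb <- as.integer(round(bands$duration[b] * fs))
      env <- hann_window(nb)
      tt <- (0:(nb - 1)) / fs
      for (e in seq_len(n_events)) {
        start <- as.integer(round((press[e] + bands$onset[b]) * fs)) + 1L
        if (start + nb - 1L > n) next
        phase <- runif(1, 0, 2 * pi)
        burst <- bands$amplitude[b] * env * sin(2 * pi * fc * tt + phase)
        idx <- start:(start + nb - 1L)
        sig[, idx] <- sig[, idx] + matrix(burst, nchan, nb, byrow = TRUE)
        truth_rows[[length(truth_rows) + 1L]] <- tibble(
          event = e, f_low = bands$f_low[b], f_high = bands$f_high[b],
          amplitude = bands$amplitude[b], start_s = (start - 1L) / fs,
          duration = bands$duration[b])
      }
    }
  }
  events <- tibble(onset_s = press, label = labels)
  rec <- eeg_recording(sig, fs, config$channel_names, events = events)
  truth <- dplyr::bind_rows(truth_rows)
  if (nrow(truth) == 0) {
    truth <- tibble(event = integer(), f_low = numeric(), f_high = numeric(),
                    amplitude = numeric(), start_s = numeric(),
                    duration = numeric())
  }
  truth$group <- group
  truth$session <- session
  truth$subject <- subject
  list(recording = rec, truth = truth)
}

#' Generate the full two-group, two-session cohort
#'
#' @param config A [cohort_config()].
#' @return A tibble with one row per recording: `group`, `session`,
#'   `subject`, and list-columns `recording` and `truth`. Deterministic
#'   given `config$seed`: each cell derives an independent RNG stream, so
#'   regenerating the cohort reproduces every recording bit-exactly.
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  grid <- tidyr::expand_grid(
    group = c("tinnitus", "control"),
    session = c("S1", "S2"),
    subject = seq_len(config$n_subjects_per_group))
  sims <- purrr::pmap(grid, function(group, session, subject) {
    generate_recording(config, group, session, subject)
  })
  grid$recording <- purrr::map(sims, "recording")
  grid$truth <- purrr::map(sims, "truth")
  grid
}
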