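# Synthetic vigilance-session generator: schedules, signals, reaction times.

#' Session configuration for the vigilance protocol
#'
#' Describes one recording session of the visual vigilance task: `n_runs`
#' runs of `trials_per_run` self-paced trials. In each trial the participant
#' fixates for a pre-stimulus interval whose duration is drawn uniformly in
#' `[pre_stimulus_base_s - jitter_max_s, pre_stimulus_base_s + jitter_max_s)`
#' (the attention interval used for classification), then responds to the
#' stimulus; the stimulus/keypress period is an unlabeled gap of `gap_s`
#' seconds. After the last trial of a run the participant rests for
#' `rest_duration_s` seconds.
#'
#' @param n_runs number of runs in the session.
#' @param trials_per_run trials per run (default 8).
#' @param pre_stimulus_base_s center of the pre-stimulus attention interval,
#'   seconds (default 6).
#' @param jitter_max_s half-width of the uniform jitter, seconds (default 2,
#'   exclusive upper bound).
#' @param rest_duration_s rest block after each run, seconds (default 48).
#' @param gap_s unlabeled stimulus/response gap after each trial, seconds
#'   (default 1.5).
#' @param sampling_rate_hz sampling rate, Hz (default 250).
#' @param n_channels number of EEG channels (default 2: left and right ear).
#' @param seed integer seed governing the schedule jitter and, combined with
#'   the subject id, all signal randomness.
#' @return a `session_config` list.
#' @export
session_config <- function(n_runs = 8, trials_per_run = 8,
                           pre_stimulus_base_s = 6, jitter_max_s = 2,
                           rest_duration_s = 48, gap_s = 1.5,
                           sampling_rate_hz = 250, n_channels = 2, seed = 1L) {
  if (!is_count(n_runs)) abort_("`n_runs` must be a non-negative integer")
  if (!is_count(trials_per_run) || trials_per_run < 1)
    abort_("`trials_per_run` must be a positive integer")
  check_scalar_num(pre_stimulus_base_s, "pre_stimulus_base_s", lower = 0, lower_open = TRUE)
  check_scalar_num(jitter_max_s, "jitter_max_s", lower = 0)
  if (jitter_max_s >= pre_stimulus_base_s)
    abort_("`jitter_max_s` must be smaller than `pre_stimulus_base_s`")
  check_scalar_num(rest_duration_s, "rest_duration_s", lower = 0, lower_open = TRUE)
  check_scalar_num(gap_s, "gap_s", lower = 0)
  check_scalar_num(sampling_rate_hz, "sampling_rate_hz", lower = 0, lower_open = TRUE)
  if (!is_count(n_channels) || n_channels < 1)
    abort_("`n_channels` must be a positive integer")
  structure(list(
    n_runs = as.integer(n_runs), trials_per_run = as.integer(trials_per_run),
    pre_stimulus_base_s = pre_stimulus_base_s, jitter_max_s = jitter_max_s,
    rest_duration_s = rest_duration_s, gap_s = gap_s,
    sampling_rate_hz = sampling_rate_hz, n_channels = as.integer(n_channels),
    seed = as.integer(seed)
  ), class = "session_config")
}

#' Band-wise effect profile of the synthetic signal
#'
#' Generative parameters of one subject's EEG: per-band baseline amplitudes
#' (peak microvolts of a random-phase band-centered sinusoid), per-band
#' multipliers applied during attentive and rest states, and the amplitude,
#' spectral exponent and inter-channel correlation of the 1/f background
#' noise. The defaults encode the attention correlates the classifier is
#' expected to exploit: alpha rises at rest (x1.8) while theta (x1.3) and
#' gamma (x1.2) rise under attention.
#'
#' @param baseline_uv named per-band baseline amplitudes, microvolts.
#' @param attentive_mult named per-band amplitude multipliers in the
#'   attentive state.
#' @param rest_mult named per-band amplitude multipliers in the rest state.
#' @param noise_amplitude_uv standard deviation of the 1/f background noise,
#'   microvolts.
#' @param noise_exponent exponent of the 1/f^exponent background (default 1).
#' @param channel_correlation correlation of the background noise across
#'   channels, in \[0, 1\].
#' @return a `band_effect_profile` list.
#' @export
band_effect_profile <- function(
    baseline_uv = c(delta = 20, theta = 10, alpha = 15, beta = 5, gamma = 2),
    attentive_mult = c(delta = 1, theta = 1.3, alpha = 1, beta = 1, gamma = 1.2),
    rest_mult = c(delta = 1, theta = 1, alpha = 1.8, beta = 1, gamma = 1),
    noise_amplitude_uv = 60, noise_exponent = 1, channel_correlation = 0.6) {
  bands <- eeg_bands()$band
  for (nm in c("baseline_uv", "attentive_mult", "rest_mult")) {
    v <- get(nm)
    if (!all(bands %in% names(v))) abort_("`%s` must name all five bands", nm)
    if (any(v < 0)) abort_("`%s` must be non-negative", nm)
  }
  check_scalar_num(noise_amplitude_uv, "noise_amplitude_uv", lower = 0)
  check_scalar_num(noise_exponent, "noise_exponent", lower = 0)
  check_scalar_num(channel_correlation, "channel_correlation", lower = 0, upper = 1)
  structure(list(
    baseline_uv = baseline_uv[bands], attentive_mult = attentive_mult[bands],
    rest_mult = rest_mult[bands], noise_amplitude_uv = noise_amplitude_uv,
    noise_exponent = noise_exponent, channel_correlation = channel_correlation
  ), class = "band_effect_profile")
}

#' Subject profile: band effects plus behavioral parameters
#'
#' @param subject_id identifier string.
#' @param band_profile a [band_effect_profile()].
#' @param subject_offset_scale log-normal perturbation scale applied once per
#'   subject to the band baseline amplitudes (captures inter-subject
#'   variability of EEG spectra; 0 disables it).
#' @param rt_mean_s,rt_sd_s mean and SD of the normal reaction-time draw,
#'   seconds.
#' @param false_start_prob probability a trial is replaced by a false start
#'   (reaction time < 0.1 s).
#' @param lapse_prob probability a trial is replaced by a lapse (reaction
#'   time drawn in 1-2 s, far above the mean).
#' @return a `subject_profile` list.
#' @export
subject_profile <- function(subject_id, band_profile = band_effect_profile(),
                            subject_offset_scale = 0.1,
                            rt_mean_s = 0.4, rt_sd_s = 0.05,
                            false_start_prob = 0.05, lapse_prob = 0.05) {
  if (!is.character(subject_id) || length(subject_id) != 1)
    abort_("`subject_id` must be a single string")
  if (!inherits(band_profile, "band_effect_profile"))
    abort_("`band_profile` must be a band_effect_profile()")
  check_scalar_num(subject_offset_scale, "subject_offset_scale", lower = 0)
  check_scalar_num(rt_mean_s, "rt_mean_s", lower = 0, lower_open = TRUE)
  check_scalar_num(rt_sd_s, "rt_sd_s", lower = 0)
  check_scalar_num(false_start_prob, "false_start_prob", lower = 0, upper = 1)
  check_scalar_num(lapse_prob, "lapse_prob", lower = 0, upper = 1)
  if (false_start_prob + lapse_prob > 1)
    abort_("false_start_prob + lapse_prob must not exceed 1")
  structure(list(
    subject_id = subject_id, band_profile = band_profile,
    subject_offset_scale = subject_offset_scale,
    rt_mean_s = rt_mean_s, rt_sd_s = rt_sd_s,
    false_start_prob = false_start_prob, lapse_prob = lapse_prob
  ), class = "subject_profile")
}

#' Build the trial/rest schedule of a session
#'
#' Lays out the session timeline as contiguous, non-overlapping intervals:
#' for every run, `trials_per_run` attentive pre-stimulus intervals each
#' followed by an unlabeled stimulus/response gap, then one rest block.
#' Attention interval durations are drawn uniformly in
#' `[pre_stimulus_base_s - jitter_max_s, pre_stimulus_base_s + jitter_max_s)`
#' from the config seed, so the schedule is deterministic given the config.
#'
#' @param config a [session_config()].
#' @return a tibble with columns `run`, `trial` (NA outside attention
#'   intervals), `state` (`"attentive"`, `"none"`, `"rest"`), `start_s`,
#'   `end_s`, and `segment` (contiguous-stream id: one attention stream and
#'   one rest block per run; NA for gaps).
#' @export
#' @examples
#' make_session_schedule(session_config(n_runs = 1, seed = 7))
make_session_schedule <- function(config) {
  if (!inherits(config, "session_config")) abort_("`config` must be a session_config()")
  if (config$n_runs == 0) {
    return(tibble(run = integer(), trial = integer(), state = character(),
                  start_s = double(), end_s = double(), segment = character()))
  }
  n_trials <- config$n_runs * config$trials_per_run
  durations <- withr::with_seed(config$seed, runif(
    n_trials,
    min = config$pre_stimulus_base_s - config$jitter_max_s,
    max = config$pre_stimulus_base_s + config$jitter_max_s
  ))
  rows <- vector("list", config$n_runs)
  k <- 0L
  for (r in seq_len(config$n_runs)) {
    run_rows <- list()
    for (j in seq_len(config$trials_per_run)) {
      k <- k + 1L
      run_rows[[length(run_rows) + 1L]] <- tibble(
        run = r, trial = j, state = "attentive", dur = durations[k],
        segment = sprintf("r%02d_task", r))
      if (config$gap_s > 0)
        run_rows[[length(run_rows) + 1L]] <- tibble(
          run = r, trial = NA_integer_, state = "none", dur = config$gap_s,
          segment = NA_character_)
    }
    run_rows[[length(run_rows) + 1L]] <- tibble(
      run = r, trial = NA_integer_, state = "rest", dur = config$rest_duration_s,
      segment = sprintf("r%02d_rest", r))
    rows[[r]] <- bind_rows(run_rows)
  }
  sched <- bind_rows(rows)
  sched$end_s <- cumsum(sched$dur)
  sched$start_s <- sched$end_s - sched$dur
  sched[, c("run", "trial", "state", "start_s", "end_s", "segment")]
}

# Sample index bounds of each schedule interval (1-based, inclusive).
# Both label painting and epoch segmentation use this one arithmetic, so
# label boundaries and interval boundaries agree exactly.
interval_samples <- function(schedule, fs) {
  tibble(start_sample = round(schedule$start_s * fs) + 1L,
         end_sample   = round(schedule$end_s * fs))
}

# 1/f^exponent noise, unit variance, length n (FFT-filtered white noise).
# Generated at the next 2/3/5-smooth length and truncated: session lengths
# are jittered and can have large prime factors, for which the mixed-radix
# FFT degrades to quadratic time.
pink_noise <- function(n, exponent = 1) {
  m <- stats::nextn(n, c(2, 3, 5))
  w <- stats::fft(rnorm(m))
  k <- 0:(m - 1)
  f <- pmin(k, m - k)
  f[1] <- 1 # keep DC finite; it is removed by unit-variance scaling anyway
  x <- Re(stats::fft(w / f^(exponent / 2), inverse = TRUE))[seq_len(n)] / m
  x <- x - mean(x)
  x / sd(x)
}

#' Synthesize a labeled EEG recording for one subject
#'
#' Per channel the signal is additive: 1/f background noise (correlated
#' across channels) plus one random-phase sinusoid per canonical band,
#' centered in the band, whose amplitude is the subject's per-band baseline
#' times the state multiplier of the sample's state (gaps use multiplier 1).
#' The generative process is stationary within a state. Per-sample labels
#' are painted from the schedule; reaction times are simulated per trial.
#' Everything is deterministic given `config$seed` and the subject id.
#'
#' @param schedule a schedule tibble from [make_session_schedule()].
#' @param subject a [subject_profile()].
#' @param config the [session_config()] that produced the schedule.
#' @return a `labeled_recording`: list with `signal` (channels x samples
#'   matrix, microvolts, rownames `left`/`right`), `sampling_rate_hz`,
#'   `labels` (per-sample state strings), `schedule`, `reaction_times`
#'   (tibble `run`, `trial`, `rt_s`) and `subject_id`.
#' @export
synthesize_recording <- function(schedule, subject, config) {
  if (!is.data.frame(schedule) || nrow(schedule) == 0)
    abort_("`schedule` must be a non-empty schedule tibble")
  if (!inherits(subject, "subject_profile")) abort_("`subject` must be a subject_profile()")
  if (!inherits(config, "session_config")) abort_("`config` must be a session_config()")
  fs <- config$sampling_rate_hz
  gamma_high <- max(eeg_bands()$high_hz)
  if (fs < 2 * gamma_high)
    abort_("sampling rate %g Hz is below twice the gamma upper edge (%g Hz): aliasing", fs, 2 * gamma_high)

  n <- round(max(schedule$end_s) * fs)
  bounds <- interval_samples(schedule, fs)
  labels <- rep("none", n)
  for (i in seq_len(nrow(schedule)))
    labels[bounds$start_sample[i]:bounds$end_sample[i]] <- schedule$state[i]

  bp <- subject$band_profile
  bands <- eeg_bands()
  nch <- config$n_channels
  seed <- derive_seed(config$seed, "recording", subject$subject_id)
  signal <- withr::with_seed(seed, {
    amp <- bp$baseline_uv *
      if (subject$subject_offset_scale > 0)
        exp(rnorm(nrow(bands), 0, subject$subject_offset_scale)) else 1
    # state-dependent per-sample multiplier per band
    mult <- sapply(seq_len(nrow(bands)), function(b) {
      m <- rep(1, n)
      m[labels == "attentive"] <- bp$attentive_mult[b]
      m[labels == "rest"] <- bp$rest_mult[b]
      m
    })
    tt <- (seq_len(n) - 1) / fs
    rho <- bp$channel_correlation
    shared <- pink_noise(n, bp$noise_exponent)
    sig <- matrix(0, nch, n)
    for (ch in seq_len(nch)) {
      own <- pink_noise(n, bp$noise_exponent)
      noise <- sqrt(rho) * shared + sqrt(1 - rho) * own
      x <- bp$noise_amplitude_uv * noise
      for (b in seq_len(nrow(bands))) {
        fc <- (bands$low_hz[b] + bands$high_hz[b]) / 2
        phase <- runif(1, 0, 2 * pi)
        x <- x + amp[b] * mult[, b] * sin(2 * pi * fc * tt + phase)
      }
      sig[ch, ] <- x
    }
    sig
  })
  rownames(signal) <- if (nch == 2) c("left", "right") else paste0("ch", seq_len(nch))

  att <- schedule[schedule$state == "attentive", ]
  rts <- simulate_reaction_times(nrow(att), subject,
                                 seed = derive_seed(config$seed, "rt", subject$subject_id))
  structure(list(
    signal = signal, sampling_rate_hz = fs, labels = labels,
    schedule = as_tibble(schedule),
    reaction_times = tibble(run = att$run, trial = att$trial, rt_s = rts),
    subject_id = subject$subject_id
  ), class = "labeled_recording")
}

#' @export
print.labeled_recording <- function(x, ...) {
  cat(sprintf("<labeled_recording> subject %s: %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, nrow(x$signal), ncol(x$signal), x$sampling_rate_hz,
              ncol(x$signal) / x$sampling_rate_hz))
  tab <- table(x$labels)
  cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("  %d trials with reaction times\n", nrow(x$reaction_times)))
  invisible(x)
}

#' Simulate per-trial reaction times
#'
#' Reaction times are normal draws truncated at zero; with probability
#' `false_start_prob` a trial is replaced by a false start (uniform below
#' 0.1 s) and with probability `lapse_prob` by a lapse (uniform in 1-2 s,
#' far above the mean for the default profile).
#'
#' @param n_trials number of trials (>= 0).
#' @param subject a [subject_profile()].
#' @param seed integer seed.
#' @return numeric vector of reaction times in seconds (length `n_trials`).
#' @export
simulate_reaction_times <- function(n_trials, subject, seed = 1L) {
  if (!is_count(n_trials)) abort_("`n_trials` must be a non-negative integer")
  if (n_trials == 0) return(numeric(0))
  if (!inherits(subject, "subject_profile")) abort_("`subject` must be a subject_profile()")
  withr::with_seed(seed, {
    rt <- rnorm(n_trials, subject$rt_mean_s, subject$rt_sd_s)
    while (any(rt < 0)) # truncate at 0 by redrawing
      rt[rt < 0] <- rnorm(sum(rt < 0), subject$rt_mean_s, subject$rt_sd_s)
    u <- runif(n_trials)
    fs <- u < subject$false_start_prob
    lp <- !fs & u < subject$false_start_prob + subject$lapse_prob
    rt[fs] <- runif(sum(fs), 0, 0.099)
    rt[lp] <- runif(sum(lp), 1, 2)
    rt
  })
}

#' Simulate one subject's full session
#'
#' Convenience wrapper: builds the schedule for `config` and synthesizes the
#' labeled recording (including reaction times).
#'
#' @inheritParams synthesize_recording
#' @return a `labeled_recording`.
#' @export
simulate_session <- function(subject, config) {
  synthesize_recording(make_session_schedule(config), subject, config)
}

#' Simulate a cohort of subjects
#'
#' Generates `n_subjects` labeled recordings. Each subject shares the session
#' structure of `config` but gets its own jitter, noise, band-amplitude
#' perturbation and reaction times (seeds derived from `config$seed` and the
#' subject id).
#'
#' @param n_subjects number of subjects.
#' @param config a [session_config()].
#' @param profiles optional list of [subject_profile()]s (length
#'   `n_subjects`); by default all subjects share the default profile and
#'   differ only through their random draws.
#' @return named list of `labeled_recording`s.
#' @export
simulate_cohort <- function(n_subjects = 6, config = session_config(), profiles = NULL) {
  if (!is_count(n_subjects) || n_subjects < 1) abort_("`n_subjects` must be a positive integer")
  ids <- sprintf("s%02d", seq_len(n_subjects))
  if (is.null(profiles)) profiles <- lapply(ids, subject_profile)
  if (length(profiles) != n_subjects) abort_("`profiles` must have length n_subjects")
  recs <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, "schedule", profiles[[i]]$subject_id)
    recs[[i]] <- simulate_session(profiles[[i]], cfg)
  }
  names(recs) <- vapply(profiles, `[[`, character(1), "subject_id")
  recs
}
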