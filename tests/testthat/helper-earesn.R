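# Shared fixtures and independent oracles. Everything is generated in code;
# sessions here are deliberately small so the suite stays fast, while the
# acceptance tests use full study-sized sessions.

quick_config <- function(n_runs = 2, trials_per_run = 4, rest_duration_s = 12,
                         seed = 1L, ...) {
  session_config(n_runs = n_runs, trials_per_run = trials_per_run,
                 rest_duration_s = rest_duration_s, seed = seed, ...)
}

quick_recording <- function(seed = 1L, id = "s01", profile = band_effect_profile(), ...) {
  cfg <- quick_config(seed = seed, ...)
  simulate_session(subject_profile(id, band_profile = profile), cfg)
}

# single-point hyperparameter grid for fast CV mechanics tests
point_grid <- function() grid_search_spec(0.3, 0.9, repeats = 1)

# a hand-made recording with one labeled interval, for segmentation tests
flat_recording <- function(duration_s, state = "rest", fs = 250, n_channels = 2,
                           signal = NULL) {
  n <- round(duration_s * fs)
  if (is.null(signal)) {
    signal <- matrix(rnorm(n_channels * n), n_channels, n)
  }
  rownames(signal) <- if (n_channels == 2) c("left", "right") else paste0("ch", seq_len(n_channels))
  structure(list(
    signal = signal, sampling_rate_hz = fs,
    labels = rep(state, n),
    schedule = tibble::tibble(run = 1L, trial = if (state == "attentive") 1L else NA_integer_,
                              state = state, start_s = 0, end_s = duration_s,
                              segment = "r01_seg"),
    reaction_times = tibble::tibble(run = integer(), trial = integer(), rt_s = double()),
    subject_id = "manual"
  ), class = "labeled_recording")
}

# independent band-power oracle: plain (untapered) periodogram of a segment,
# mean power over bins inside [low, high) -- deliberately not the package's
# Hamming-tapered square-root PSD
oracle_band_power <- function(x, fs, low, high) {
  n <- length(x)
  X <- stats::fft(x)[seq_len(n %/% 2 + 1)]
  p <- Mod(X)^2 / n
  f <- (seq_along(p) - 1) * fs / n
  mean(p[f >= low & f < high])
}

# mean alpha power of all samples of a recording with a given state label
state_band_power <- function(rec, state, low = 8, high = 13) {
  idx <- which(rec$labels == state)
  # split into runs of consecutive samples, use segments >= 1 s
  brk <- c(0, which(diff(idx) > 1), length(idx))
  ps <- c()
  for (k in seq_len(length(brk) - 1)) {
    seg <- idx[(brk[k] + 1):brk[k + 1]]
    if (length(seg) >= rec$sampling_rate_hz)
      ps <- c(ps, mean(sapply(seq_len(nrow(rec$signal)), function(ch)
        oracle_band_power(rec$signal[ch, seg], rec$sampling_rate_hz, low, high))))
  }
  mean(ps)
}

# brute-force causal windowed mean (the smoothing oracle)
brute_smooth <- function(y, n) {
  vapply(seq_along(y), function(t) mean(y[max(1, t - n + 1):t]), numeric(1))
}

# brute-force reaction-time exclusion (both rules, statistics over all trials)
brute_exclusion <- function(rts, fs_thr = 0.1, k = 3) {
  keep <- logical(length(rts))
  m <- mean(rts); s <- stats::sd(rts)
  for (i in seq_along(rts)) keep[i] <- !(rts[i] < fs_thr || rts[i] > m + k * s)
  keep
}

# linearly separable feature tibble: two Gaussian clusters at +/- delta SD in
# the informative dimensions, organised into contiguous alternating segments
cluster_features <- function(n_segments = 10, seg_len = 30, n_feat = 10,
                             n_informative = 4, delta = 1.5, seed = 1) {
  withr::with_seed(seed, {
    rows <- list()
    for (s in seq_len(n_segments)) {
      lab <- if (s %% 2 == 0) 1 else -1
      m <- matrix(rnorm(seg_len * n_feat), seg_len, n_feat)
      m[, seq_len(n_informative)] <- m[, seq_len(n_informative)] + lab * delta
      df <- tibble::as_tibble(m, .name_repair = ~ sprintf("f%02d", seq_len(n_feat)))
      df$segment <- sprintf("seg%02d", s)
      df$t <- seq_len(seg_len)
      df$label <- lab
      df$run <- (s + 1) %/% 2
      df$subject <- "sim"
      rows[[s]] <- df
    }
    dplyr::bind_rows(rows)
  })
}
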