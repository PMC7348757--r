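# Band-wise spectral/temporal feature extraction on 0.5 s epochs.

# Butterworth bandpass designed directly in second-order sections (cascaded
# biquads). A 6th-order (12-pole) bandpass with a low edge near DC is
# numerically unusable in single transfer-function form at 250 Hz — the
# pole polynomial is so ill-conditioned that the filtered output is mostly
# rounding noise — so the design goes the classic route: analog Butterworth
# prototype poles, lowpass-to-bandpass transform of the prewarped edges,
# bilinear transform, conjugate poles paired into biquads with one z = 1 and
# one z = -1 zero each, gain normalized to 1 at the band's geometric center.
# Returns an n_sections x 6 matrix [b0 b1 b2 a0 a1 a2].
butter_sos <- function(order, low, high, fs) {
  k <- seq_len(order)
  p <- exp(1i * (pi * (2 * k - 1) / (2 * order) + pi / 2)) # left-half-plane
  wl <- 2 * fs * tan(pi * low / fs) # prewarp
  wh <- 2 * fs * tan(pi * high / fs)
  B <- wh - wl
  w0 <- sqrt(wl * wh)
  pb <- unlist(lapply(p, function(pk) {
    d <- sqrt((pk * B / 2)^2 - w0^2 + 0i)
    c(pk * B / 2 + d, pk * B / 2 - d)
  }))
  zd <- (2 * fs + pb) / (2 * fs - pb) # bilinear transform
  keep <- zd[Im(zd) > 1e-12]
  reals <- sort(Re(zd[abs(Im(zd)) <= 1e-12]))
  if (length(reals))
    keep <- c(keep, complex(real = sqrt(reals[seq(1, length(reals), by = 2)] *
                                        reals[seq(2, length(reals), by = 2)])))
  sos <- t(vapply(keep, function(pp) c(1, 0, -1, 1, -2 * Re(pp), Mod(pp)^2),
                  numeric(6)))
  w0d <- 2 * atan(w0 / (2 * fs))
  z1 <- exp(-1i * w0d)
  H <- prod(apply(sos, 1, function(s)
    (s[1] + s[2] * z1 + s[3] * z1^2) / (s[4] + s[5] * z1 + s[6] * z1^2)))
  sos[, 1:3] <- sos[, 1:3] * (1 / Mod(H))^(1 / nrow(sos))
  sos
}

# Zero-phase (forward-backward) filtering of the biquad cascade with
# odd-reflection edge padding and steady-state initialization (see
# src/sosfilt.cpp), so edge transients stay negligible even for near-DC
# inputs on short windows.
filtfilt_ss <- function(sos, x) {
  n <- length(x)
  npad <- min(6L * nrow(sos), n - 1L)
  xx <- if (npad > 0) {
    c(2 * x[1] - x[seq(npad + 1, 2)], x, 2 * x[n] - x[seq(n - 1, n - npad)])
  } else x
  y <- rev(sosfilt_ss(sos, rev(sosfilt_ss(sos, xx))))
  y[npad + seq_len(n)]
}

#' Zero-phase Butterworth bandpass filter
#'
#' Applies a Butterworth bandpass of the given design order forward and
#' backward (zero phase), so filtering introduces no group delay that would
#' misalign epochs. Output length equals input length.
#'
#' @param x numeric vector, or channels-by-samples matrix (filtered per row).
#' @param low,high band edges in Hz; must satisfy `0 < low < high < fs/2`.
#' @param fs sampling rate in Hz.
#' @param order filter design order (default 6).
#' @return filtered signal, same shape as `x`.
#' @export
broadband_filter <- function(x, low = 1, high = 50, fs, order = 6) {
  check_scalar_num(fs, "fs", lower = 0, lower_open = TRUE)
  if (!(low > 0 && low < high && high < fs / 2))
    abort_("band edges must satisfy 0 < low < high < fs/2 (got %g-%g at fs=%g)", low, high, fs)
  bf <- butter_sos(order, low, high, fs)
  if (is.matrix(x)) {
    out <- t(apply(x, 1, function(row) filtfilt_ss(bf, row)))
    dimnames(out) <- dimnames(x)
    out
  } else {
    filtfilt_ss(bf, x)
  }
}

#' Cut a labeled recording into fixed-length single-state epochs
#'
#' Each labeled schedule interval (attentive or rest) is cut into
#' consecutive non-overlapping windows of `epoch_s` seconds; a trailing
#' remainder shorter than one window is dropped, as is any interval shorter
#' than the window, so every epoch is a full window of a single state.
#' Unlabeled gap intervals produce no epochs.
#'
#' @param recording a `labeled_recording` (see [synthesize_recording()]).
#' @param epoch_s epoch length in seconds; `epoch_s * sampling_rate` must be
#'   an integer (default 0.5, i.e. 125 samples at 250 Hz).
#' @return a tibble with one row per epoch: `subject`, `run`, `trial`,
#'   `segment`, `state`, `t0_s` (epoch start), `t` (epoch order within its
#'   segment) and a list-column `samples` of channels-by-samples matrices.
#' @export
segment_epochs <- function(recording, epoch_s = 0.5) {
  if (!inherits(recording, "labeled_recording")) abort_("`recording` must be a labeled_recording")
  fs <- recording$sampling_rate_hz
  len <- epoch_s * fs
  if (abs(len - round(len)) > 1e-9)
    abort_("epoch_s * sampling rate must be an integer number of samples (got %g)", len)
  len <- as.integer(round(len))
  sched <- recording$schedule
  keep <- sched$state %in% c("attentive", "rest")
  sched <- sched[keep, , drop = FALSE]
  bounds <- interval_samples(sched, fs)
  rows <- vector("list", nrow(sched))
  for (i in seq_len(nrow(sched))) {
    n_ep <- (bounds$end_sample[i] - bounds$start_sample[i] + 1L) %/% len
    if (n_ep < 1) next
    starts <- bounds$start_sample[i] + (seq_len(n_ep) - 1L) * len
    rows[[i]] <- tibble(
      run = sched$run[i], trial = sched$trial[i], segment = sched$segment[i],
      state = sched$state[i], t0_s = (starts - 1L) / fs,
      samples = lapply(starts, function(s)
        recording$signal[, s:(s + len - 1L), drop = FALSE])
    )
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0)
    return(tibble(subject = character(), run = integer(), trial = integer(),
                  segment = character(), state = character(), t0_s = double(),
                  t = integer(), samples = list()))
  out <- out %>%
    mutate(subject = recording$subject_id, .before = 1) %>%
    arrange(.data$t0_s) %>%
    group_by(.data$segment) %>%
    mutate(t = row_number()) %>%
    ungroup()
  out[, c("subject", "run", "trial", "segment", "state", "t0_s", "t", "samples")]
}

# Hamming window periodogram bins for an epoch length; cached per call site.
stft_bins <- function(n, fs) {
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, n - 1) / (n - 1)) # Hamming
  k <- 0:(n %/% 2)
  list(window = w, freq = k * fs / n, scale = 1 / (fs * sum(w^2)))
}

band_bin_index <- function(freq, bands) {
  idx <- lapply(seq_len(nrow(bands)), function(b)
    which(freq >= bands$low_hz[b] & freq < bands$high_hz[b]))
  empty <- lengths(idx) == 0
  if (any(empty))
    abort_("band(s) %s contain no spectral bins at this resolution (%g Hz spacing)",
           paste(bands$band[empty], collapse = ", "), freq[2] - freq[1])
  names(idx) <- bands$band
  idx
}

#' Band-wise square-root spectral power of one epoch
#'
#' Computes a single-segment short-time Fourier transform of the epoch
#' (Hamming taper, no zero padding; 2 Hz bin spacing for a 0.5 s window at
#' 250 Hz), converts it to a one-sided power spectral density, takes the
#' square root, and aggregates over the bins whose center frequency lies in
#' `[low_hz, high_hz)` of each band. Five bands by `n_channels` values.
#'
#' @param epoch channels-by-samples numeric matrix (one 0.5 s window).
#' @param fs sampling rate in Hz.
#' @param bands band definition tibble, see [eeg_bands()].
#' @param agg aggregation over band bins: `"mean"` (default) or `"sum"`.
#' @return named numeric vector `<channel>_<band>_power`, channel-major.
#' @export
spectral_features <- function(epoch, fs, bands = eeg_bands(), agg = c("mean", "sum")) {
  agg <- match.arg(agg)
  bands <- validate_bands(bands)
  if (!is.matrix(epoch)) epoch <- matrix(epoch, nrow = 1)
  n <- ncol(epoch)
  st <- stft_bins(n, fs)
  idx <- band_bin_index(st$freq, bands)
  chn <- channel_names(epoch)
  out <- numeric(0)
  for (ch in seq_len(nrow(epoch))) {
    X <- stats::fft(epoch[ch, ] * st$window)[seq_along(st$freq)]
    psd <- Mod(X)^2 * st$scale
    if (length(psd) > 1) { # one-sided: double everything except DC (and Nyquist if present)
      dbl <- 2:(length(psd) - if (n %% 2 == 0) 1 else 0)
      psd[dbl] <- 2 * psd[dbl]
    }
    amp <- sqrt(psd)
    v <- vapply(idx, function(i) if (agg == "mean") mean(amp[i]) else sum(amp[i]), numeric(1))
    names(v) <- paste(chn[ch], bands$band, "power", sep = "_")
    out <- c(out, v)
  }
  out
}

channel_names <- function(epoch) {
  if (!is.null(rownames(epoch))) rownames(epoch) else paste0("ch", seq_len(nrow(epoch)))
}

band_filters <- function(fs, bands, order = 6) {
  lapply(seq_len(nrow(bands)), function(b)
    butter_sos(order, bands$low_hz[b], bands$high_hz[b], fs))
}

#' Temporal statistics of band-filtered epochs
#'
#' Filters the epoch with each band-specific zero-phase Butterworth bandpass
#' and computes five statistics of the filtered window per channel and band:
#' mean amplitude (mean of absolute values by default, since a band-filtered
#' window has near-zero signed mean), standard deviation, peak-to-peak
#' amplitude, skewness and kurtosis (Pearson convention: a normal signal has
#' kurtosis 3). For a constant filtered window, skewness and kurtosis are
#' undefined and are returned as 0 with a `"degenerate"` attribute naming
#' the affected features.
#'
#' @inheritParams spectral_features
#' @param mean_amplitude `"absolute"` (default) or `"signed"`.
#' @param .filters precomputed filter list (internal fast path).
#' @return named numeric vector of 5 stats x bands x channels,
#'   `<channel>_<band>_<stat>`, channel-major then band then stat.
#' @export
temporal_features <- function(epoch, fs, bands = eeg_bands(),
                              mean_amplitude = c("absolute", "signed"),
                              .filters = NULL) {
  mean_amplitude <- match.arg(mean_amplitude)
  bands <- validate_bands(bands)
  if (!is.matrix(epoch)) epoch <- matrix(epoch, nrow = 1)
  if (is.null(.filters)) .filters <- band_filters(fs, bands)
  chn <- channel_names(epoch)
  stats_nm <- c("meanamp", "sd", "ptp", "skew", "kurt")
  out <- numeric(0)
  degenerate <- character(0)
  for (ch in seq_len(nrow(epoch))) {
    x <- epoch[ch, ]
    for (b in seq_len(nrow(bands))) {
      y <- filtfilt_ss(.filters[[b]], x)
      s <- sd(y)
      v <- c(
        if (mean_amplitude == "absolute") mean(abs(y)) else mean(y),
        s,
        max(y) - min(y),
        if (s > 0) e1071::skewness(y, type = 1) else 0,
        if (s > 0) e1071::kurtosis(y, type = 1) + 3 else 0 # Pearson kurtosis
      )
      nms <- paste(chn[ch], bands$band[b], stats_nm, sep = "_")
      if (s == 0) degenerate <- c(degenerate, nms[4:5])
      names(v) <- nms
      out <- c(out, v)
    }
  }
  if (length(degenerate)) attr(out, "degenerate") <- degenerate
  out
}

#' Extract the per-epoch feature matrix from a labeled recording
#'
#' The full feature pipeline of one recording: broadband 1-50 Hz zero-phase
#' Butterworth filtering of the continuous signal, segmentation into
#' single-state `epoch_s` windows, then per epoch the band-wise square-root
#' spectral power ([spectral_features()]) followed by the five temporal
#' statistics per band ([temporal_features()]). For two channels and five
#' bands this yields 60 features per epoch: 10 spectral then 50 temporal.
#' Attentive epochs are labeled +1 and rest epochs -1; unlabeled gaps yield
#' no epochs.
#'
#' @param recording a `labeled_recording`.
#' @param epoch_s epoch length in seconds (default 0.5).
#' @param bands band definitions (default [eeg_bands()]).
#' @param prefilter broadband filter edges in Hz (default `c(1, 50)`), or
#'   `NULL` to skip.
#' @param mean_amplitude passed to [temporal_features()].
#' @param band_power_agg passed to [spectral_features()] (`agg`).
#' @return a tibble: bookkeeping columns `subject`, `run`, `trial`,
#'   `segment`, `state`, `label` (+1/-1), `t0_s`, `t`, then one numeric
#'   column per feature.
#' @export
extract_features <- function(recording, epoch_s = 0.5, bands = eeg_bands(),
                             prefilter = c(1, 50),
                             mean_amplitude = c("absolute", "signed"),
                             band_power_agg = c("mean", "sum")) {
  mean_amplitude <- match.arg(mean_amplitude)
  band_power_agg <- match.arg(band_power_agg)
  bands <- validate_bands(bands)
  fs <- recording$sampling_rate_hz
  if (!is.null(prefilter)) {
    recording$signal <- broadband_filter(recording$signal, prefilter[1], prefilter[2], fs = fs)
  }
  eps <- segment_epochs(recording, epoch_s)
  if (nrow(eps) == 0) abort_("recording produced no epochs")
  # validate the band/bin layout once, not silently per epoch
  invisible(band_bin_index(stft_bins(ncol(eps$samples[[1]]), fs)$freq, bands))
  filters <- band_filters(fs, bands)
  feats <- lapply(eps$samples, function(m) {
    c(spectral_features(m, fs, bands, agg = band_power_agg),
      temporal_features(m, fs, bands, mean_amplitude = mean_amplitude, .filters = filters))
  })
  fm <- do.call(rbind, feats)
  meta <- eps %>%
    select(-"samples") %>%
    mutate(label = ifelse(.data$state == "attentive", 1, -1), .after = "state")
  bind_cols(meta, as_tibble(fm))
}

#' Fit a feature standardizer on training epochs
#'
#' Records, per feature and from the supplied (training) rows only: the mean
#' and standard deviation used for z-scoring, and the min/max of the
#' z-scored training values used to rescale to \[-1, 1\]. Zero-variance
#' features get standard deviation 1 and are flagged. Freezing these
#' statistics on training rows keeps test rows from leaking into the
#' transform in cross-validation.
#'
#' @param training a feature tibble (training rows only), >= 2 rows.
#' @return a `feature_standardizer`: tibble with columns `feature`, `mean`,
#'   `sd`, `zmin`, `zmax`, `zero_var`.
#' @export
fit_standardizer <- function(training) {
  cols <- feature_columns(training)
  if (nrow(training) < 2) abort_("need at least 2 training epochs to fit a standardizer")
  m <- feature_matrix_of(training, cols)
  mu <- colMeans(m)
  sdev <- apply(m, 2, sd)
  zero_var <- sdev == 0
  sdev[zero_var] <- 1
  z <- sweep(sweep(m, 2, mu), 2, sdev, "/")
  params <- tibble(
    feature = cols, mean = unname(mu), sd = unname(sdev),
    zmin = unname(apply(z, 2, min)), zmax = unname(apply(z, 2, max)),
    zero_var = unname(zero_var)
  )
  if (any(zero_var))
    warning(sprintf("zero-variance feature(s): %s",
                    paste(cols[zero_var], collapse = ", ")), call. = FALSE)
  structure(params, class = c("feature_standardizer", class(params)))
}

#' Standardize and rescale a feature tibble
#'
#' Applies the frozen training transform: z-scoring by the training mean and
#' standard deviation, then the linear map sending the training minimum and
#' maximum of each z-scored feature to -1 and +1. Training rows land in
#' \[-1, 1\]; test rows may exceed it (no clipping).
#'
#' @param features a feature tibble.
#' @param params a `feature_standardizer` from [fit_standardizer()].
#' @return the tibble with feature columns transformed (bookkeeping columns
#'   untouched).
#' @export
apply_standardizer <- function(features, params) {
  if (!inherits(params, "feature_standardizer")) abort_("`params` must come from fit_standardizer()")
  cols <- feature_columns(features)
  if (!setequal(cols, params$feature) || length(cols) != nrow(params))
    abort_("feature columns do not match the fitted standardizer (dimension mismatch)")
  m <- feature_matrix_of(features, params$feature)
  z <- sweep(sweep(m, 2, params$mean), 2, params$sd, "/")
  rng <- params$zmax - params$zmin
  scale <- ifelse(rng > 0, 2 / rng, 0) # degenerate features map to constant 0
  r <- sweep(sweep(z, 2, params$zmin), 2, scale, "*") - 1
  r[, rng == 0] <- 0
  features[params$feature] <- as_tibble(r)
  features
}
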