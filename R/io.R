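# Readers/writers: delimited-text and EDF recordings (with label/trial
# sidecars), feature matrices, CV reports.

sidecar_paths <- function(prefix) {
  list(labels = paste0(prefix, "_labels.tsv"),
       trials = paste0(prefix, "_trials.tsv"),
       meta = paste0(prefix, "_meta.json"))
}

#' Write a labeled recording to disk
#'
#' Writes the signal either as delimited text (one column per channel,
#' header row, microvolts) or as a minimal EDF file (one EDF signal per
#' channel, 16-bit; values are quantized to the channel's physical range,
#' so the round-trip is exact only to quantization precision). Labels and
#' reaction times always go to delimited sidecars: `<prefix>_labels.tsv`
#' with columns `start_sample`, `end_sample`, `state`, `run`, `trial`,
#' `segment` (1-based inclusive sample indices) and `<prefix>_trials.tsv`
#' with columns `trial_index`, `run`, `trial`, `rt_seconds`; sampling rate
#' and subject id go to `<prefix>_meta.json`.
#'
#' @param recording a `labeled_recording`.
#' @param prefix output path prefix (directory must exist).
#' @param format `"delim"` (default) or `"edf"`.
#' @return invisibly, the paths written.
#' @export
write_recording <- function(recording, prefix, format = c("delim", "edf")) {
  format <- match.arg(format)
  if (!inherits(recording, "labeled_recording")) abort_("`recording` must be a labeled_recording")
  side <- sidecar_paths(prefix)
  fs <- recording$sampling_rate_hz
  sched <- recording$schedule
  bounds <- interval_samples(sched, fs)
  readr::write_tsv(
    tibble(start_sample = bounds$start_sample, end_sample = bounds$end_sample,
           state = sched$state, run = sched$run, trial = sched$trial,
           segment = sched$segment),
    side$labels)
  rt <- recording$reaction_times
  readr::write_tsv(
    tibble(trial_index = seq_len(nrow(rt)), run = rt$run, trial = rt$trial,
           rt_seconds = rt$rt_s),
    side$trials)
  jsonlite::write_json(
    list(subject_id = recording$subject_id, sampling_rate_hz = fs,
         n_channels = nrow(recording$signal),
         channels = rownames(recording$signal)),
    side$meta, auto_unbox = TRUE, digits = NA)
  signal_path <- paste0(prefix, if (format == "delim") "_signal.tsv" else ".edf")
  if (format == "delim") {
    df <- as_tibble(t(recording$signal))
    readr::write_tsv(df, signal_path)
  } else {
    write_edf(recording$signal, fs, signal_path, patient = recording$subject_id)
  }
  invisible(c(signal = signal_path, unlist(side)))
}

#' Read a labeled recording from disk
#'
#' Counterpart of [write_recording()]: reads the signal (delimited text or
#' EDF) plus the label/trial/meta sidecars and rebuilds the
#' `labeled_recording`. Fails with an explicit message naming the expected
#' path when a sidecar is missing, when the EDF header sampling rate
#' disagrees with the sidecar metadata, or when the channel count does not
#' match `expect_channels`.
#'
#' @param prefix path prefix used when writing.
#' @param format `"delim"` (default) or `"edf"`.
#' @param expect_channels optional expected channel count.
#' @return a `labeled_recording`.
#' @export
read_recording <- function(prefix, format = c("delim", "edf"), expect_channels = NULL) {
  format <- match.arg(format)
  side <- sidecar_paths(prefix)
  for (p in unlist(side))
    if (!file.exists(p)) abort_("missing sidecar file: expected %s", p)
  meta <- jsonlite::read_json(side$meta, simplifyVector = TRUE)
  fs <- meta$sampling_rate_hz
  signal_path <- paste0(prefix, if (format == "delim") "_signal.tsv" else ".edf")
  if (!file.exists(signal_path)) abort_("missing signal file: expected %s", signal_path)
  if (format == "delim") {
    df <- readr::read_tsv(signal_path, show_col_types = FALSE, progress = FALSE)
    sig <- t(as.matrix(df))
  } else {
    edf <- read_edf(signal_path)
    if (abs(edf$sampling_rate_hz - fs) > 1e-9)
      abort_("EDF header sampling rate (%g Hz) disagrees with sidecar metadata (%g Hz)",
             edf$sampling_rate_hz, fs)
    sig <- edf$signal
  }
  if (!is.null(expect_channels) && nrow(sig) != expect_channels)
    abort_("expected %d channel(s) but %s has %d", expect_channels, signal_path, nrow(sig))
  labels_df <- readr::read_tsv(side$labels, show_col_types = FALSE, progress = FALSE)
  if (max(labels_df$end_sample) > ncol(sig))
    abort_("label intervals extend to sample %d but the signal has %d samples",
           max(labels_df$end_sample), ncol(sig))
  labels <- rep("none", ncol(sig))
  for (i in seq_len(nrow(labels_df)))
    labels[labels_df$start_sample[i]:labels_df$end_sample[i]] <- labels_df$state[i]
  sched <- tibble(
    run = as.integer(labels_df$run), trial = as.integer(labels_df$trial),
    state = labels_df$state,
    start_s = (labels_df$start_sample - 1L) / fs,
    end_s = labels_df$end_sample / fs,
    segment = labels_df$segment)
  trials <- readr::read_tsv(side$trials, show_col_types = FALSE, progress = FALSE)
  structure(list(
    signal = sig, sampling_rate_hz = fs, labels = labels, schedule = sched,
    reaction_times = tibble(run = as.integer(trials$run),
                            trial = as.integer(trials$trial),
                            rt_s = trials$rt_seconds),
    subject_id = meta$subject_id
  ), class = "labeled_recording")
}

# ---- minimal EDF (European Data Format) support ---------------------------
# Classic EDF: 256-byte fixed header + 256 bytes per signal, then 2-byte
# little-endian integer samples per data record. One data record per second
# here. No pre-installed R package reads EDF, so this is a from-scratch
# implementation of the published format (header fields are fixed-width
# ASCII).

pad_field <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = -width) # left-justified, space padded
}

write_edf <- function(signal, fs, path, patient = "X") {
  if (abs(fs - round(fs)) > 1e-9)
    abort_("EDF writer requires an integer sampling rate, got %g", fs)
  fs <- as.integer(round(fs))
  ns <- nrow(signal)
  # pad to whole 1 s records
  n_rec <- ceiling(ncol(signal) / fs)
  padded <- matrix(0, ns, n_rec * fs)
  padded[, seq_len(ncol(signal))] <- signal
  phys_min <- floor(apply(padded, 1, min))
  phys_max <- ceiling(apply(padded, 1, max))
  phys_max <- pmax(phys_max, phys_min + 1)
  dig_min <- -32768L; dig_max <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8), pad_field(patient, 80), pad_field("earesn synthetic", 80),
    pad_field("01.01.20", 8), pad_field("00.00.00", 8),
    pad_field(256 + 256 * ns, 8), pad_field("", 44),
    pad_field(n_rec, 8), pad_field(1, 8), pad_field(ns, 4))
  writeChar(hdr, con, eos = NULL)
  lab <- rownames(signal)
  if (is.null(lab)) lab <- paste0("ch", seq_len(ns))
  fields <- list(
    c(vapply(lab, pad_field, "", width = 16)),                 # label
    rep(pad_field("", 80), ns),                                # transducer
    rep(pad_field("uV", 8), ns),                               # physical dimension
    vapply(phys_min, pad_field, "", width = 8),
    vapply(phys_max, pad_field, "", width = 8),
    rep(pad_field(dig_min, 8), ns),
    rep(pad_field(dig_max, 8), ns),
    rep(pad_field("", 80), ns),                                # prefiltering
    rep(pad_field(fs, 8), ns),                                 # samples per record
    rep(pad_field("", 32), ns))                                # reserved
  for (f in fields) writeChar(paste0(f, collapse = ""), con, eos = NULL)
  gain <- (dig_max - dig_min) / (phys_max - phys_min)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (s in seq_len(ns)) {
      dig <- round((padded[s, idx] - phys_min[s]) * gain[s]) + dig_min
      writeBin(as.integer(pmin(pmax(dig, dig_min), dig_max)), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8) # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (!isTRUE(ns >= 1) || !isTRUE(n_rec >= 0)) abort_("corrupt EDF header in %s", path)
  lab <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  phys_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  phys_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dig_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dig_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1) abort_("EDF with per-signal sampling rates is not supported")
  sig <- matrix(0, ns, n_rec * spr[1])
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[s], size = 2, endian = "little", signed = TRUE)
      if (length(dig) != spr[s]) abort_("truncated EDF data in %s", path)
      sig[s, ((r - 1L) * spr[s] + 1L):(r * spr[s])] <- phys_min[s] + (dig - dig_min[s]) * gain[s]
    }
  }
  rownames(sig) <- lab
  list(signal = sig, sampling_rate_hz = spr[1] / rec_dur, n_records = n_rec)
}

# ---- feature matrices and reports -----------------------------------------

#' Write a feature tibble as delimited text
#'
#' @param features feature tibble from [extract_features()].
#' @param path output path (TSV, fixed header naming each feature).
#' @return invisibly, `path`.
#' @export
write_features <- function(features, path) {
  readr::write_tsv(features, path)
  invisible(path)
}

#' Read a feature tibble written by [write_features()]
#'
#' @param path TSV path.
#' @return feature tibble.
#' @export
read_features <- function(path) {
  if (!file.exists(path)) abort_("missing feature file: expected %s", path)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write a cross-validation result as a JSON report
#'
#' Serializes scheme, per-fold accuracies and selected hyperparameters, the
#' summary, and (optionally) the smoothing curve.
#'
#' @param cv an `esn_cv`.
#' @param path output JSON path.
#' @param windows smoothing windows to include, or NULL to skip the curve.
#' @return invisibly, `path`.
#' @export
write_cv_report <- function(cv, path, windows = 1:12) {
  report <- list(
    scheme = cv$scheme,
    summary = as.list(glance(cv)),
    folds = cv$folds
  )
  if (!is.null(windows)) report$smoothing_curve <- smoothing_curve(cv, windows)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
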