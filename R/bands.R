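#' Canonical EEG frequency bands
#'
#' The five-band partition used throughout the pipeline: delta 1-4 Hz,
#' theta 4-8 Hz, alpha 8-13 Hz, beta 13-30 Hz, gamma 30-50 Hz. Band
#' membership of a spectral bin is decided by `low_hz <= f < high_hz`.
#'
#' @return a tibble with columns `band`, `low_hz`, `high_hz` (one row per
#'   band, canonical order delta..gamma).
#' @export
#' @examples
#' eeg_bands()
eeg_bands <- function() {
  tibble(
    band    = c("delta", "theta", "alpha", "beta", "gamma"),
    low_hz  = c(1, 4, 8, 13, 30),
    high_hz = c(4, 8, 13, 30, 50)
  )
}

validate_bands <- function(bands) {
  if (!is.data.frame(bands) || !all(c("band", "low_hz", "high_hz") %in% names(bands)))
    abort_("`bands` must be a data frame with columns band, low_hz, high_hz")
  if (any(bands$low_hz >= bands$high_hz))
    abort_("each band must satisfy low_hz < high_hz")
  if (anyDuplicated(bands$band)) abort_("band names must be unique")
  as_tibble(bands)
}
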