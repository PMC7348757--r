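# Internal helpers: seed derivation and input checks.

#' Derive a reproducible child seed
#'
#' Folds a base seed and an arbitrary sequence of keys (stage names, subject
#' ids, fold indices, hyperparameter values) into a new 31-bit seed with a
#' multiplicative string hash. Used so that every source of randomness in the
#' pipeline flows deterministically from one user seed while distinct stages,
#' repeats and folds get distinct streams.
#'
#' @param seed integer base seed.
#' @param ... keys (coerced to character) identifying the consumer.
#' @return an integer seed in \[0, 2^31 - 2\].
#' @export
#' @examples
#' derive_seed(1, "grid", 0.3, 0.9, 2)
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  keys <- paste(vapply(list(...), function(p) paste(format(p, digits = 15), collapse = ","),
                       character(1)), collapse = "|")
  h <- abs(as.double(seed)) %% 2147483647
  for (v in utf8ToInt(keys)) h <- (h * 69069 + v) %% 2147483647
  as.integer(h)
}

# stop() with call.=FALSE and sprintf formatting
abort_ <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                             lower_open = FALSE, upper_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    abort_("`%s` must be a single finite number", name)
  if (x < lower || (lower_open && x == lower))
    abort_("`%s` must be %s %g", name, if (lower_open) ">" else ">=", lower)
  if (x > upper || (upper_open && x == upper))
    abort_("`%s` must be %s %g", name, if (upper_open) "<" else "<=", upper)
  invisible(x)
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0 && x == floor(x)

# columns of a feature tibble that are not feature values
META_COLS <- c("subject", "run", "trial", "segment", "state", "label", "t0_s", "t", "epoch")

#' Names of the feature columns of an epoch-by-feature tibble
#'
#' Feature tibbles produced by [extract_features()] carry bookkeeping columns
#' (subject, run, trial, segment, state, label, epoch timing) alongside the
#' numeric feature columns; this helper returns the feature column names.
#'
#' @param features a feature tibble.
#' @return character vector of feature column names, in stored order.
#' @export
feature_columns <- function(features) {
  setdiff(names(features), META_COLS)
}

feature_matrix_of <- function(features, cols = feature_columns(features)) {
  m <- as.matrix(features[, cols, drop = FALSE])
  if (!is.numeric(m)) abort_("feature columns must be numeric")
  m
}
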