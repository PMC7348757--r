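# Leaky echo state network: reservoir construction, state recursion,
# ridge-trained readout, sign classification, readout smoothing.

#' Reservoir configuration
#'
#' Hyperparameters of the fixed random reservoir. The recurrent weight
#' matrix has a fraction `connectivity` of nonzero entries drawn uniform in
#' \[-0.5, 0.5\] and is rescaled so its largest eigenvalue magnitude equals
#' `spectral_radius`. The state update is the leaky-integrator recursion
#' `x(t) = (1 - alpha) x(t-1) + alpha tanh(W_in u(t) + W x(t-1))` with
#' leaking rate `alpha` and tanh activation; no output feedback is used.
#'
#' @param n_internal number of internal units N (default 100).
#' @param connectivity fraction of nonzero recurrent weights, in (0, 1\]
#'   (default 0.1).
#' @param leaking_rate leaking rate alpha, in (0, 1\] (default 0.3).
#' @param spectral_radius target spectral radius lambda of the recurrent
#'   matrix, > 0; values at or slightly above 1 can work in practice, the
#'   grid used for optimization spans (0, 2\] (default 0.9).
#' @param input_scaling half-width sigma of the uniform input-weight
#'   distribution (default 1, for features already rescaled to \[-1, 1\]).
#' @param seed integer seed fixing W and W_in.
#' @return a `reservoir_config` list.
#' @export
reservoir_config <- function(n_internal = 100, connectivity = 0.1,
                             leaking_rate = 0.3, spectral_radius = 0.9,
                             input_scaling = 1, seed = 1L) {
  if (!is_count(n_internal) || n_internal < 1) abort_("`n_internal` must be a positive integer")
  check_scalar_num(connectivity, "connectivity", lower = 0, upper = 1, lower_open = TRUE)
  check_scalar_num(leaking_rate, "leaking_rate", lower = 0, upper = 1, lower_open = TRUE)
  check_scalar_num(spectral_radius, "spectral_radius", lower = 0, lower_open = TRUE)
  check_scalar_num(input_scaling, "input_scaling", lower = 0, lower_open = TRUE)
  structure(list(
    n_internal = as.integer(n_internal), connectivity = connectivity,
    leaking_rate = leaking_rate, spectral_radius = spectral_radius,
    input_scaling = input_scaling, seed = as.integer(seed)
  ), class = "reservoir_config")
}

#' Readout training configuration
#'
#' @param beta ridge (Tikhonov) regularization parameter; the default 1e-8
#'   is small enough to behave like plain least squares while avoiding its
#'   numerical instabilities.
#' @param washout number of initial steps of every input sequence excluded
#'   from readout fitting (default 0).
#' @param statistic score used when this config drives hyperparameter
#'   search: `"accuracy"` (default) or `"sse"` (sum of squared readout
#'   errors).
#' @return a `training_config` list.
#' @export
training_config <- function(beta = 1e-8, washout = 0,
                            statistic = c("accuracy", "sse")) {
  check_scalar_num(beta, "beta", lower = 0, lower_open = TRUE)
  if (!is_count(washout)) abort_("`washout` must be a non-negative integer")
  structure(list(beta = beta, washout = as.integer(washout),
                 statistic = match.arg(statistic)),
            class = "training_config")
}

#' Initialize an echo state network
#'
#' Draws the fixed weights: recurrent `W` (N x N, sparse, entries nonzero
#' with probability `connectivity`, uniform in \[-0.5, 0.5\], rescaled to
#' unit largest-eigenvalue magnitude and then multiplied by the target
#' spectral radius) and input `W_in` (N x (n_features + 1), uniform in
#' \[-sigma, sigma\]; the extra column multiplies a constant-1 input
#' component serving as bias). Both are deterministic given the config seed
#' and stay fixed during learning; only the readout is trained later.
#' If a draw yields a reservoir that cannot be rescaled (all-zero or
#' nilpotent, possible at tiny N x connectivity), it is redrawn with an
#' incremented seed and a warning.
#'
#' @param config a [reservoir_config()].
#' @param n_features input dimension (without the bias component).
#' @return an `esn_model`: list with `W_in`, `W` (a sparse
#'   [Matrix::Matrix()]), `W_out` (NULL until trained), `state`, `config`,
#'   `n_features`.
#' @export
init_reservoir <- function(config, n_features) {
  if (!inherits(config, "reservoir_config")) abort_("`config` must be a reservoir_config()")
  if (!is_count(n_features) || n_features < 1) abort_("`n_features` must be a positive integer")
  N <- config$n_internal
  seed <- config$seed
  repeat {
    W <- withr::with_seed(seed, {
      mask <- runif(N * N) < config$connectivity
      matrix(runif(N * N, -0.5, 0.5) * mask, N, N)
    })
    sr <- max(Mod(eigen(W, only.values = TRUE)$values))
    if (sr > 1e-12) break
    warning(sprintf("sampled reservoir has zero spectral radius (N=%d, c=%g); resampling with seed %d",
                    N, config$connectivity, seed + 1L), call. = FALSE)
    seed <- seed + 1L
  }
  W <- W * (config$spectral_radius / sr)
  W_in <- withr::with_seed(derive_seed(seed, "input"), {
    matrix(runif(N * (n_features + 1), -config$input_scaling, config$input_scaling),
           N, n_features + 1)
  })
  structure(list(
    W_in = W_in, W = Matrix::Matrix(W, sparse = TRUE), W_out = NULL,
    state = numeric(N), config = config, n_features = as.integer(n_features),
    feature_names = NULL
  ), class = "esn_model")
}

#' @export
print.esn_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<esn_model> N=%d, connectivity=%g, leaking rate=%g, spectral radius=%g, %d input features\n",
              cfg$n_internal, cfg$connectivity, cfg$leaking_rate, cfg$spectral_radius, x$n_features))
  cat(if (is.null(x$W_out)) "  readout: untrained\n"
      else sprintf("  readout: trained (%d weights)\n", length(x$W_out)))
  invisible(x)
}

#' One leaky-integrator state update
#'
#' Computes `x = (1 - alpha) x_prev + alpha tanh(W_in c(u, 1) + W x_prev)`.
#'
#' @param model an `esn_model`.
#' @param x_prev previous state, length N.
#' @param u input feature vector, length `n_features` (the bias component is
#'   appended internally).
#' @return the new state, length N.
#' @export
update_state <- function(model, x_prev, u) {
  if (length(u) != model$n_features) abort_("`u` must have length %d", model$n_features)
  if (length(x_prev) != model$config$n_internal)
    abort_("`x_prev` must have length %d", model$config$n_internal)
  if (!all(is.finite(u)) || !all(is.finite(x_prev))) abort_("non-finite inputs to update_state")
  a <- model$config$leaking_rate
  (1 - a) * x_prev + a * tanh(as.numeric(model$W_in %*% c(u, 1)) + as.numeric(model$W %*% x_prev))
}

#' Run the reservoir over one input sequence
#'
#' Iterates [update_state()] over the rows of `U` (time-ordered feature
#' vectors of one contiguous segment) starting from `x0`. The final state is
#' attached as attribute `"final_state"` so callers can thread it; the model
#' object itself is not mutated (functional semantics).
#'
#' @param model an `esn_model`.
#' @param U steps-by-features numeric matrix (possibly 0 rows).
#' @param x0 initial state (default: zeros).
#' @return steps-by-N matrix of states, attribute `"final_state"`.
#' @export
run_sequence <- function(model, U, x0 = NULL) {
  N <- model$config$n_internal
  if (is.null(x0)) x0 <- numeric(N)
  if (length(x0) != N) abort_("`x0` must have length %d", N)
  U <- as.matrix(U)
  Tn <- nrow(U)
  states <- matrix(0, Tn, N)
  if (Tn == 0) {
    attr(states, "final_state") <- x0
    return(states)
  }
  if (ncol(U) != model$n_features) abort_("`U` must have %d columns", model$n_features)
  if (!all(is.finite(U))) abort_("non-finite inputs in `U`")
  a <- model$config$leaking_rate
  Uin <- model$W_in %*% rbind(t(U), 1) # N x T, input drive precomputed
  W <- model$W
  x <- x0
  for (t in seq_len(Tn)) {
    x <- (1 - a) * x + a * tanh(Uin[, t] + as.numeric(W %*% x))
    states[t, ] <- x
  }
  attr(states, "final_state") <- x
  states
}

# ridge normal equations on an explicit design matrix
ridge_solve <- function(X, y, beta) {
  A <- crossprod(X)
  diag(A) <- diag(A) + beta
  as.numeric(solve(A, crossprod(X, y)))
}

#' Train the linear readout by ridge regression
#'
#' Builds the readout design rows as the concatenation `(u(t), 1, x(t))` of
#' input, bias and reservoir state, and solves the Tikhonov-regularized
#' normal equations for the readout weights. Only the readout is learned;
#' `W_in` and `W` are untouched.
#'
#' @param states steps-by-N state matrix from [run_sequence()].
#' @param inputs steps-by-features input matrix (same rows as `states`).
#' @param targets numeric targets per step (+1 attentive / -1 rest).
#' @param tc a [training_config()]; `washout` initial rows are dropped
#'   before fitting.
#' @return numeric readout weight vector `W_out`, length
#'   `n_features + 1 + N`.
#' @export
train_readout <- function(states, inputs, targets, tc = training_config()) {
  states <- as.matrix(states); inputs <- as.matrix(inputs)
  if (nrow(states) != nrow(inputs) || nrow(states) != length(targets))
    abort_("states, inputs and targets must have matching row counts")
  keep <- seq_len(nrow(states))
  if (tc$washout > 0) {
    if (tc$washout >= nrow(states)) abort_("washout leaves no rows to fit")
    keep <- keep[-seq_len(tc$washout)]
  }
  if (length(keep) < 1) abort_("need at least one row to fit the readout")
  X <- cbind(inputs[keep, , drop = FALSE], 1, states[keep, , drop = FALSE])
  ridge_solve(X, targets[keep], tc$beta)
}

# order a feature tibble into per-segment input matrices (time order)
segment_inputs <- function(features) {
  cols <- feature_columns(features)
  req <- c("segment", "t", "label")
  if (!all(req %in% names(features)))
    abort_("feature tibble must have columns %s", paste(req, collapse = ", "))
  features <- arrange(features, .data$segment, .data$t)
  split_idx <- split(seq_len(nrow(features)), features$segment)
  m <- feature_matrix_of(features, cols)
  lapply(split_idx, function(i)
    list(U = m[i, , drop = FALSE], labels = features$label[i], rows = i))
}

#' Fit an echo state network on a standardized feature tibble
#'
#' High-level training entry point: the rows of `features` are grouped into
#' contiguous segments (a run's attention stream or a rest block), the
#' reservoir is run over each segment from a zero state (state resets at
#' segment boundaries so no label information crosses them), and one ridge
#' readout is fitted on all resulting `(u, 1, x)` rows against the +1/-1
#' labels.
#'
#' @param features standardized feature tibble with `segment`, `t` and
#'   `label` columns (see [extract_features()], [apply_standardizer()]).
#' @param reservoir a [reservoir_config()].
#' @param training a [training_config()].
#' @return a trained `esn_model` (with `W_out`, `feature_names`,
#'   `train_accuracy`, `n_train`).
#' @export
fit_esn <- function(features, reservoir = reservoir_config(),
                    training = training_config()) {
  cols <- feature_columns(features)
  model <- init_reservoir(reservoir, length(cols))
  segs <- segment_inputs(features)
  X_parts <- vector("list", length(segs))
  y_parts <- vector("list", length(segs))
  for (i in seq_along(segs)) {
    st <- run_sequence(model, segs[[i]]$U)
    keep <- seq_len(nrow(st))
    if (training$washout > 0 && training$washout < length(keep))
      keep <- keep[-seq_len(training$washout)]
    X_parts[[i]] <- cbind(segs[[i]]$U[keep, , drop = FALSE], 1, st[keep, , drop = FALSE])
    y_parts[[i]] <- segs[[i]]$labels[keep]
  }
  X <- do.call(rbind, X_parts)
  y <- unlist(y_parts)
  if (length(y) < 1) abort_("no rows to fit the readout")
  model$W_out <- ridge_solve(X, y, training$beta)
  model$feature_names <- cols
  model$training <- training
  yhat <- as.numeric(X %*% model$W_out)
  model$train_accuracy <- mean(classify_readout(yhat) == y)
  model$train_sse <- sum((yhat - y)^2)
  model$n_train <- length(y)
  model
}

#' Readout trace for one input sequence
#'
#' Runs the reservoir over `U` from `x0` and returns the real-valued readout
#' `y(t) = W_out (u(t), 1, x(t))` per step; classification is separate
#' ([classify_readout()]).
#'
#' @inheritParams run_sequence
#' @return numeric readout values, one per row of `U`.
#' @export
predict_readout <- function(model, U, x0 = NULL) {
  if (is.null(model$W_out)) abort_("model has no trained readout")
  U <- as.matrix(U)
  st <- run_sequence(model, U, x0)
  X <- cbind(U, 1, st)
  as.numeric(X %*% model$W_out)
}

#' Predict attention states for a feature tibble
#'
#' Groups `newdata` into contiguous segments, computes the readout trace per
#' segment (reservoir restarted from zero at each segment boundary),
#' optionally smooths it causally, and thresholds at zero.
#'
#' @param object a trained `esn_model`.
#' @param newdata standardized feature tibble.
#' @param smooth_n causal moving-average window in outputs (default 1 = no
#'   smoothing).
#' @param ... unused.
#' @return the bookkeeping columns of `newdata` plus `.readout`,
#'   `.smoothed` and `.pred` (+1/-1).
#' @export
predict.esn_model <- function(object, newdata, smooth_n = 1, ...) {
  if (is.null(object$W_out)) abort_("model has no trained readout")
  cols <- feature_columns(newdata)
  if (!identical(sort(cols), sort(object$feature_names)))
    abort_("feature columns of `newdata` do not match the fitted model")
  newdata <- arrange(newdata, .data$segment, .data$t)
  segs <- segment_inputs(newdata)
  y <- numeric(nrow(newdata))
  ys <- numeric(nrow(newdata))
  for (s in segs) {
    # keep the model's stored column order
    tr <- predict_readout(object, s$U[, match(object$feature_names, cols), drop = FALSE])
    y[s$rows] <- tr
    ys[s$rows] <- smooth_readout(tr, smooth_n)
  }
  out <- newdata[, intersect(META_COLS, names(newdata)), drop = FALSE]
  out$.readout <- y
  out$.smoothed <- ys
  out$.pred <- classify_readout(ys)
  as_tibble(out)
}

#' Sign-threshold classification of readout values
#'
#' Positive readout values are classified attentive (+1), negative resting
#' (-1). An exact zero is classified resting: the conservative class for an
#' attention monitor, and a measure-zero event.
#'
#' @param y numeric readout values.
#' @return integer labels in \{+1, -1\}.
#' @export
classify_readout <- function(y) {
  ifelse(y > 0, 1L, -1L)
}

#' Causal moving-average smoothing of a readout trace
#'
#' Each output is replaced by the mean of itself and the `n - 1` previous
#' outputs; at the start of the trace, where fewer previous outputs exist,
#' the mean runs over every available output (trailing edge only, causal:
#' no future samples are used).
#'
#' @param y numeric readout trace (one contiguous segment).
#' @param n window size in outputs, >= 1 (each output spans 0.5 s).
#' @return smoothed trace, same length as `y`.
#' @export
smooth_readout <- function(y, n = 1) {
  if (!is_count(n) || n < 1) abort_("`n` must be a positive integer")
  Tn <- length(y)
  if (Tn == 0) return(numeric(0))
  if (n == 1) return(y)
  s <- cumsum(y)
  lagged <- c(rep(0, min(n, Tn)), s[seq_len(max(0, Tn - n))])
  (s - lagged) / pmin(seq_len(Tn), n)
}

#' @export
tidy.esn_model <- function(x, ...) {
  if (is.null(x$W_out)) abort_("model has no trained readout")
  N <- x$config$n_internal
  tibble(
    term = c(x$feature_names %||% paste0("u", seq_len(x$n_features)), "(bias)",
             paste0("x", seq_len(N))),
    component = c(rep("input", x$n_features), "bias", rep("reservoir", N)),
    estimate = x$W_out
  )
}

#' @export
glance.esn_model <- function(x, ...) {
  tibble(
    n_internal = x$config$n_internal, connectivity = x$config$connectivity,
    leaking_rate = x$config$leaking_rate, spectral_radius = x$config$spectral_radius,
    input_scaling = x$config$input_scaling, beta = x$training$beta %||% NA_real_,
    n_train = x$n_train %||% NA_integer_,
    train_accuracy = x$train_accuracy %||% NA_real_
  )
}
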