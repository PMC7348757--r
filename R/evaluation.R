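# Cross-validation protocols, trial exclusion, grid search, sweeps.

#' Reaction-time exclusion rule
#'
#' Attended trials are excluded when the reaction time is too short (false
#' start, < 100 ms) or too long (lapse, > mean(RT) + 3 sd(RT), statistics
#' computed over all of the subject's trials before any exclusion).
#'
#' @param false_start_threshold_s false-start threshold in seconds
#'   (default 0.1).
#' @param lapse_sd_multiplier lapse threshold in SDs above the mean
#'   (default 3).
#' @return an `exclusion_rule` list.
#' @export
exclusion_rule <- function(false_start_threshold_s = 0.1, lapse_sd_multiplier = 3) {
  check_scalar_num(false_start_threshold_s, "false_start_threshold_s", lower = 0, lower_open = TRUE)
  check_scalar_num(lapse_sd_multiplier, "lapse_sd_multiplier", lower = 0, lower_open = TRUE)
  structure(list(false_start_threshold_s = false_start_threshold_s,
                 lapse_sd_multiplier = lapse_sd_multiplier),
            class = "exclusion_rule")
}

#' Keep mask for attended trials
#'
#' Applies the false-start and lapse rules to one subject's reaction times.
#' The lapse statistics (mean and SD) are computed over all supplied trials.
#'
#' @param rts numeric reaction times in seconds, one per trial (>= 1).
#' @param rule an [exclusion_rule()].
#' @return logical vector: TRUE where the trial is kept.
#' @export
#' @examples
#' exclude_trials(c(0.35, 0.40, 0.05, 0.41)) # the 0.05 s false start drops
exclude_trials <- function(rts, rule = exclusion_rule()) {
  if (!is.numeric(rts) || length(rts) < 1) abort_("`rts` must contain at least one trial")
  m <- mean(rts)
  s <- sd(rts) # NA for a single trial: lapse rule cannot fire then
  lapse_thr <- if (is.na(s)) Inf else m + rule$lapse_sd_multiplier * s
  keep <- !(rts < rule$false_start_threshold_s | rts > lapse_thr)
  if (!any(keep))
    abort_("all %d trials excluded (mean RT %.3f s, lapse threshold %.3f s)",
           length(rts), m, lapse_thr)
  keep
}

#' Drop attentive epochs of excluded trials
#'
#' Applies [exclude_trials()] per subject and removes attentive epochs that
#' belong to excluded trials from the feature tibble; rest epochs are never
#' excluded (the rules concern attended trials only). Exclusion happens
#' before any cross-validation split, so excluded trials appear in neither
#' training nor test pools.
#'
#' @param features feature tibble (possibly several subjects).
#' @param reaction_times tibble with columns `subject`, `run`, `trial`,
#'   `rt_s`, or the `reaction_times` element of a single recording (then
#'   `subject` is optional).
#' @param rule an [exclusion_rule()].
#' @return the filtered feature tibble, with attribute `"n_excluded"` (trials
#'   dropped per subject).
#' @export
filter_attended <- function(features, reaction_times, rule = exclusion_rule()) {
  rt <- as_tibble(reaction_times)
  if (!"subject" %in% names(rt)) {
    subj <- unique(features$subject)
    if (length(subj) != 1)
      abort_("`reaction_times` lacks a subject column but `features` has %d subjects", length(subj))
    rt$subject <- subj
  }
  rt <- rt %>%
    group_by(.data$subject) %>%
    mutate(keep = exclude_trials(.data$rt_s, rule)) %>%
    ungroup()
  dropped <- rt %>% filter(!.data$keep) %>% select("subject", "run", "trial")
  out <- features %>%
    anti_join(dropped, by = c("subject", "run", "trial"))
  n_excl <- table(dropped$subject)
  attr(out, "n_excluded") <- n_excl
  out
}

#' Grid-search specification for leaking rate and spectral radius
#'
#' The optimization grid: leaking rate over (0, 1\] and spectral radius over
#' (0, 2\], both in steps of 0.1 by default (10 x 20 = 200 combinations),
#' each combination evaluated with `repeats` independently seeded reservoirs
#' and scored by the mean over repeats.
#'
#' @param leaking_rates candidate leaking rates.
#' @param spectral_radii candidate spectral radii.
#' @param repeats reservoirs evaluated per combination (default 10).
#' @return a `grid_search_spec` list.
#' @export
grid_search_spec <- function(leaking_rates = seq(0.1, 1, by = 0.1),
                             spectral_radii = seq(0.1, 2, by = 0.1),
                             repeats = 10) {
  if (!is.numeric(leaking_rates) || !length(leaking_rates) ||
      any(leaking_rates <= 0 | leaking_rates > 1))
    abort_("`leaking_rates` must lie in (0, 1]")
  if (!is.numeric(spectral_radii) || !length(spectral_radii) || any(spectral_radii <= 0))
    abort_("`spectral_radii` must be positive")
  if (!is_count(repeats) || repeats < 1) abort_("`repeats` must be a positive integer")
  if (anyDuplicated(leaking_rates) || anyDuplicated(spectral_radii))
    abort_("grid values must be unique")
  structure(list(leaking_rates = leaking_rates, spectral_radii = spectral_radii,
                 repeats = as.integer(repeats)),
            class = "grid_search_spec")
}

#' Reservoir size/connectivity sweep specification
#'
#' Defaults reproduce the small-reservoir sweep (N = 10..100 step 10 by 11
#' connectivities, 110 configurations); `large = TRUE` gives the
#' large-reservoir sweep (N = 100..1000 step 100 by c in \{0.01, 0.1\},
#' 20 configurations).
#'
#' @param n_internal candidate reservoir sizes.
#' @param connectivity candidate connectivities in (0, 1\].
#' @param repeats reservoirs evaluated per configuration (default 10).
#' @param large use the large-reservoir defaults.
#' @return a `sweep_spec` list.
#' @export
sweep_spec <- function(n_internal = NULL, connectivity = NULL, repeats = 10,
                       large = FALSE) {
  if (is.null(n_internal))
    n_internal <- if (large) seq(100, 1000, by = 100) else seq(10, 100, by = 10)
  if (is.null(connectivity))
    connectivity <- if (large) c(0.01, 0.1) else c(0.01, seq(0.1, 1, by = 0.1))
  if (any(n_internal < 1) || any(n_internal != floor(n_internal)))
    abort_("`n_internal` must be positive integers")
  if (any(connectivity <= 0 | connectivity > 1)) abort_("`connectivity` must lie in (0, 1]")
  if (anyDuplicated(n_internal) || anyDuplicated(connectivity))
    abort_("sweep values must be unique")
  if (!is_count(repeats) || repeats < 1) abort_("`repeats` must be a positive integer")
  structure(list(n_internal = as.integer(n_internal), connectivity = connectivity,
                 repeats = as.integer(repeats)),
            class = "sweep_spec")
}

#' Classification accuracy
#'
#' Fraction of positions where predicted and true +1/-1 labels agree.
#'
#' @param predicted,truth equal-length vectors of +1/-1 labels.
#' @return a fraction in \[0, 1\].
#' @export
accuracy <- function(predicted, truth) {
  if (length(predicted) == 0) abort_("cannot compute accuracy of zero predictions")
  if (length(predicted) != length(truth)) abort_("label vectors must have equal length")
  if (!all(c(predicted, truth) %in% c(-1, 1))) abort_("labels must be +1 or -1")
  mean(predicted == truth)
}

# score one hyperparameter combination: mean statistic over `repeats`
# independently seeded reservoirs trained on `features` (training rows only)
score_combo <- function(features, reservoir, training, repeats, seed, keys) {
  vals <- vapply(seq_len(repeats), function(r) {
    cfg <- reservoir
    cfg$seed <- derive_seed(seed, keys, r)
    fit <- fit_esn(features, cfg, training)
    if (training$statistic == "sse") fit$train_sse else fit$train_accuracy
  }, numeric(1))
  mean(vals)
}

#' Grid search over leaking rate and spectral radius
#'
#' Scores every (leaking rate, spectral radius) combination on the supplied
#' (training-side) features with `repeats` independently seeded reservoirs
#' and returns the combination with the best mean score (highest accuracy,
#' or lowest SSE when `training$statistic == "sse"`). Ties are broken toward
#' the smaller spectral radius, then the smaller leaking rate: the more
#' contractive, more stable reservoir.
#'
#' @param features standardized training feature tibble.
#' @param spec a [grid_search_spec()].
#' @param reservoir base [reservoir_config()] supplying N, connectivity and
#'   input scaling.
#' @param training a [training_config()].
#' @param seed integer seed; reservoir seeds are derived from it per
#'   combination and repeat.
#' @return an `esn_grid`: list with `best` (one-row tibble), `table` (one
#'   row per combination with its mean score) and `statistic`.
#' @export
grid_search <- function(features, spec = grid_search_spec(),
                        reservoir = reservoir_config(),
                        training = training_config(), seed = 1L) {
  if (!inherits(spec, "grid_search_spec")) abort_("`spec` must be a grid_search_spec()")
  combos <- tidyr::expand_grid(leaking_rate = spec$leaking_rates,
                               spectral_radius = spec$spectral_radii)
  combos$score <- vapply(seq_len(nrow(combos)), function(i) {
    cfg <- reservoir
    cfg$leaking_rate <- combos$leaking_rate[i]
    cfg$spectral_radius <- combos$spectral_radius[i]
    score_combo(features, cfg, training, spec$repeats, seed,
                keys = sprintf("grid|%g|%g", cfg$leaking_rate, cfg$spectral_radius))
  }, numeric(1))
  ord <- order(if (training$statistic == "sse") combos$score else -combos$score,
               combos$spectral_radius, combos$leaking_rate)
  structure(list(best = combos[ord[1], ], table = combos,
                 statistic = training$statistic),
            class = "esn_grid")
}

#' @export
print.esn_grid <- function(x, ...) {
  cat(sprintf("<esn_grid> %d combinations, statistic = %s\n", nrow(x$table), x$statistic))
  cat(sprintf("  best: leaking rate %g, spectral radius %g (score %.4f)\n",
              x$best$leaking_rate, x$best$spectral_radius, x$best$score))
  invisible(x)
}

#' Sweep reservoir size and connectivity
#'
#' Scores every (N, connectivity) configuration at fixed leaking rate and
#' spectral radius (taken from `reservoir`), with the same repeat-averaged
#' statistic as [grid_search()].
#'
#' @param features standardized training feature tibble.
#' @param spec a [sweep_spec()].
#' @inheritParams grid_search
#' @return tibble with columns `n_internal`, `connectivity`, `score`.
#' @export
reservoir_sweep <- function(features, spec = sweep_spec(),
                            reservoir = reservoir_config(),
                            training = training_config(), seed = 1L) {
  if (!inherits(spec, "sweep_spec")) abort_("`spec` must be a sweep_spec()")
  combos <- tidyr::expand_grid(n_internal = spec$n_internal,
                               connectivity = spec$connectivity)
  combos$score <- vapply(seq_len(nrow(combos)), function(i) {
    cfg <- reservoir
    cfg$n_internal <- combos$n_internal[i]
    cfg$connectivity <- combos$connectivity[i]
    score_combo(features, cfg, training, spec$repeats, seed,
                keys = sprintf("sweep|%d|%g", cfg$n_internal, cfg$connectivity))
  }, numeric(1))
  combos
}

# one CV fold: standardize on train, grid-search on train, fit the final
# model on train, predict both sides. Test rows are touched only by
# apply_standardizer/predict, never by any fitting function.
run_fold <- function(train, test, fold_id, grid, reservoir, training, seed,
                     keep_models = FALSE) {
  std <- fit_standardizer(train)
  train_s <- apply_standardizer(train, std)
  test_s <- apply_standardizer(test, std)
  gs <- grid_search(train_s, grid, reservoir, training,
                    seed = derive_seed(seed, "grid", fold_id))
  cfg <- reservoir
  cfg$leaking_rate <- gs$best$leaking_rate
  cfg$spectral_radius <- gs$best$spectral_radius
  cfg$seed <- derive_seed(seed, "final", fold_id)
  final <- fit_esn(train_s, cfg, training)
  pred <- predict(final, test_s)
  pred$fold <- fold_id
  list(
    fold = tibble(
      fold = fold_id, n_train = nrow(train), n_test = nrow(test),
      leaking_rate = gs$best$leaking_rate, spectral_radius = gs$best$spectral_radius,
      train_accuracy = final$train_accuracy,
      test_accuracy = accuracy(pred$.pred, pred$label)
    ),
    predictions = pred,
    model = if (keep_models) list(model = final, standardizer = std, grid = gs)
  )
}

new_esn_cv <- function(scheme, folds, predictions, models = NULL) {
  structure(list(scheme = scheme, folds = folds, predictions = predictions,
                 models = models),
            class = "esn_cv")
}

#' @export
print.esn_cv <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<esn_cv> %s: %d folds, mean test accuracy %.3f +/- %.3f (SEM)\n",
              x$scheme, g$n_folds, g$mean_test_accuracy, g$sem_test_accuracy))
  invisible(x)
}

#' @export
tidy.esn_cv <- function(x, ...) x$folds

#' @export
glance.esn_cv <- function(x, ...) {
  f <- x$folds
  tibble(
    scheme = x$scheme, n_folds = nrow(f),
    mean_train_accuracy = mean(f$train_accuracy),
    mean_test_accuracy = mean(f$test_accuracy),
    sem_test_accuracy = sd(f$test_accuracy) / sqrt(nrow(f)),
    n_test = sum(f$n_test)
  )
}

#' Within-subject (leave-one-run-out) cross-validation
#'
#' For a single subject with K runs, fold i tests on run i (its attention
#' stream and its paired rest block) and trains on the remaining K - 1 runs.
#' Per fold, the feature standardizer is fitted on the training runs only
#' and the leaking rate and spectral radius are chosen by [grid_search()] on
#' the training side; accuracies are averaged over the K folds.
#'
#' @param features feature tibble of one subject (raw, unstandardized).
#' @param grid a [grid_search_spec()].
#' @param reservoir base [reservoir_config()].
#' @param training a [training_config()].
#' @param seed integer seed driving all fold-level randomness.
#' @param keep_models keep per-fold fitted models/standardizers (for
#'   auditing; default FALSE).
#' @return an `esn_cv` (see [tidy()], [glance()], [smoothing_curve()]).
#' @export
within_subject_cv <- function(features, grid = grid_search_spec(),
                              reservoir = reservoir_config(),
                              training = training_config(), seed = 1L,
                              keep_models = FALSE) {
  subj <- unique(features$subject)
  if (length(subj) != 1) abort_("within-subject CV expects exactly one subject, got %d", length(subj))
  runs <- sort(unique(features$run))
  if (length(runs) < 2) abort_("need at least 2 runs for leave-one-run-out CV")
  folds <- list(); preds <- list(); models <- list()
  for (r in runs) {
    test <- features[features$run == r, , drop = FALSE]
    train <- features[features$run != r, , drop = FALSE]
    if (nrow(test) == 0) {
      warning(sprintf("run %s has no surviving epochs; fold skipped", r), call. = FALSE)
      next
    }
    res <- run_fold(train, test, fold_id = r, grid, reservoir, training, seed, keep_models)
    folds[[length(folds) + 1L]] <- res$fold
    preds[[length(preds) + 1L]] <- res$predictions
    if (keep_models) models[[as.character(r)]] <- res$model
  }
  new_esn_cv("within_subject", bind_rows(folds), bind_rows(preds),
             if (keep_models) models)
}

#' Cross-subject (leave-one-subject-out) cross-validation
#'
#' One fold per subject: that subject's epochs are the test set and the
#' remaining subjects' epochs the training set. Standardizer and
#' hyperparameters come from the training subjects only.
#'
#' @param features feature tibble of >= 2 subjects.
#' @inheritParams within_subject_cv
#' @return an `esn_cv`.
#' @export
cross_subject_cv <- function(features, grid = grid_search_spec(),
                             reservoir = reservoir_config(),
                             training = training_config(), seed = 1L,
                             keep_models = FALSE) {
  subjects <- sort(unique(features$subject))
  if (length(subjects) < 2) abort_("cross-subject CV needs at least 2 subjects")
  folds <- list(); preds <- list(); models <- list()
  for (s in subjects) {
    test <- features[features$subject == s, , drop = FALSE]
    train <- features[features$subject != s, , drop = FALSE]
    res <- run_fold(train, test, fold_id = s, grid, reservoir, training, seed, keep_models)
    folds[[length(folds) + 1L]] <- res$fold
    preds[[length(preds) + 1L]] <- res$predictions
    if (keep_models) models[[s]] <- res$model
  }
  new_esn_cv("cross_subject", bind_rows(folds), bind_rows(preds),
             if (keep_models) models)
}

#' Pooled k-fold cross-validation
#'
#' Epochs from all subjects are pooled and randomly partitioned into k folds
#' of near-equal size (differing by at most one); fold i tests on partition
#' i and trains on the rest, so 90% of the data train and 10% test at
#' k = 10. Reservoir input sequences are formed from the time-ordered
#' training (resp. test) subsequence of each contiguous segment, so test
#' rows never influence training states. The random partition ignores run
#' boundaries, so temporally adjacent epochs can fall on opposite sides of
#' a split; the optimism this induces is inherent to the scheme.
#'
#' @param features pooled feature tibble.
#' @param k number of folds (default 10).
#' @inheritParams within_subject_cv
#' @return an `esn_cv`.
#' @export
kfold_cv <- function(features, k = 10, grid = grid_search_spec(),
                     reservoir = reservoir_config(),
                     training = training_config(), seed = 1L,
                     keep_models = FALSE) {
  if (!is_count(k) || k < 2) abort_("`k` must be an integer >= 2")
  n <- nrow(features)
  if (n < k) abort_("need at least k = %d epochs, got %d", k, n)
  assignment <- withr::with_seed(derive_seed(seed, "kfold-partition"),
                                 sample(rep_len(seq_len(k), n)))
  folds <- list(); preds <- list(); models <- list()
  for (i in seq_len(k)) {
    test <- features[assignment == i, , drop = FALSE]
    train <- features[assignment != i, , drop = FALSE]
    res <- run_fold(train, test, fold_id = i, grid, reservoir, training, seed, keep_models)
    folds[[length(folds) + 1L]] <- res$fold
    preds[[length(preds) + 1L]] <- res$predictions
    if (keep_models) models[[as.character(i)]] <- res$model
  }
  cv <- new_esn_cv("kfold", bind_rows(folds), bind_rows(preds),
                   if (keep_models) models)
  cv$assignment <- assignment
  cv
}

#' Accuracy as a function of the smoothing window
#'
#' Re-thresholds the stored raw test readout traces of a cross-validation
#' result after causal moving-average smoothing at each window size, without
#' retraining: per fold and contiguous segment the trace is smoothed with
#' [smooth_readout()], classified, and fold accuracies are averaged. Window
#' size 1 reproduces the unsmoothed accuracy exactly.
#'
#' @param cv an `esn_cv` with stored predictions.
#' @param windows window sizes in outputs (default 1:12, i.e. 0.5 to 6 s).
#' @return tibble with columns `window`, `accuracy`.
#' @export
smoothing_curve <- function(cv, windows = 1:12) {
  if (!inherits(cv, "esn_cv")) abort_("`cv` must be an esn_cv result")
  p <- cv$predictions
  if (is.null(p) || nrow(p) == 0 || !".readout" %in% names(p))
    abort_("cross-validation result has no stored readout traces")
  p <- arrange(p, .data$fold, .data$segment, .data$t)
  purrr::map_dfr(windows, function(n) {
    acc <- p %>%
      group_by(.data$fold, .data$segment) %>%
      mutate(.sm = smooth_readout(.data$.readout, n)) %>%
      group_by(.data$fold) %>%
      summarise(acc = accuracy(classify_readout(.data$.sm), .data$label),
                .groups = "drop")
    tibble(window = n, accuracy = mean(acc$acc))
  })
}
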