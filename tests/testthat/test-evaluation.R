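# Trial exclusion, CV schemes, grid search, sweeps, smoothing curve

test_that("reaction-time exclusion applies both rules over all trials", {
  expect_true(all(exclude_trials(c(0.35, 0.40, 0.38, 0.41))))
  rts <- c(0.35, 0.40, 0.05, 0.38)
  expect_identical(which(!exclude_trials(rts)), 3L)
  # brute-force oracle on 100 simulated RTs with planted lapses
  rts2 <- withr::with_seed(3, {
    x <- rnorm(100, 0.4, 0.05)
    x[c(10, 50)] <- c(1.6, 1.9)
    x[77] <- 0.02
    x
  })
  expect_identical(exclude_trials(rts2), brute_exclusion(rts2))
  expect_error(exclude_trials(c(0.01, 0.02)), "excluded")
})

test_that("attentive epochs of excluded trials are dropped; rest epochs never are", {
  rec <- quick_recording(seed = 8)
  f <- extract_features(rec, prefilter = NULL)
  rt <- rec$reaction_times
  rt$rt_s <- rep(0.4, nrow(rt)) # neutralize random false starts/lapses
  rt$rt_s[2] <- 0.05 # plant a false start in run 1, trial 2
  f2 <- filter_attended(f, rt)
  expect_true(nrow(f2) < nrow(f))
  expect_equal(sum(f$label == -1), sum(f2$label == -1))
  dropped <- dplyr::anti_join(f, f2, by = names(f))
  expect_true(all(dropped$run == rt$run[2] & dropped$trial == rt$trial[2]))
})

test_that("accuracy is the agreement fraction", {
  expect_equal(accuracy(c(1, -1, 1), c(1, -1, 1)), 1)
  expect_equal(accuracy(c(1, -1), c(-1, 1)), 0)
  p <- withr::with_seed(4, sample(c(-1, 1), 1000, replace = TRUE))
  y <- withr::with_seed(5, sample(c(-1, 1), 1000, replace = TRUE))
  expect_equal(accuracy(p, y), sum(p == y) / 1000)
  expect_error(accuracy(numeric(0), numeric(0)), "zero")
  expect_error(accuracy(c(1, 0), c(1, 1)), "labels")
})

test_that("grid search scores every combination and returns the argmax", {
  f <- cluster_features(n_segments = 4, seg_len = 8, n_feat = 5)
  res <- reservoir_config(n_internal = 10, seed = 1)
  spec <- grid_search_spec(c(0.3, 0.7), c(0.5, 0.9, 1.3), repeats = 2)
  gs <- suppressWarnings(grid_search(f, spec, res, seed = 6))
  expect_equal(nrow(gs$table), 6)
  # argmax self-consistency with the documented tie-break
  ord <- order(-gs$table$score, gs$table$spectral_radius, gs$table$leaking_rate)
  expect_equal(gs$best, gs$table[ord[1], ])
  expect_true(all(gs$best$score >= gs$table$score))
  # degenerate single-point grid returns that point
  gs1 <- suppressWarnings(grid_search(f, grid_search_spec(0.4, 1.1, repeats = 1), res, seed = 6))
  expect_equal(gs1$best$leaking_rate, 0.4)
  expect_equal(gs1$best$spectral_radius, 1.1)
  expect_error(grid_search_spec(c(0.3, 0.3), 0.9), "unique")
})

test_that("grid search selection tracks a finer exhaustive scoring of the same data", {
  f <- cluster_features(n_segments = 6, seg_len = 12, n_feat = 5, delta = 0.8, seed = 9)
  res <- reservoir_config(n_internal = 20, seed = 1)
  coarse <- grid_search(f, grid_search_spec(0.3, seq(0.3, 1.5, 0.3), repeats = 2),
                        res, seed = 7)
  fine <- grid_search(f, grid_search_spec(0.3, seq(0.3, 1.5, 0.15), repeats = 2),
                      res, seed = 7)
  expect_lte(abs(coarse$best$spectral_radius - fine$best$spectral_radius), 0.3)
})

test_that("reservoir sweeps cover the requested configuration table", {
  f <- cluster_features(n_segments = 4, seg_len = 8, n_feat = 5)
  spec <- sweep_spec(n_internal = c(10, 20), connectivity = c(0.1, 0.5, 1), repeats = 1)
  sw <- reservoir_sweep(f, spec, reservoir_config(seed = 1), seed = 8)
  expect_equal(nrow(sw), 6)
  expect_equal(nrow(dplyr::distinct(sw[, c("n_internal", "connectivity")])), 6)
  expect_true(all(sw$score >= 0 & sw$score <= 1))
  expect_error(sweep_spec(n_internal = c(10, 10)), "unique")
  # the default and large specs have the documented shapes
  expect_equal(nrow(tidyr::expand_grid(sweep_spec()$n_internal,
                                       sweep_spec()$connectivity)), 110)
  expect_equal(nrow(tidyr::expand_grid(sweep_spec(large = TRUE)$n_internal,
                                       sweep_spec(large = TRUE)$connectivity)), 20)
})

test_that("within-subject CV leaves one run out per fold", {
  rec <- quick_recording(seed = 12, n_runs = 3)
  f <- extract_features(rec, prefilter = NULL)
  cv <- within_subject_cv(f, point_grid(), seed = 1)
  expect_equal(sort(cv$folds$fold), sort(unique(f$run)))
  expect_equal(nrow(cv$folds), 3)
  expect_true(all(cv$folds$test_accuracy >= 0 & cv$folds$test_accuracy <= 1))
  # fold test sets partition the epochs
  expect_equal(sort(unique(cv$predictions$run)), sort(unique(f$run)))
  expect_equal(nrow(cv$predictions), nrow(f))
  expect_error(within_subject_cv(f[f$run == 1, ], point_grid()), "at least 2 runs")
  f2 <- f; f2$subject <- rep(c("a", "b"), length.out = nrow(f))
  expect_error(within_subject_cv(f2, point_grid()), "one subject")
})

test_that("cross-subject CV tests each subject exactly once on held-out training", {
  recs <- simulate_cohort(3, quick_config(seed = 13))
  f <- purrr::map_dfr(recs, extract_features, prefilter = NULL)
  cv <- cross_subject_cv(f, point_grid(), seed = 2)
  expect_equal(sort(cv$folds$fold), sort(names(recs)))
  expect_equal(nrow(cv$folds), 3)
  expect_error(cross_subject_cv(f[f$subject == "s01", ], point_grid()), "2 subjects")
})

test_that("cross-subject accuracy degrades when subjects have disjoint effect profiles", {
  cfg <- quick_config(seed = 14, n_runs = 2)
  reversed <- band_effect_profile( # alpha rises with attention instead of rest
    attentive_mult = c(delta = 1, theta = 1, alpha = 1.8, beta = 1, gamma = 1),
    rest_mult = c(delta = 1, theta = 1.3, alpha = 1, beta = 1, gamma = 1.2))
  gaps <- sapply(1:2, function(s) {
    cfg$seed <- 14 + s
    homog <- simulate_cohort(3, cfg)
    profs <- list(subject_profile("s01"), subject_profile("s02"),
                  subject_profile("s03", band_profile = reversed))
    heter <- simulate_cohort(3, cfg, profiles = profs)
    acc <- function(recs) {
      f <- purrr::map_dfr(recs, extract_features, prefilter = NULL)
      mean(cross_subject_cv(f, point_grid(), seed = s)$folds$test_accuracy)
    }
    acc(homog) - acc(heter)
  })
  expect_true(all(gaps > 0))
})

test_that("k-fold partitions are balanced, exhaustive, disjoint and seed-determined", {
  f <- cluster_features(n_segments = 6, seg_len = 11, n_feat = 5) # 66 epochs
  cv <- suppressWarnings(kfold_cv(f, k = 5, grid = point_grid(),
                 reservoir = reservoir_config(n_internal = 10, seed = 1), seed = 3))
  sizes <- table(cv$assignment)
  expect_lte(max(sizes) - min(sizes), 1)
  expect_equal(sum(sizes), nrow(f))
  expect_equal(nrow(cv$folds), 5)
  expect_equal(nrow(cv$predictions), nrow(f))
  cv2 <- suppressWarnings(kfold_cv(f, k = 5, grid = point_grid(),
                  reservoir = reservoir_config(n_internal = 10, seed = 1), seed = 3))
  expect_identical(cv$assignment, cv2$assignment)
  expect_identical(cv$folds, cv2$folds)
  cv3 <- suppressWarnings(kfold_cv(f, k = 5, grid = point_grid(),
                  reservoir = reservoir_config(n_internal = 10, seed = 1), seed = 4))
  expect_false(identical(cv$assignment, cv3$assignment))
  expect_error(kfold_cv(f, k = 1), ">= 2")
  expect_error(kfold_cv(f[1:3, ], k = 5), "at least k")
})

test_that("the smoothing curve re-thresholds stored traces per window", {
  rec <- quick_recording(seed = 15)
  f <- extract_features(rec, prefilter = NULL)
  cv <- within_subject_cv(f, point_grid(), seed = 5)
  curve <- smoothing_curve(cv, 1:12)
  expect_equal(nrow(curve), 12)
  expect_equal(curve$window, 1:12)
  expect_equal(curve$accuracy[1], mean(cv$folds$test_accuracy), tolerance = 1e-12)
  # oracle: recompute one window by brute force over fold/segment groups
  p <- dplyr::arrange(cv$predictions, fold, segment, t)
  accs <- sapply(split(p, p$fold), function(pf) {
    sm <- unlist(lapply(split(pf$.readout, pf$segment), brute_smooth, n = 4))
    lab <- unlist(lapply(split(pf$label, pf$segment), identity))
    mean(ifelse(sm > 0, 1, -1) == lab)
  })
  expect_equal(curve$accuracy[4], mean(accs), tolerance = 1e-12)
})

test_that("pipeline predictions are invariant to common amplitude rescaling", {
  # standardization makes the transform scale-free exactly; a well-conditioned
  # readout (more epochs than design columns, moderate ridge) keeps the
  # remaining float-level feature differences from being amplified
  rec <- quick_recording(seed = 16, n_runs = 3)
  rec_scaled <- rec
  rec_scaled$signal <- rec$signal * 3.7
  pred_of <- function(r) {
    f <- extract_features(r, prefilter = NULL)
    std <- fit_standardizer(f[f$run != 3, ])
    fit <- fit_esn(apply_standardizer(f[f$run != 3, ], std),
                   reservoir_config(n_internal = 20, seed = 17),
                   training_config(beta = 1e-4))
    predict(fit, apply_standardizer(f[f$run == 3, ], std))
  }
  p1 <- pred_of(rec)
  p2 <- pred_of(rec_scaled)
  expect_equal(p1$.readout, p2$.readout, tolerance = 1e-6)
  expect_identical(p1$.pred, p2$.pred)
})
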