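# Epoching, filtering, spectral/temporal features, standardization

test_that("segmentation yields floor(duration / epoch) windows of one state", {
  rec <- flat_recording(10)
  eps <- segment_epochs(rec, 0.5)
  expect_equal(nrow(eps), 20)
  expect_true(all(vapply(eps$samples, ncol, 0L) == 125))
  expect_true(all(eps$state == "rest"))

  expect_equal(nrow(segment_epochs(flat_recording(0.4))), 0)

  rec2 <- flat_recording(6.3, state = "attentive")
  expect_equal(nrow(segment_epochs(rec2, 0.5)), floor(6.3 / 0.5))

  # per-interval floor oracle on a real schedule
  cfg <- quick_config(seed = 11)
  rec3 <- simulate_session(subject_profile("s01"), cfg)
  eps3 <- segment_epochs(rec3, 0.5)
  sched <- rec3$schedule[rec3$schedule$state %in% c("attentive", "rest"), ]
  n_oracle <- sum((round(sched$end_s * 250) - round(sched$start_s * 250)) %/% 125)
  expect_equal(nrow(eps3), n_oracle)

  expect_error(segment_epochs(rec, 0.3333), "integer")
})

test_that("the broadband filter passes the band and kills DC and drift", {
  fs <- 250
  t <- seq(0, 8, by = 1 / fs)
  dc <- rep(2, length(t))
  expect_lt(max(abs(broadband_filter(dc, 1, 50, fs = fs))), 1e-6 * 2)
  mid <- seq(2 * fs, 6 * fs) # trim filter edges
  y10 <- broadband_filter(sin(2 * pi * 10 * t), 1, 50, fs = fs)
  expect_equal(max(abs(y10[mid])), 1, tolerance = 0.01)
  yslow <- broadband_filter(sin(2 * pi * 0.2 * t), 1, 50, fs = fs)
  expect_lt(max(abs(yslow[mid])), 0.05)
  expect_error(broadband_filter(dc, 0, 50, fs = fs), "band edges")
  expect_error(broadband_filter(dc, 1, 130, fs = fs), "band edges")
})

test_that("spectral features isolate the band containing a pure tone", {
  zero <- matrix(0, 2, 125, dimnames = list(c("left", "right"), NULL))
  expect_true(all(spectral_features(zero, 250) == 0))
  expect_length(spectral_features(zero, 250), 10)

  t <- (0:124) / 250
  tone <- rbind(left = sin(2 * pi * 10 * t), right = sin(2 * pi * 10 * t))
  sf <- spectral_features(tone, 250)
  for (ch in c("left", "right")) {
    v <- sf[grep(paste0("^", ch, "_"), names(sf))]
    expect_equal(names(which.max(v)), paste0(ch, "_alpha_power"))
  }
  # a band with no bins at this resolution is rejected at construction
  expect_error(spectral_features(matrix(0, 2, 25), 250), "no spectral bins")
})

test_that("temporal features compute the five statistics per band and flag degenerate windows", {
  zero <- matrix(0, 2, 125, dimnames = list(c("left", "right"), NULL))
  tf <- temporal_features(zero, 250)
  expect_length(tf, 50)
  expect_true(all(tf == 0))
  expect_true(length(attr(tf, "degenerate")) > 0)

  # alpha-filtered Gaussian noise has skewness ~ 0 (Monte Carlo, 3 SE)
  skews <- withr::with_seed(21, sapply(1:200, function(i) {
    temporal_features(matrix(rnorm(125), 1, 125), 250)[["ch1_alpha_skew"]]
  }))
  expect_lt(abs(mean(skews)), 3 * sd(skews) / sqrt(length(skews)))

  # Pearson kurtosis convention: near 3 for Gaussian noise
  kurts <- withr::with_seed(22, sapply(1:100, function(i)
    temporal_features(matrix(rnorm(125), 1, 125), 250)[["ch1_beta_kurt"]]))
  expect_equal(mean(kurts), 3, tolerance = 0.3)
})

test_that("feature dimension is 60 for two channels and halves for one channel", {
  f2 <- extract_features(quick_recording(seed = 1, n_runs = 1), prefilter = NULL)
  expect_length(feature_columns(f2), 60)
  expect_equal(sum(grepl("_power$", feature_columns(f2))), 10)
  expect_equal(sum(!grepl("_power$", feature_columns(f2))), 50)

  f1 <- extract_features(quick_recording(seed = 1, n_runs = 1, n_channels = 1),
                         prefilter = NULL)
  expect_length(feature_columns(f1), 30)
  expect_true(all(f2$label %in% c(-1, 1)))
})

test_that("the spectral alpha feature is monotone in injected 10 Hz amplitude", {
  base <- withr::with_seed(31, rnorm(125))
  t <- (0:124) / 250
  vals <- sapply(c(1, 2, 4), function(A) {
    ep <- matrix(base + A * sin(2 * pi * 10 * t), 1, 125)
    spectral_features(ep, 250)[["ch1_alpha_power"]]
  })
  expect_true(all(diff(vals) > 0))
})

test_that("feature extraction is translation-equivariant over whole epochs", {
  n <- round(20 * 250)
  sig <- withr::with_seed(41, matrix(rnorm(2 * n), 2, n))
  rec <- flat_recording(20, signal = sig)
  shifted <- flat_recording(19.5, signal = sig[, -(1:125)])
  f <- extract_features(rec, prefilter = NULL)
  fsh <- extract_features(shifted, prefilter = NULL)
  cols <- feature_columns(f)
  expect_equal(as.matrix(fsh[, cols]), as.matrix(f[-1, cols]),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("standardization is fit on training rows and inverts algebraically", {
  f <- extract_features(quick_recording(seed = 51), prefilter = NULL)
  std <- fit_standardizer(f)
  fz <- apply_standardizer(f, std)
  cols <- feature_columns(f)
  m <- as.matrix(fz[, cols])
  expect_true(all(m >= -1 - 1e-12 & m <= 1 + 1e-12))
  # the underlying z-scores have mean 0, sd 1 by construction of the params
  z <- sweep(sweep(as.matrix(f[, cols]), 2, std$mean), 2, std$sd, "/")
  expect_equal(unname(colMeans(z)), rep(0, length(cols)), tolerance = 1e-9)
  expect_equal(unname(apply(z, 2, sd)), rep(1, length(cols)), tolerance = 1e-9)
  # algebraic inverse recovers the raw features
  raw <- sweep(sweep(sweep(sweep(m + 1, 2, 2 / (std$zmax - std$zmin), "/"),
                           2, std$zmin, "+"), 2, std$sd, "*"), 2, std$mean, "+")
  expect_equal(raw, as.matrix(f[, cols]), ignore_attr = TRUE, tolerance = 1e-9)
  # a test row equal to a training row transforms identically
  expect_equal(apply_standardizer(f[3, ], std), fz[3, ])
  # permutation invariance of the fit
  std_p <- fit_standardizer(f[sample(nrow(f)), ])
  expect_equal(std, std_p)
  # zero-variance flag
  f0 <- f
  f0$left_delta_power <- 1
  expect_warning(std0 <- fit_standardizer(f0), "zero-variance")
  expect_true(std0$zero_var[std0$feature == "left_delta_power"])
  # dimension mismatch
  expect_error(apply_standardizer(f[, -10], std), "mismatch")
})
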