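test_that("feature name enumeration matches the published counts", {
  full <- feature_names()
  expect_length(full, 148)
  per_mod <- feature_names(modalities = "accel")
  expect_length(per_mod, 74)
  counts <- table(sub("^accel_[a-z]+_([TFECD])_.*$", "\\1", per_mod))
  expect_equal(unname(counts[c("T", "F", "E", "C", "D")]),
               c(24L, 24L, 4L, 6L, 16L), ignore_attr = TRUE)
  tri <- per_mod[!grepl("_mag_", per_mod)]
  mag <- per_mod[grepl("_mag_", per_mod)]
  expect_length(tri, 57)
  expect_length(mag, 17)
  # magnitude-only keeps the 17 magnitude features plus 6 correlation ones
  expect_length(feature_names(modalities = "accel", magnitude_only = TRUE), 23)
  expect_length(feature_names(c("T", "F"), "accel"), 48)
})

test_that("magnitude is the per-sample Euclidean norm", {
  expect_equal(magnitude(matrix(c(3, 4, 0), 1)), 5)
  expect_equal(magnitude(matrix(c(-2.5, 0, 0), 1)), 2.5)
  set.seed(1)
  m <- matrix(rnorm(300), 100, 3)
  expect_equal(magnitude(m)^2, m[, 1]^2 + m[, 2]^2 + m[, 3]^2)
})

test_that("time features use population moments with degeneracy conventions", {
  tf <- time_features(c(1, 2, 3, 4))
  expect_equal(tf[["mean"]], 2.5)
  expect_equal(tf[["range"]], 3)
  expect_equal(tf[["rms"]], sqrt(7.5))
  expect_equal(tf[["variance"]], 1.25)
  expect_equal(tf[["skew"]], 0)
  expect_equal(tf[["kurtosis"]], -1.36)

  tc <- time_features(rep(-3, 10))
  expect_equal(unname(tc), c(3, 0, -3, 0, 0, 0))

  set.seed(2)
  x <- rnorm(100, 5, 2)
  tf2 <- time_features(x)
  expect_equal(tf2[["rms"]]^2, tf2[["mean"]]^2 + tf2[["variance"]])
  expect_error(time_features(1), class = "wp_data_error")
})

test_that("frequency features locate tones and spectral moments", {
  rate <- 62.5; W <- 312
  t <- (0:(W - 1)) / rate
  ff <- frequency_features(sin(2 * pi * 5 * t), rate)
  expect_equal(ff[["dom_freq"]], 5, tolerance = rate / W + 1e-9)
  expect_gt(ff[["rel_mag"]], 0.8)

  # flat spectrum centroid ~ rate / 4 (averaged over draws)
  set.seed(3)
  cents <- replicate(8, frequency_features(rnorm(W), rate)[["psd_mean"]])
  expect_equal(mean(cents), rate / 4, tolerance = 0.1 * rate / 4)

  # equal-power 2 Hz + 6 Hz tones: centroid at the midpoint
  two <- sin(2 * pi * 2 * t) + sin(2 * pi * 6 * t)
  expect_equal(frequency_features(two, rate)[["psd_mean"]], 4,
               tolerance = 0.25)

  z <- frequency_features(rep(0, W), rate)
  expect_equal(unname(z), rep(0, 6))
  expect_error(frequency_features(1:4, rate), class = "wp_data_error")
})

test_that("sample entropy matches the brute-force oracle exactly", {
  expect_equal(sample_entropy(rep(1, 50)), 0)
  set.seed(4)
  for (i in 1:40) {
    W <- sample(20:200, 1)
    x <- switch(1 + i %% 3,
                rnorm(W),
                sin(2 * pi * 5 * (1:W) / 62.5) + rnorm(W, 0, 0.3),
                cumsum(rnorm(W)))
    expect_identical(sample_entropy(x), sampen_oracle(x))
  }
  # iid Gaussian at clip length: broad sanity band
  set.seed(5)
  se <- replicate(5, sample_entropy(rnorm(312)))
  expect_true(all(se > 1.5 & se < 3.0))
  expect_error(sample_entropy(c(1, 2, 3)), class = "wp_data_error")
})

test_that("cross-correlation features match the lag-scan oracle", {
  rate <- 50; W <- 100
  t <- (0:(W - 1)) / rate
  x <- sin(2 * pi * 1 * t)
  same <- correlation_features(cbind(x, x, x), rate)
  expect_equal(same[["peak_xy"]], 1, tolerance = 1e-9)
  expect_equal(same[["lag_xy"]], 0)

  set.seed(8)
  xr <- rnorm(W)
  yr <- c(rep(0, 10), xr[1:(W - 10)])  # x delayed by 10 samples
  cf <- correlation_features(cbind(xr, yr, xr), rate)
  expect_equal(abs(cf[["lag_xy"]]), 10 / rate, tolerance = 1e-9)

  zv <- correlation_features(cbind(x, rep(2, W), x), rate)
  expect_equal(zv[["peak_xy"]], 0)
  expect_equal(zv[["lag_xy"]], 0)

  set.seed(6)
  for (i in 1:30) {
    Wi <- sample(10:100, 1)
    m <- matrix(rnorm(3 * Wi), Wi, 3)
    got <- correlation_features(m, rate)
    for (pr in list(c(1, 2, "xy"), c(1, 3, "xz"), c(2, 3, "yz"))) {
      o <- xcorr_oracle(m[, as.integer(pr[1])], m[, as.integer(pr[2])], rate)
      expect_equal(got[[paste0("peak_", pr[3])]], o[["peak"]], tolerance = 1e-9)
      expect_equal(got[[paste0("lag_", pr[3])]], o[["lag"]], tolerance = 1e-12)
    }
  }
})

test_that("derivative features are moments of the scaled first difference", {
  rate <- 62.5
  t <- (0:99) / rate
  df <- derivative_features(3 * t, rate)
  expect_equal(unname(df), c(3, 0, 0, 0), tolerance = 1e-9)
  expect_equal(unname(derivative_features(rep(2, 50), rate)), c(0, 0, 0, 0))
  set.seed(7)
  x <- rnorm(120)
  d <- diff(x) * rate
  mo <- derivative_features(x, rate)
  expect_equal(mo[["mean"]], mean(d))
  expect_equal(mo[["sd"]], sqrt(mean((d - mean(d))^2)))
  expect_error(derivative_features(c(1, 2), rate), class = "wp_data_error")
})

test_that("clip extraction assembles the canonical feature vector", {
  clip <- make_clip()
  full <- extract_features(clip)
  fcols <- setdiff(names(full), c("clip_id", "device", "participant", "task",
                                  "repetition", "start_time", "rate",
                                  "tremor_score", "brady_score"))
  expect_identical(fcols, feature_names())
  expect_length(fcols, 148)
  expect_true(all(is.finite(unlist(full[fcols]))))

  acc <- extract_features(clip, modalities = "accel")
  expect_length(intersect(names(acc), feature_names()), 74)
  mag <- extract_features(clip, modalities = "accel", magnitude_only = TRUE)
  expect_length(intersect(names(mag), feature_names(magnitude_only = TRUE)), 23)

  watch_clip <- make_clip(gyro = FALSE)
  expect_error(extract_features(watch_clip, modalities = c("accel", "gyro")),
               class = "wp_missing_modality")
})

test_that("dominant frequency separates tremor scores in generated data", {
  cfg <- mini_config(seed = 6)
  ds <- generate_dataset(cfg, devices = "hand_sensor")
  clips <- dplyr::filter(preprocess(ds, devices = "hand_sensor"), valid)
  fx <- extract_features(clips, categories = "F", modalities = "accel")
  dom <- fx$accel_mag_F_dom_freq
  hi <- dom[fx$tremor_score >= 2]
  lo <- dom[fx$tremor_score == 0]
  expect_gt(length(hi), 5)
  m_hi <- mean(hi)
  expect_gt(m_hi, 4); expect_lt(m_hi, 6)
  expect_lt(mean(lo), 4)
})

test_that("feature-set timing is subadditive with entropy the costliest", {
  clips <- dplyr::bind_rows(lapply(1:40, function(s) make_clip(seed = s)))
  tt <- time_feature_sets(
    clips, combos = list(character(0), "T", "F", "E", "C", c("T", "F")),
    repeats = 3, modalities = "accel")
  expect_equal(tt$mean_time_ms[1], 0)
  t_of <- function(lbl) tt$mean_time_ms[tt$label == lbl]
  # entropy dominates every other single category on 312-sample clips
  expect_gt(t_of("E"), t_of("C"))
  expect_gt(t_of("E"), t_of("T"))
  expect_gt(t_of("E"), t_of("F"))
  # shared preliminaries make combinations subadditive (50% slack for noise)
  expect_lt(t_of("FT"), (t_of("T") + t_of("F")) * 1.5)
})
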