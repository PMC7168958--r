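test_that("generator configuration validates its fields by name", {
  cfg <- generator_config(seed = 7)
  expect_s3_class(cfg, "wp_config")
  expect_equal(cfg$hand_rate, 62.5)
  expect_equal(cfg$watch_rate, 50)
  expect_equal(cfg$accel_range, 4)
  expect_equal(cfg$gyro_range, 1000)
  expect_equal(cfg$tremor_band, c(4, 6))
  expect_equal(cfg$tremor_amp_by_score[1], 0)
  expect_equal(cfg$brady_slowing_by_score[1], 1)
  expect_error(generator_config(n_participants = 0), "n_participants",
               class = "wp_config_error")
  expect_error(generator_config(sample_drop_prob = 1), "sample_drop_prob",
               class = "wp_config_error")
  expect_error(generator_config(tremor_amp_by_score = c(1, 2, 3, 4, 5)),
               "tremor_amp_by_score", class = "wp_config_error")
  expect_error(generator_config(brady_slowing_by_score = c(1, 1.1, 1, 1, 1)),
               "brady_slowing_by_score", class = "wp_config_error")
})

test_that("cohort generation is deterministic with propensities in range", {
  cfg <- generator_config(seed = 7)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co), 13)
  expect_true(all(co$tremor_propensity >= 0 & co$tremor_propensity < 4))
  expect_true(all(co$brady_propensity >= 0 & co$brady_propensity < 4))
  expect_identical(co, generate_cohort(cfg))
  co2 <- generate_cohort(generator_config(n_participants = 2, seed = 7))
  expect_equal(nrow(co2), 2)
})

test_that("medication response starts at OFF-state maximum and declines", {
  for (n in c(1, 2, 3, 7, 10)) {
    m <- medication_response(n)
    expect_length(m, n)
    expect_equal(m[1], 1)
    expect_true(all(m[1] >= m))
  }
  co <- generate_cohort(generator_config(seed = 3))
  for (m in co$med_response) expect_true(all(m[1] >= m))
})

test_that("clinician scoring follows propensity, task, and medication state", {
  prof0 <- tibble::tibble(participant_id = "P01", tremor_propensity = 0,
                          brady_propensity = 0,
                          med_response = list(rep(1, 7)))
  task <- mini_tasks()[1, ]
  set.seed(1)
  expect_equal(score_task(prof0, task, 1, "tremor"), 0L)
  # bradykinesia not scorable during a postural hold
  hold <- dplyr::filter(mini_tasks(), !brady_scorable)[1, ]
  expect_true(is.na(score_task(prof0, hold, 1, "bradykinesia")))
  # deterministic rounding with zero noise and full expression
  prof <- tibble::tibble(participant_id = "P01", tremor_propensity = 3.2,
                         brady_propensity = 3.2,
                         med_response = list(rep(1, 7)))
  task_full <- task
  task_full$tremor_expression <- 1
  expect_equal(score_task(prof, task_full, 1, "tremor", label_noise_sd = 0), 3L)
  expect_error(score_task(prof, task_full, 9, "tremor"),
               class = "wp_config_error")
})

test_that("annotations omit bradykinesia for non-scorable tasks", {
  cfg <- mini_config(seed = 2)
  ann <- annotate_cohort(generate_cohort(cfg), cfg)
  hold_ids <- cfg$tasks$task_id[!cfg$tasks$brady_scorable]
  br <- dplyr::filter(ann, symptom == "bradykinesia")
  expect_false(any(br$task %in% hold_ids))
  expect_true(all(ann$score %in% 0:4))
  tr <- dplyr::filter(ann, symptom == "tremor")
  expect_equal(nrow(tr), 7 * 5 * 3)
})

test_that("a zero-propensity cohort yields only score-0 annotations", {
  cfg <- mini_config(seed = 5)
  co <- generate_cohort(cfg)
  co$tremor_propensity <- 0
  co$brady_propensity <- 0
  ann <- annotate_cohort(co, cfg)
  expect_true(all(ann$score == 0))
})

band_power <- function(x, rate, lo, hi) {
  sp <- stats::spec.pgram(stats::ts(x - mean(x), frequency = rate),
                          plot = FALSE, taper = 0)
  sum(sp$spec[sp$freq >= lo & sp$freq <= hi])
}

test_that("tremor score drives a 4-6 Hz spectral peak, absent at score 0", {
  cfg <- generator_config(seed = 4, duration_range = c(15, 60))
  task <- dplyr::filter(default_tasks(), task_id == "postural_hold")
  set.seed(42)
  quiet <- synthesize_kinematics(task, 0, 0, 20, cfg)
  mag <- sqrt(rowSums(quiet$accel^2))
  # spectrum above 4 Hz is noise floor only: tremor band no stronger than
  # a reference high band that never holds signal
  p_band <- band_power(mag, 200, 4, 6)
  p_ref <- band_power(mag, 200, 20, 40)
  expect_lt(p_band / p_ref, 3)

  set.seed(43)
  trem <- synthesize_kinematics(task, 3, 0, 20, cfg)
  for (ax in 1:3) {
    x <- trem$accel[, ax] + sqrt(rowSums(trem$accel^2)) * 0
    sp <- stats::spec.pgram(stats::ts(trem$accel[, ax] - mean(trem$accel[, ax]),
                                      frequency = 200), plot = FALSE, taper = 0)
    # consider only the band above orientation drift
    keep <- sp$freq > 1
    dom <- sp$freq[keep][which.max(sp$spec[keep])]
    expect_gt(dom, 4 - 0.1)
    expect_lt(dom, 6 + 0.1)
  }
  expect_error(synthesize_kinematics(task, 0, 0, 5, cfg),
               class = "wp_data_error")
})

test_that("bradykinetic slowing lowers peak voluntary speed", {
  cfg <- generator_config(seed = 4)
  task <- dplyr::filter(default_tasks(), task_id == "finger_to_nose")
  set.seed(7)
  v0 <- synthesize_kinematics(task, 0, 0, 20, cfg)$voluntary
  set.seed(7)
  v2 <- synthesize_kinematics(task, 0, 2, 20, cfg)$voluntary
  speed <- function(v) max(abs(diff(v[, 1])))
  expect_lt(speed(v2), speed(v0))
})

test_that("the sensor model samples, jitters, drops, and clips", {
  cfg0 <- generator_config(seed = 1, timestamp_jitter_sd = 0,
                           sample_drop_prob = 0, noise_sd = 0)
  task <- default_tasks()[1, ]
  set.seed(1)
  motion <- synthesize_kinematics(task, 0, 0, 60, cfg0)
  rec <- apply_sensor_model(motion, "hand_sensor", cfg0)
  ts <- rec$signal[[1]]$t
  expect_equal(length(ts), 3750)
  expect_equal(diff(ts), rep(1 / 62.5, 3749), tolerance = 1e-12)
  expect_true(all(c("gx", "gy", "gz") %in% names(rec$signal[[1]])))

  # binomial sample retention under dropping
  cfg_drop <- generator_config(seed = 1, timestamp_jitter_sd = 0,
                               sample_drop_prob = 0.1)
  set.seed(2)
  rec_d <- apply_sensor_model(motion, "hand_sensor", cfg_drop)
  n_kept <- nrow(rec_d$signal[[1]])
  expect_gt(n_kept, 3750 * 0.9 - 3 * sqrt(3750 * 0.9 * 0.1))
  expect_lt(n_kept, 3750 * 0.9 + 3 * sqrt(3750 * 0.9 * 0.1))

  # a 10 G ideal acceleration saturates the +/- 4 G range
  big <- motion
  big$accel <- matrix(10 * 9.80665, nrow = length(motion$time), ncol = 3)
  set.seed(3)
  rec_big <- apply_sensor_model(big, "hand_sensor", cfg0)
  expect_true(all(abs(rec_big$signal[[1]]$ax - 4) < 1e-9))

  # watch: no gyro channels, attenuated relative to hand
  set.seed(4)
  w <- apply_sensor_model(motion, "watch", cfg0)
  expect_false(any(c("gx", "gy", "gz") %in% names(w$signal[[1]])))
  expect_equal(w$nominal_rate, 50)
})

test_that("dataset generation is reproducible and complete", {
  cfg <- generator_config(n_participants = 1, tasks = default_tasks(2),
                          n_repetitions = 1, duration_range = c(15, 16),
                          seed = 3)
  ds <- generate_dataset(cfg)
  expect_equal(nrow(ds$recordings), 2 * 2)  # hand + watch per performance
  expect_setequal(unique(ds$recordings$device), c("hand_sensor", "watch"))
  ds2 <- generate_dataset(cfg)
  expect_identical(ds$recordings, ds2$recordings)
  expect_identical(ds$annotations, ds2$annotations)
  ds_h <- generate_dataset(cfg, devices = "hand_sensor")
  expect_equal(nrow(ds_h$recordings), 2)
})

test_that("default cohort score distribution matches the expected clip table", {
  # three quarters of tremor annotations at score 0, score 4 never emitted
  fracs <- vapply(1:4, function(s) {
    cfg <- generator_config(seed = s)
    ann <- annotate_cohort(generate_cohort(cfg), cfg)
    tr <- dplyr::filter(ann, symptom == "tremor")
    expect_lt(max(ann$score), 4)
    mean(tr$score == 0)
  }, numeric(1))
  expect_true(all(fracs > 0.6 & fracs < 0.85))
})

test_that("tremor-band power of generated clips is monotone in score", {
  cfg <- generator_config(seed = 9)
  task <- dplyr::filter(default_tasks(), task_id == "postural_hold")
  set.seed(99)
  mean_power <- vapply(0:3, function(s) {
    p <- replicate(30, {
      mo <- synthesize_kinematics(task, s, 0, 15, cfg)
      rec <- apply_sensor_model(mo, "hand_sensor", cfg)
      clips <- segment_clips(highpass_accel(regularize(rec)))
      mean(vapply(clips$accel_raw[clips$valid], function(a) {
        band_power(magnitude(a), 62.5, 4, 6)
      }, numeric(1)))
    })
    mean(p)
  }, numeric(1))
  expect_true(all(diff(mean_power) >= 0))
})
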