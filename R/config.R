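#' Default motor-task battery
#'
#' A battery of 13 standardized motor tasks spanning gait, fine and gross
#' upper-extremity activity, clinical assessment maneuvers, and low-movement
#' postural/rest holds. Voluntary movement is modeled as an oscillation at
#' `base_frequency` (all tasks fall in the 0-5 Hz band typical of human
#' movement) with acceleration amplitude `base_amplitude` (m/s^2).
#' Low-movement tasks carry `brady_scorable = FALSE`: they do not involve
#' enough voluntary movement for bradykinesia to be rated, so bradykinesia
#' annotations are absent for them and the bradykinesia clip count is smaller
#' than the tremor clip count.
#'
#' Symptom expression varies across tasks: parkinsonian rest/postural
#' tremor is fullest during low-movement holds and partially suppressed by
#' voluntary action (`tremor_expression` in `[0, 1]` scales the latent
#' severity), while bradykinesia is most visible in fine-motor and clinical
#' assessment tasks (`brady_expression`). This task modulation gives each
#' participant a mixture of score-0 and symptomatic clips, as a clinician
#' rating a real session would produce.
#'
#' @param n Number of tasks to return (first `n` rows of the battery,
#'   recycled if `n` exceeds 13). Default 13.
#' @return A tibble with columns `task_id`, `archetype`, `base_frequency`
#'   (Hz), `base_amplitude` (m/s^2), `brady_scorable`,
#'   `tremor_expression`, `brady_expression`.
#' @examples
#' default_tasks()
#' @export
default_tasks <- function(n = 13) {
  battery <- tibble::tribble(
    ~task_id,               ~archetype,            ~base_frequency, ~base_amplitude, ~brady_scorable, ~tremor_expression, ~brady_expression,
    "walk_60s",             "gait",                1.8,             3.0,             TRUE,            0.45,               0.50,
    "walk_30s",             "gait",                1.9,             3.0,             TRUE,            0.45,               0.50,
    "typing",               "fine_upper",          3.0,             1.2,             TRUE,            0.25,               1.00,
    "writing",              "fine_upper",          2.5,             1.0,             TRUE,            0.25,               1.00,
    "buttoning",            "fine_upper",          2.0,             1.0,             TRUE,            0.30,               0.90,
    "pouring_water",        "gross_upper",         1.2,             2.0,             TRUE,            0.35,               0.60,
    "drinking",             "gross_upper",         1.0,             1.8,             TRUE,            0.35,               0.60,
    "folding_towels",       "gross_upper",         1.1,             2.0,             TRUE,            0.40,               0.60,
    "finger_to_nose",       "clinical_assessment", 1.5,             2.5,             TRUE,            0.45,               0.95,
    "pronation_supination", "clinical_assessment", 2.5,             2.5,             TRUE,            0.45,               1.00,
    "postural_hold",        "postural_hold",       0.3,             0.30,            FALSE,           1.00,               0,
    "seated_reading",       "postural_hold",       0.2,             0.20,            FALSE,           0.90,               0,
    "rest_sitting",         "postural_hold",       0.1,             0.15,            FALSE,           1.00,               0
  )
  if (n == 13) return(battery)
  idx <- rep_len(seq_len(nrow(battery)), n)
  out <- battery[idx, ]
  out$task_id <- make.unique(out$task_id, sep = "_v")
  # keep at least one non-scorable task in any truncation
  if (all(out$brady_scorable)) out$brady_scorable[nrow(out)] <- FALSE
  out
}

#' Generator configuration for the synthetic cohort
#'
#' Bundles every tunable of the synthetic-data generator. Defaults emulate
#' the study conditions the analysis assumes: 13 participants performing 13
#' standardized motor tasks, 7 repetitions each across two visits; a
#' skin-mounted hand sensor recording tri-axial acceleration (range +/- 4 G)
#' and angular velocity (range +/- 1000 deg/s) at 62.5 Hz; a wrist smart
#' watch recording tri-axial acceleration only at a nominal 50 Hz;
#' recordings lasting 15-60 s; parkinsonian tremor in the 4-6 Hz band with
#' amplitude increasing in clinical score (zero at score 0); bradykinetic
#' slowing as a per-score speed multiplier (1 at score 0).
#'
#' @param n_participants Cohort size. Default 13.
#' @param tasks Task battery tibble as produced by [default_tasks()].
#' @param n_repetitions Repetitions of each task per participant (repetition
#'   1 = medication OFF, 2-6 = successive post-dose intervals, 7 = second
#'   visit ON). Default 7.
#' @param hand_rate,watch_rate Nominal sampling rates in Hz (62.5 and 50).
#' @param accel_range Accelerometer saturation in G (4).
#' @param gyro_range Gyroscope saturation in deg/s (1000).
#' @param tremor_band Tremor frequency interval in Hz, `c(4, 6)`.
#' @param tremor_amp_by_score Monotone map from score 0-4 to tremor
#'   acceleration amplitude in m/s^2; must start at 0.
#' @param brady_slowing_by_score Monotone non-increasing map from score 0-4
#'   to a voluntary-movement speed multiplier <= 1; must start at 1.
#' @param brady_accel_coupling Exponent in `[0, 1]` governing how strongly
#'   bradykinetic slowing shows in the accelerometer's voluntary component
#'   (the gyroscope always carries the full slowing signature). 0 confines
#'   the signature to angular velocity. Default 0.4.
#' @param duration_range Recording length interval in seconds, `c(15, 60)`.
#' @param timestamp_jitter_sd SD of per-sample timestamp jitter, seconds.
#' @param sample_drop_prob Independent per-sample drop probability in `[0, 1)`.
#' @param noise_sd Accelerometer sensor noise SD in m/s^2 (scaled
#'   appropriately for the gyroscope).
#' @param label_noise_sd SD of the clinician scoring noise added before
#'   rounding to the 0-4 scale; truncated at +/- 0.49 so a propensity below
#'   3.5 can never round up two steps.
#' @param watch_attenuation Multiplicative attenuation of the wrist signal
#'   relative to the hand signal (wrist placement sees slightly damped hand
#'   motion). Default 0.85.
#' @param seed Integer seed; the dataset is a deterministic function of the
#'   full configuration including the seed.
#' @return An object of class `wp_config` (a named list).
#' @examples
#' cfg <- generator_config(n_participants = 2, seed = 1)
#' cfg$hand_rate
#' @export
generator_config <- function(n_participants = 13,
                             tasks = default_tasks(),
                             n_repetitions = 7,
                             hand_rate = 62.5,
                             watch_rate = 50,
                             accel_range = 4,
                             gyro_range = 1000,
                             tremor_band = c(4, 6),
                             tremor_amp_by_score = c(0, 0.8, 2, 4, 8),
                             brady_slowing_by_score = c(1, 0.8, 0.65, 0.5, 0.35),
                             brady_accel_coupling = 0.4,
                             duration_range = c(15, 60),
                             timestamp_jitter_sd = 0.002,
                             sample_drop_prob = 0.03,
                             noise_sd = 0.08,
                             label_noise_sd = 0.25,
                             watch_attenuation = 0.85,
                             seed = 1L) {
  cfg <- structure(
    list(
      n_participants = n_participants, tasks = tasks,
      n_repetitions = n_repetitions, hand_rate = hand_rate,
      watch_rate = watch_rate, accel_range = accel_range,
      gyro_range = gyro_range, tremor_band = tremor_band,
      tremor_amp_by_score = tremor_amp_by_score,
      brady_slowing_by_score = brady_slowing_by_score,
      brady_accel_coupling = brady_accel_coupling,
      duration_range = duration_range,
      timestamp_jitter_sd = timestamp_jitter_sd,
      sample_drop_prob = sample_drop_prob, noise_sd = noise_sd,
      label_noise_sd = label_noise_sd,
      watch_attenuation = watch_attenuation, seed = as.integer(seed)
    ),
    class = "wp_config"
  )
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  bad <- function(field, why) {
    abort(sprintf("invalid generator configuration: field `%s` %s", field, why),
          class = "wp_config_error")
  }
  if (!is.numeric(cfg$n_participants) || cfg$n_participants < 1)
    bad("n_participants", "must be a positive count")
  if (!is.data.frame(cfg$tasks) || nrow(cfg$tasks) < 1)
    bad("tasks", "must be a non-empty task table")
  req <- c("task_id", "archetype", "base_frequency", "base_amplitude",
           "brady_scorable", "tremor_expression", "brady_expression")
  if (!all(req %in% names(cfg$tasks)))
    bad("tasks", paste("must have columns", paste(req, collapse = ", ")))
  if (any(cfg$tasks$base_frequency < 0 | cfg$tasks$base_frequency > 5))
    bad("tasks", "base_frequency must lie in [0, 5] Hz")
  expr <- c(cfg$tasks$tremor_expression, cfg$tasks$brady_expression)
  if (any(expr < 0 | expr > 1))
    bad("tasks", "expression factors must lie in [0, 1]")
  if (cfg$n_repetitions < 1) bad("n_repetitions", "must be a positive count")
  if (cfg$hand_rate <= 0 || cfg$watch_rate <= 0)
    bad("hand_rate/watch_rate", "rates must be positive")
  if (cfg$accel_range <= 0) bad("accel_range", "must be positive")
  if (cfg$gyro_range <= 0) bad("gyro_range", "must be positive")
  if (length(cfg$tremor_band) != 2 || diff(cfg$tremor_band) <= 0 || cfg$tremor_band[1] <= 0)
    bad("tremor_band", "must be an increasing positive interval")
  amp <- cfg$tremor_amp_by_score
  if (length(amp) != 5 || amp[1] != 0 || any(diff(amp) < 0))
    bad("tremor_amp_by_score", "must be length 5, monotone, with value 0 at score 0")
  slw <- cfg$brady_slowing_by_score
  if (length(slw) != 5 || slw[1] != 1 || any(diff(slw) > 0) || any(slw <= 0))
    bad("brady_slowing_by_score", "must be length 5, positive, non-increasing, 1 at score 0")
  if (cfg$brady_accel_coupling < 0 || cfg$brady_accel_coupling > 1)
    bad("brady_accel_coupling", "must lie in [0, 1]")
  if (length(cfg$duration_range) != 2 || diff(cfg$duration_range) < 0 ||
      cfg$duration_range[1] <= 0)
    bad("duration_range", "must be a positive interval")
  if (cfg$sample_drop_prob < 0 || cfg$sample_drop_prob >= 1)
    bad("sample_drop_prob", "must lie in [0, 1)")
  if (cfg$timestamp_jitter_sd < 0) bad("timestamp_jitter_sd", "must be >= 0")
  if (cfg$noise_sd < 0) bad("noise_sd", "must be >= 0")
  if (cfg$label_noise_sd < 0) bad("label_noise_sd", "must be >= 0")
  if (cfg$watch_attenuation <= 0 || cfg$watch_attenuation > 1)
    bad("watch_attenuation", "must lie in (0, 1]")
  invisible(cfg)
}

#' @export
print.wp_config <- function(x, ...) {
  cat("<wearpd generator config>\n")
  cat(sprintf("  cohort: %d participants x %d tasks x %d repetitions\n",
              x$n_participants, nrow(x$tasks), x$n_repetitions))
  cat(sprintf("  hand sensor: accel+gyro @ %.1f Hz (+/-%g G, +/-%g deg/s)\n",
              x$hand_rate, x$accel_range, x$gyro_range))
  cat(sprintf("  watch: accel @ %.1f Hz\n", x$watch_rate))
  cat(sprintf("  tremor band: %g-%g Hz; duration: %g-%g s; seed %d\n",
              x$tremor_band[1], x$tremor_band[2],
              x$duration_range[1], x$duration_range[2], x$seed))
  invisible(x)
}

#' Read or write a generator configuration as YAML
#'
#' The task battery is stored as a list of task records; all other fields
#' are scalar key-value pairs mirroring [generator_config()]. The round
#' trip is lossless.
#'
#' @param cfg A `wp_config` object.
#' @param path File path to a YAML document.
#' @return `write_config()` returns `path` invisibly; `read_config()`
#'   returns a validated `wp_config`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "wp_config"))
  lst <- unclass(cfg)
  lst$tasks <- purrr::transpose(as.list(cfg$tasks))
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lst <- yaml::read_yaml(path)
  lst$tasks <- dplyr::bind_rows(lapply(lst$tasks, tibble::as_tibble))
  do.call(generator_config, lst)
}
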