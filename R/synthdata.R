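#' Medication-response curve
#'
#' Per-repetition symptom-severity multiplier. Repetition 1 is performed in
#' the medication OFF state (multiplier 1, maximal severity); repetitions
#' 2 to n-1 follow dosing at successive intervals, with severity declining
#' as the medication takes effect; the final repetition is a second-visit ON
#' assessment. The curve is non-increasing from repetition 1.
#'
#' @param n_repetitions Number of repetitions per task.
#' @return Numeric vector of length `n_repetitions` with first element 1.
#' @examples
#' medication_response(7)
#' @export
medication_response <- function(n_repetitions) {
  n <- as.integer(n_repetitions)
  if (n == 1) return(1)
  if (n == 2) return(c(1, 0.62))
  c(1, seq(0.9, 0.58, length.out = n - 2), 0.62)
}

#' Generate a synthetic cohort of participant profiles
#'
#' Draws latent tremor and bradykinesia severities ("propensities", on the
#' clinical 0-4 scale) for each participant, together with an individual
#' medication-response curve. The propensity mixture spans mild-to-moderate
#' disease: a majority of participants with mild tremor propensity (0.2-0.65)
#' and a minority in the 1.0-2.9 range, so that score 4 is never emitted
#' under the default configuration and roughly three quarters of tremor
#' annotations are score 0, with the 1 > 2 > 3 frequency ordering of a
#' mild-to-moderate clinic cohort.
#'
#' @param config A [generator_config()].
#' @return A tibble with one row per participant: `participant_id`,
#'   `tremor_propensity`, `brady_propensity`, and `med_response` (list
#'   column of per-repetition multipliers). Deterministic given
#'   `config$seed`.
#' @examples
#' generate_cohort(generator_config(n_participants = 3, seed = 7))
#' @export
generate_cohort <- function(config) {
  validate_config(config)
  set.seed(config$seed)
  n <- config$n_participants
  base <- medication_response(config$n_repetitions)
  draw_prop <- function(p_low, low_range, mod_range) {
    ifelse(runif(n) < p_low,
           runif(n, low_range[1], low_range[2]),
           runif(n, mod_range[1], mod_range[2]))
  }
  tremor <- draw_prop(0.62, c(0.2, 0.65), c(1.0, 2.9))
  brady  <- draw_prop(0.40, c(0.4, 1.0), c(0.9, 2.2))
  strength <- runif(n, 0.8, 1.1)
  med <- lapply(strength, function(s) {
    m <- 1 - s * (1 - base)
    m[1] <- 1
    pmin(pmax(m, 0.2), 1)
  })
  tibble::tibble(
    participant_id = sprintf("P%02d", seq_len(n)),
    tremor_propensity = tremor,
    brady_propensity = brady,
    med_response = med
  )
}

clamp_score <- function(x) as.integer(pmin(pmax(round(x), 0), 4))

#' Score one task performance on the clinical 0-4 scale
#'
#' Emulates a clinician rating of symptom severity: the participant's latent
#' propensity is scaled by the medication-response multiplier of the given
#' repetition, perturbed by truncated Gaussian scoring noise, rounded, and
#' clamped to 0-4. Bradykinesia cannot be rated during tasks that do not
#' involve enough movement (`brady_scorable = FALSE`); those return `NA`.
#'
#' Uses R's RNG; call `set.seed()` for reproducibility.
#'
#' @param profile One row of the cohort tibble from [generate_cohort()].
#' @param task One row of the task battery.
#' @param repetition Repetition index (1-based).
#' @param symptom `"tremor"` or `"bradykinesia"`.
#' @param label_noise_sd SD of the scoring noise, truncated at +/- 0.49.
#' @return Integer score 0-4, or `NA` when the symptom cannot be scored.
#' @examples
#' cohort <- generate_cohort(generator_config(n_participants = 1, seed = 1))
#' set.seed(1)
#' score_task(cohort[1, ], default_tasks()[1, ], 1, "tremor")
#' @export
score_task <- function(profile, task, repetition, symptom,
                       label_noise_sd = 0.25) {
  stopifnot(symptom %in% c("tremor", "bradykinesia"))
  if (symptom == "bradykinesia" && !task$brady_scorable) return(NA_integer_)
  med <- profile$med_response[[1]]
  if (repetition < 1 || repetition > length(med))
    abort("`repetition` outside 1..n_repetitions", class = "wp_config_error")
  prop <- if (symptom == "tremor") profile$tremor_propensity else profile$brady_propensity
  expr <- if (symptom == "tremor") task$tremor_expression else task$brady_expression
  noise <- pmin(pmax(rnorm(1, 0, label_noise_sd), -0.49), 0.49)
  clamp_score(prop * expr * med[repetition] + noise)
}

#' Annotate a cohort with per-task symptom scores
#'
#' Produces the full table of clinician-style annotations for every
#' participant x task x repetition, one row per scored symptom. Tremor is
#' scored for every performance; bradykinesia only for tasks with
#' `brady_scorable = TRUE`.
#'
#' @param cohort Cohort tibble from [generate_cohort()].
#' @param config The matching [generator_config()].
#' @return A tibble `participant`, `task`, `repetition`, `symptom`, `score`.
#'   Deterministic given the configuration (seeds derived from
#'   `config$seed`).
#' @export
annotate_cohort <- function(cohort, config) {
  grid <- score_grid(cohort, config)
  task_idx <- match(grid$task, config$tasks$task_id)
  brady <- grid$brady
  brady[!config$tasks$brady_scorable[task_idx]] <- NA_integer_
  keep <- c("participant", "task", "repetition")
  out <- dplyr::bind_rows(
    dplyr::mutate(grid[keep], symptom = "tremor", score = grid$tremor),
    dplyr::mutate(grid[keep], symptom = "bradykinesia", score = brady)
  )
  dplyr::arrange(dplyr::filter(out, !is.na(.data$score)),
                 .data$participant, .data$task, .data$repetition, .data$symptom)
}

# one deterministic scoring pass shared by annotations and kinematics:
# latent (possibly unscorable) severities for every participant/task/rep
score_grid <- function(cohort, config) {
  set.seed((config$seed * 2L + 1L) %% .Machine$integer.max)
  grid <- tidyr::expand_grid(
    participant = cohort$participant_id,
    task = config$tasks$task_id,
    repetition = seq_len(config$n_repetitions)
  )
  prof_idx <- match(grid$participant, cohort$participant_id)
  task_idx <- match(grid$task, config$tasks$task_id)
  med <- vapply(seq_len(nrow(grid)), function(i) {
    cohort$med_response[[prof_idx[i]]][grid$repetition[i]]
  }, numeric(1))
  tnoise <- pmin(pmax(rnorm(nrow(grid), 0, config$label_noise_sd), -0.49), 0.49)
  bnoise <- pmin(pmax(rnorm(nrow(grid), 0, config$label_noise_sd), -0.49), 0.49)
  texpr <- config$tasks$tremor_expression[task_idx]
  bexpr <- config$tasks$brady_expression[task_idx]
  grid$tremor <- clamp_score(cohort$tremor_propensity[prof_idx] * texpr * med + tnoise)
  grid$brady <- clamp_score(cohort$brady_propensity[prof_idx] * bexpr * med + bnoise)
  grid
}

random_unit_vector <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

#' Synthesize ideal continuous-time hand motion for one task performance
#'
#' Builds the noiseless-device kinematics on a dense uniform grid:
#' a slowly varying gravity projection (hand orientation drift), a voluntary
#' oscillation at the task's base frequency whose speed and amplitude are
#' scaled down by the bradykinesia slowing map (with a within-recording
#' amplitude decrement proportional to score), a tremor sinusoid drawn from
#' the 4-6 Hz band with amplitude set by the tremor score and slow amplitude
#' modulation, and low-level process noise. Angular velocity is built from
#' the same oscillatory phases, so the gyroscope carries the full slowing
#' signature; the share of the slowing expressed in the accelerometer is
#' governed by `config$brady_accel_coupling`.
#'
#' Uses R's RNG; call `set.seed()` for reproducibility.
#'
#' @param task One row of the task battery.
#' @param tremor_score,brady_score Integer severities 0-4 driving the tremor
#'   amplitude and bradykinetic slowing.
#' @param duration Recording length in seconds; must lie within
#'   `config$duration_range`.
#' @param config A [generator_config()].
#' @param dense_rate Grid rate in Hz (>= 200).
#' @return A list with `time` (seconds), `accel` (N x 3, m/s^2), `gyro`
#'   (N x 3, deg/s), and `voluntary` (N x 3, m/s^2; the voluntary
#'   acceleration component alone, for inspection).
#' @export
synthesize_kinematics <- function(task, tremor_score, brady_score, duration,
                                  config, dense_rate = 200) {
  if (duration < config$duration_range[1] || duration > config$duration_range[2])
    abort(sprintf("duration %.1f s outside configured range [%g, %g]",
                  duration, config$duration_range[1], config$duration_range[2]),
          class = "wp_data_error")
  stopifnot(dense_rate >= 200)
  t <- seq(0, duration, by = 1 / dense_rate)
  n <- length(t)

  # gravity projection under slow orientation drift
  f1 <- runif(1, 0.03, 0.12); f2 <- runif(1, 0.03, 0.12)
  th <- runif(1, 0, pi) + 0.15 * sin(2 * pi * f1 * t + runif(1, 0, 2 * pi))
  ph <- runif(1, 0, 2 * pi) + 0.15 * sin(2 * pi * f2 * t + runif(1, 0, 2 * pi))
  grav <- G_MS2 * cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  # angular velocity of the drift itself (deg/s)
  drift_gyro <- (180 / pi) * cbind(c(0, diff(th)), c(0, diff(ph)), 0) * dense_rate

  # voluntary component with bradykinetic slowing
  s <- config$brady_slowing_by_score[brady_score + 1]
  cpl <- config$brady_accel_coupling
  s_acc <- s^cpl
  decrement <- 1 - 0.5 * (brady_score / 4) * (t / duration)
  ph0 <- runif(1, 0, 2 * pi); ph1 <- runif(1, 0, 2 * pi)
  wave <- function(phase) sin(phase) + 0.3 * sin(2 * phase + ph1)
  u_vol <- random_unit_vector()
  vol_amp <- task$base_amplitude * s_acc * decrement
  vol <- outer(vol_amp * wave(2 * pi * task$base_frequency * s_acc * t + ph0), u_vol)
  u_gyr <- random_unit_vector()
  gyro_gain <- 25  # deg/s of angular velocity per m/s^2 of voluntary acceleration
  gyr_amp <- gyro_gain * task$base_amplitude * s * decrement
  gyr_vol <- outer(gyr_amp * wave(2 * pi * task$base_frequency * s * t + ph0), u_gyr)

  # tremor component
  amp <- config$tremor_amp_by_score[tremor_score + 1]
  f_tr <- runif(1, config$tremor_band[1], config$tremor_band[2])
  am <- 1 + 0.3 * sin(2 * pi * 0.25 * t + runif(1, 0, 2 * pi))
  ph_tr <- runif(1, 0, 2 * pi)
  u_tr <- random_unit_vector()
  trem <- outer(amp * am * sin(2 * pi * f_tr * t + ph_tr), u_tr)
  u_trg <- random_unit_vector()
  gyro_tremor_gain <- 12  # deg/s per m/s^2 of tremor amplitude
  trem_gyr <- outer(gyro_tremor_gain * amp * am * cos(2 * pi * f_tr * t + ph_tr), u_trg)

  pn <- config$noise_sd / 2
  accel <- grav + vol + trem + matrix(rnorm(3 * n, 0, pn), n, 3)
  gyro <- drift_gyro + gyr_vol + trem_gyr + matrix(rnorm(3 * n, 0, 10 * pn), n, 3)
  list(time = t, accel = accel, gyro = gyro, voluntary = vol)
}

make_strictly_increasing <- function(t, eps = 1e-6) {
  t <- sort(t)
  d <- diff(t)
  while (any(d <= 0)) {
    i <- which(d <= 0)[1] + 1L
    t[i] <- t[i - 1L] + eps
    d <- diff(t)
  }
  t
}

#' Sample ideal motion through a device model
#'
#' Emulates the measurement process of either the skin-mounted hand sensor
#' (tri-axial accelerometer +/- 4 G and gyroscope +/- 1000 deg/s at 62.5 Hz)
#' or the wrist smart watch (tri-axial accelerometer only, nominal 50 Hz):
#' samples the ideal motion at the nominal rate with timestamp jitter, drops
#' each sample independently with `sample_drop_prob`, adds sensor noise,
#' clips to the device range, and stores acceleration in G and angular
#' velocity in deg/s. The watch signal is the same hand motion slightly
#' attenuated (wrist vs hand placement) with its own independent noise and
#' no gyroscope channels.
#'
#' Uses R's RNG; call `set.seed()` for reproducibility.
#'
#' @param motion Output of [synthesize_kinematics()].
#' @param device `"hand_sensor"` or `"watch"`.
#' @param config A [generator_config()].
#' @param participant,task,repetition Provenance identifiers stored on the
#'   recording.
#' @return A one-row recordings tibble: identifiers, `nominal_rate`, and a
#'   `signal` list column holding a tibble with strictly increasing `t`
#'   (seconds) and channels `ax, ay, az` (G) plus `gx, gy, gz` (deg/s) for
#'   the hand sensor.
#' @export
apply_sensor_model <- function(motion, device, config,
                               participant = "P01", task = "task", repetition = 1L) {
  stopifnot(device %in% c("hand_sensor", "watch"))
  rate <- if (device == "hand_sensor") config$hand_rate else config$watch_rate
  dur <- motion$time[length(motion$time)]
  n <- floor(dur * rate)
  ts <- (seq_len(n) - 1) / rate
  if (config$timestamp_jitter_sd > 0) {
    ts <- ts + rnorm(n, 0, config$timestamp_jitter_sd)
    ts <- pmin(pmax(ts, 0), dur)
    ts <- make_strictly_increasing(ts)
  }
  keep <- if (config$sample_drop_prob > 0)
    runif(n) >= config$sample_drop_prob else rep(TRUE, n)
  ts <- ts[keep]
  m <- length(ts)
  samp <- function(col) approx(motion$time, col, xout = ts, rule = 2)$y
  acc <- apply(motion$accel, 2, samp)
  if (m == 1) acc <- matrix(acc, nrow = 1)
  if (device == "watch") {
    acc <- acc * config$watch_attenuation +
      matrix(rnorm(3 * m, 0, 1.2 * config$noise_sd), m, 3)
  } else {
    acc <- acc + matrix(rnorm(3 * m, 0, config$noise_sd), m, 3)
  }
  acc_g <- pmin(pmax(ms2_to_g(acc), -config$accel_range), config$accel_range)
  sig <- tibble::tibble(t = ts, ax = acc_g[, 1], ay = acc_g[, 2], az = acc_g[, 3])
  if (device == "hand_sensor") {
    gyr <- apply(motion$gyro, 2, samp)
    if (m == 1) gyr <- matrix(gyr, nrow = 1)
    gyr <- gyr + matrix(rnorm(3 * m, 0, 10 * config$noise_sd), m, 3)
    gyr <- pmin(pmax(gyr, -config$gyro_range), config$gyro_range)
    sig$gx <- gyr[, 1]; sig$gy <- gyr[, 2]; sig$gz <- gyr[, 3]
  }
  tibble::tibble(
    device = device, participant = participant, task = task,
    repetition = as.integer(repetition), nominal_rate = rate,
    signal = list(sig)
  )
}

#' Generate a complete synthetic dataset
#'
#' Runs the full generative chain: cohort profiles, clinician-style
#' annotations, ideal kinematics, and device sampling, producing one hand
#' sensor and one watch recording per participant x task x repetition. The
#' whole dataset is a deterministic function of the configuration (including
#' its seed).
#'
#' Bradykinetic slowing is applied to the movement whenever the participant
#' is bradykinetic, whether or not the task allows the clinician to score
#' it; only scorable tasks contribute bradykinesia annotations.
#'
#' @param config A [generator_config()].
#' @param devices Devices to simulate; default both.
#' @return An object of class `wp_dataset`: a list with `recordings` (tibble,
#'   one row per device recording), `annotations` (tibble), `cohort`, and
#'   `config`.
#' @examples
#' cfg <- generator_config(n_participants = 1, tasks = default_tasks(2),
#'                         n_repetitions = 1, duration_range = c(15, 16),
#'                         seed = 3)
#' ds <- generate_dataset(cfg)
#' ds$recordings
#' @export
generate_dataset <- function(config, devices = c("hand_sensor", "watch")) {
  validate_config(config)
  devices <- match.arg(devices, several.ok = TRUE)
  cohort <- generate_cohort(config)
  ann <- annotate_cohort(cohort, config)
  # latent (possibly unscorable) severities drive the kinematics
  grid <- score_grid(cohort, config)

  set.seed((config$seed * 3L + 7L) %% .Machine$integer.max)
  task_tbl <- config$tasks
  recs <- vector("list", nrow(grid) * length(devices))
  k <- 0L
  for (i in seq_len(nrow(grid))) {
    task <- task_tbl[match(grid$task[i], task_tbl$task_id), ]
    dur <- runif(1, config$duration_range[1], config$duration_range[2])
    motion <- synthesize_kinematics(task, grid$tremor[i], grid$brady[i],
                                    dur, config)
    for (dev in devices) {
      k <- k + 1L
      recs[[k]] <- apply_sensor_model(motion, dev, config,
                                      participant = grid$participant[i],
                                      task = grid$task[i],
                                      repetition = grid$repetition[i])
    }
  }
  structure(
    list(recordings = dplyr::bind_rows(recs), annotations = ann,
         cohort = cohort, config = config),
    class = "wp_dataset"
  )
}

#' @export
print.wp_dataset <- function(x, ...) {
  cat("<wearpd synthetic dataset>\n")
  cat(sprintf("  %d recordings (%s), %d annotations, %d participants\n",
              nrow(x$recordings),
              paste(unique(x$recordings$device), collapse = " + "),
              nrow(x$annotations), nrow(x$cohort)))
  invisible(x)
}
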