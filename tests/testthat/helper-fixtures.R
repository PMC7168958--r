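# Shared fixtures built in code. The mini cohort keeps the full study
# structure (OFF/ON repetitions, task archetypes spanning gait, fine/gross
# upper extremity, clinical assessment, and a postural hold that cannot be
# scored for bradykinesia) at a size small enough for fast model fits.

mini_tasks <- function() default_tasks()[c(1, 3, 6, 9, 11), ]

mini_config <- function(seed = 1, ...) {
  generator_config(n_participants = 7, tasks = mini_tasks(),
                   n_repetitions = 3, duration_range = c(15, 18),
                   seed = seed, ...)
}

# a single uniform recording tibble built directly from a closed-form signal
uniform_recording <- function(f = function(t) sin(2 * pi * t), rate = 62.5,
                              duration = 20, device = "hand_sensor") {
  t <- (0:(duration * rate - 1)) / rate
  sig <- tibble::tibble(t = t, ax = f(t), ay = f(t + 0.1), az = f(t + 0.2))
  if (device == "hand_sensor") {
    sig$gx <- f(t + 0.3); sig$gy <- f(t + 0.4); sig$gz <- f(t + 0.5)
  }
  tibble::tibble(device = device, participant = "P01", task = "task",
                 repetition = 1L, nominal_rate = rate, signal = list(sig))
}

# one synthetic valid clip with plausible content (tremor-like burst + noise)
make_clip <- function(W = 312, rate = 62.5, seed = 1, gyro = TRUE) {
  set.seed(seed)
  t <- (0:(W - 1)) / rate
  base <- function(a) a * sin(2 * pi * 5 * t + runif(1, 0, 2 * pi)) +
    rnorm(W, 0, 0.2)
  acc <- cbind(base(0.5), base(0.3), base(0.2))
  colnames(acc) <- c("ax", "ay", "az")
  tibble::tibble(
    device = if (gyro) "hand_sensor" else "watch", participant = "P01",
    task = "task", repetition = 1L, clip_id = sprintf("clip%d", seed),
    start_time = 0, rate = rate, nominal_rate = rate, window_samples = W,
    raw_sample_count = W, valid = TRUE,
    accel = list(acc),
    gyro = list(if (gyro) acc * 30),
    tremor_score = 1L, brady_score = 0L
  )
}

# labeled feature table with a single informative feature, for model tests:
# participant-level clips whose feature separates label classes cleanly
separable_features <- function(n_participants = 6, clips_per = 40,
                               gap = 3, seed = 1) {
  set.seed(seed)
  rows <- lapply(seq_len(n_participants), function(p) {
    lab <- rep(c(0L, 1L), length.out = clips_per)
    tibble::tibble(
      participant = sprintf("P%02d", p),
      clip_id = sprintf("P%02d-%03d", p, seq_len(clips_per)),
      tremor_score = lab, brady_score = lab,
      accel_x_T_rms = lab * gap + rnorm(clips_per, 0, 0.5),
      accel_x_T_mean = rnorm(clips_per)
    )
  })
  dplyr::bind_rows(rows)
}
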