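channel_names <- function(sig) intersect(c("ax", "ay", "az", "gx", "gy", "gz"), names(sig))

#' Regularize recordings to a uniform sampling grid
#'
#' Device timestamps are jittered and samples are occasionally dropped;
#' every recording is therefore interpolated to its intended (nominal)
#' sampling rate with a cubic spline before any further processing. The
#' uniform grid spans the recorded time range only (no extrapolation), and
#' the original, un-interpolated timestamps are retained alongside each
#' recording so the downstream clip-validity rule can count raw samples.
#'
#' @param recordings A recordings tibble (rows from [apply_sensor_model()]
#'   or [read_recordings()]).
#' @return The same tibble with `signal` replaced by its uniform version,
#'   plus columns `rate` (current rate, Hz) and `raw_times` (list column of
#'   original timestamps).
#' @export
regularize <- function(recordings) {
  stopifnot(is.data.frame(recordings), "signal" %in% names(recordings))
  out <- recordings
  out$raw_times <- lapply(recordings$signal, function(s) s$t)
  out$rate <- recordings$nominal_rate
  out$signal <- purrr::map2(recordings$signal, recordings$nominal_rate, function(sig, rate) {
    t <- sig$t
    if (length(t) < 4)
      abort(sprintf("unusable recording: %d samples (cubic spline needs >= 4)",
                    length(t)), class = "wp_unusable_recording")
    if (any(diff(t) <= 0))
      abort("recording timestamps are not strictly increasing",
            class = "wp_data_error")
    t_out <- t[1] + (0:floor((t[length(t)] - t[1]) * rate)) / rate
    uni <- tibble::tibble(t = t_out)
    for (ch in channel_names(sig))
      uni[[ch]] <- spline(t, sig[[ch]], xout = t_out, method = "fmm")$y
    uni
  })
  out
}

# rational ratio target/original as reduced integers p/q
rate_ratio <- function(original, target) {
  scale <- 1000
  a <- round(original * scale); b <- round(target * scale)
  if (abs(a - original * scale) > 1e-6 || abs(b - target * scale) > 1e-6)
    abort("rates must be expressible to 1/1000 Hz", class = "wp_config_error")
  g <- function(x, y) if (y == 0) x else g(y, x %% y)
  d <- g(a, b)
  c(p = b / d, q = a / d)
}

#' Rational polyphase resampling of a numeric signal
#'
#' Converts a uniformly sampled signal between rates related by a rational
#' factor p/q: the signal is upsampled by zero-insertion, filtered with a
#' long linear-phase FIR low-pass at the smaller of the two Nyquist
#' frequencies (anti-aliasing), and decimated. The filter is designed with
#' [signal::fir1()] with 20 x max(p, q) + 1 taps, giving better than 95%
#' power suppression of out-of-band tones.
#'
#' @param x Numeric vector at the original rate.
#' @param p,q Coprime up/down factors (target rate = original x p / q).
#' @return Numeric vector of length `ceiling(length(x) * p / q)`.
#' @export
resample_poly <- function(x, p, q) {
  p <- as.integer(p); q <- as.integer(q)
  stopifnot(p >= 1, q >= 1)
  if (p == 1 && q == 1) return(x)
  max_rate <- max(p, q)
  half <- 10L * max_rate
  h <- signal::fir1(2L * half, 1 / max_rate) * p
  n_in <- length(x)
  up <- numeric(n_in * p)
  up[seq(1, by = p, length.out = n_in)] <- x
  full <- convolve(up, rev(h), type = "open")
  core <- full[(half + 1):(half + n_in * p)]
  n_out <- ceiling(n_in * p / q)
  core[seq(1, by = q, length.out = n_out)]
}

#' Downsample regularized recordings to a target rate
#'
#' Applies rational polyphase resampling (see [resample_poly()]) to every
#' channel. The built-in anti-alias low-pass means any spectral content
#' above the new Nyquist frequency (target/2) is suppressed -- the mechanism
#' by which low sampling rates destroy the 4-6 Hz tremor signature.
#'
#' @param recordings Regularized recordings tibble (from [regularize()]).
#' @param target_rate Target rate in Hz; must not exceed the current rate
#'   and must share a rational ratio with it (62.5 to 7.5 Hz is up 3 /
#'   down 25).
#' @return The recordings tibble resampled, with `rate` updated. Equal
#'   target and current rate is the identity.
#' @export
downsample <- function(recordings, target_rate) {
  stopifnot("rate" %in% names(recordings))
  if (any(target_rate > recordings$rate))
    abort(sprintf("target rate %g Hz above original rate", target_rate),
          class = "wp_config_error")
  out <- recordings
  out$signal <- purrr::map2(recordings$signal, recordings$rate, function(sig, rate) {
    if (rate == target_rate) return(sig)
    pq <- rate_ratio(rate, target_rate)
    res <- lapply(sig[channel_names(sig)], resample_poly, p = pq["p"], q = pq["q"])
    n_out <- length(res[[1]])
    tibble::as_tibble(c(list(t = sig$t[1] + (0:(n_out - 1)) / target_rate), res))
  })
  out$rate <- target_rate
  out
}

#' High-pass filter accelerometer channels
#'
#' Removes the gravity/orientation component of the acceleration signal
#' with a 4th-order Butterworth high-pass applied forward and backward
#' (zero phase, so clip boundaries stay aligned with their labels).
#' Gyroscope channels are passed through untouched. The unfiltered
#' accelerometer channels are retained alongside (`ax_raw`, `ay_raw`,
#' `az_raw`): the signal-magnitude features are computed from them, since
#' the Euclidean norm is orientation-invariant by construction and the
#' gravity baseline is what keeps tremor power at the tremor frequency in
#' the norm (removing it first would fold the oscillation to twice the
#' frequency through rectification).
#'
#' @param recordings Regularized (optionally downsampled) recordings tibble.
#' @param cutoff Cutoff frequency in Hz; default 0.5. The sampling rate must
#'   exceed twice the cutoff.
#' @return The recordings tibble with filtered accelerometer channels.
#' @export
highpass_accel <- function(recordings, cutoff = 0.5) {
  stopifnot("rate" %in% names(recordings))
  if (any(recordings$rate <= 2 * cutoff))
    abort(sprintf("sampling rate too low for a %g Hz high-pass", cutoff),
          class = "wp_config_error")
  out <- recordings
  out$signal <- purrr::map2(recordings$signal, recordings$rate, function(sig, rate) {
    bf <- signal::butter(4, cutoff / (rate / 2), type = "high")
    n <- nrow(sig)
    # odd-reflection padding tames the filter's edge transient (the step
    # from the gravity baseline) before the forward-backward pass
    pad <- min(n - 1L, ceiling(6 * rate / cutoff))
    for (ch in intersect(c("ax", "ay", "az"), names(sig))) {
      x <- sig[[ch]]
      sig[[paste0(ch, "_raw")]] <- x
      ext <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
      y <- signal::filtfilt(bf, ext)
      sig[[ch]] <- y[(pad + 1):(pad + n)]
    }
    sig
  })
  out
}

#' Segment recordings into overlapping clips
#'
#' Cuts each uniform recording into fixed-length windows (default 5 s with
#' 50% overlap). A window of `floor(window_s * rate)` samples advances by
#' half its length. Each clip counts the raw (un-interpolated) samples whose
#' original timestamps fall inside its time span; clips with fewer than 80%
#' of the expected raw samples (`0.8 * window_s * nominal_rate`) are flagged
#' invalid and are excluded from modeling. Clips inherit the recording's
#' symptom scores unchanged.
#'
#' @param recordings Regularized recordings tibble.
#' @param annotations Annotation tibble (`participant`, `task`,
#'   `repetition`, `symptom`, `score`); optional, may be `NULL`.
#' @param window_s Window length in seconds (default 5).
#' @param overlap Fractional overlap between consecutive windows (default
#'   0.5).
#' @return A clips tibble: provenance identifiers, `clip_id`, `start_time`,
#'   `rate`, `window_samples`, `raw_sample_count`, `valid`, list columns
#'   `accel` / `accel_raw` / `gyro` (W x 3 matrices; `accel_raw` holds the
#'   pre-high-pass channels used for magnitude features and equals `accel`
#'   when no high-pass was applied; `gyro` entries `NULL` for the watch),
#'   and score columns `tremor_score`, `brady_score` when annotations are
#'   supplied. A recording shorter than one window yields no rows.
#' @export
segment_clips <- function(recordings, annotations = NULL, window_s = 5,
                          overlap = 0.5) {
  stopifnot("rate" %in% names(recordings), "raw_times" %in% names(recordings))
  rows <- purrr::pmap(
    list(seq_len(nrow(recordings))),
    function(i) {
      rec <- recordings[i, ]
      sig <- rec$signal[[1]]
      rate <- rec$rate
      W <- floor(window_s * rate)
      hop <- max(1L, floor(W * (1 - overlap)))
      N <- nrow(sig)
      if (N < W || W < 2) return(NULL)
      starts <- seq(1L, N - W + 1L, by = hop)
      raw_t <- rec$raw_times[[1]]
      expected <- window_s * rec$nominal_rate
      has_gyro <- all(c("gx", "gy", "gz") %in% names(sig))
      has_raw <- all(c("ax_raw", "ay_raw", "az_raw") %in% names(sig))
      acc_mat <- as.matrix(sig[c("ax", "ay", "az")])
      raw_mat <- if (has_raw) as.matrix(sig[c("ax_raw", "ay_raw", "az_raw")])
                 else acc_mat
      gyr_mat <- if (has_gyro) as.matrix(sig[c("gx", "gy", "gz")]) else NULL
      purrr::map(seq_along(starts), function(k) {
        s <- starts[k]
        t0 <- sig$t[s]
        n_raw <- sum(raw_t >= t0 & raw_t < t0 + window_s)
        tibble::tibble(
          device = rec$device, participant = rec$participant,
          task = rec$task, repetition = rec$repetition,
          clip_id = sprintf("%s/%s/%s/r%d/c%02d", rec$device, rec$participant,
                            rec$task, rec$repetition, k),
          start_time = t0, rate = rate, nominal_rate = rec$nominal_rate,
          window_samples = W, raw_sample_count = n_raw,
          valid = n_raw >= 0.8 * expected,
          accel = list(acc_mat[s:(s + W - 1L), , drop = FALSE]),
          accel_raw = list(raw_mat[s:(s + W - 1L), , drop = FALSE]),
          gyro = list(if (has_gyro) gyr_mat[s:(s + W - 1L), , drop = FALSE])
        )
      })
    }
  )
  clips <- dplyr::bind_rows(purrr::flatten(rows))
  if (nrow(clips) == 0) return(clips)
  if (!is.null(annotations)) {
    wide <- tidyr::pivot_wider(annotations, names_from = "symptom",
                               values_from = "score")
    if (!"bradykinesia" %in% names(wide)) wide$bradykinesia <- NA_integer_
    if (!"tremor" %in% names(wide)) wide$tremor <- NA_integer_
    wide <- dplyr::rename(wide, tremor_score = "tremor",
                          brady_score = "bradykinesia")
    clips <- dplyr::left_join(clips, wide,
                              by = c("participant", "task", "repetition"))
  }
  clips
}

#' Run the full preprocessing chain
#'
#' Convenience wrapper enforcing the pipeline order regularize ->
#' downsample -> high-pass -> segment on a dataset's recordings.
#'
#' @param dataset A `wp_dataset` (or a list with `recordings` and
#'   `annotations`).
#' @param target_rate Optional target sampling rate in Hz applied to every
#'   recording; `NULL` keeps each device at its nominal rate.
#' @param cutoff High-pass cutoff in Hz for accelerometer channels.
#' @param window_s,overlap Segmentation parameters.
#' @param devices Which devices to keep (default all present).
#' @param verbose Log the stages to `message()`.
#' @return A clips tibble (see [segment_clips()]).
#' @export
preprocess <- function(dataset, target_rate = NULL, cutoff = 0.5,
                       window_s = 5, overlap = 0.5, devices = NULL,
                       verbose = FALSE) {
  recs <- dataset$recordings
  if (!is.null(devices)) recs <- dplyr::filter(recs, .data$device %in% devices)
  say <- function(...) if (verbose) message(sprintf(...))
  say("preprocess: regularize (%d recordings)", nrow(recs))
  recs <- regularize(recs)
  if (!is.null(target_rate)) {
    say("preprocess: downsample to %g Hz", target_rate)
    recs <- downsample(recs, target_rate)
  }
  say("preprocess: high-pass accelerometer at %g Hz", cutoff)
  recs <- highpass_accel(recs, cutoff)
  say("preprocess: segment into %g-s clips, %g%% overlap", window_s, overlap * 100)
  segment_clips(recs, dataset$annotations, window_s, overlap)
}
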