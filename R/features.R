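# population central moments with degenerate-signal conventions:
# zero variance => skew 0, excess kurtosis 0
pop_moments <- function(x) {
  mu <- mean(x)
  d <- x - mu
  m2 <- mean(d^2)
  if (m2 <= .Machine$double.eps * (mean(x^2) + 1)) {
    return(list(mean = mu, var = 0, sd = 0, skew = 0, kurt = 0))
  }
  list(mean = mu, var = m2, sd = sqrt(m2),
       skew = mean(d^3) / m2^1.5, kurt = mean(d^4) / m2^2 - 3)
}

#' Per-sample magnitude of a tri-axial signal
#'
#' @param mat A W x 3 numeric matrix (axes in columns).
#' @return Numeric vector of Euclidean norms, length W.
#' @examples
#' magnitude(cbind(3, 4, 0))  # 5
#' @export
magnitude <- function(mat) {
  stopifnot(is.matrix(mat), ncol(mat) == 3)
  sqrt(rowSums(mat^2))
}

#' Time-domain features of a signal
#'
#' Root mean square, range, mean, variance, skew, and excess kurtosis.
#' Moments are population moments; a constant signal has skew 0 and
#' kurtosis 0 by convention.
#'
#' @param x Numeric vector, length >= 2.
#' @return Named numeric vector `rms`, `range`, `mean`, `variance`, `skew`,
#'   `kurtosis`.
#' @export
time_features <- function(x) {
  if (length(x) < 2) abort("time features need >= 2 samples", class = "wp_data_error")
  mo <- pop_moments(x)
  c(rms = sqrt(mean(x^2)), range = max(x) - min(x), mean = mo$mean,
    variance = mo$var, skew = mo$skew, kurtosis = mo$kurt)
}

# one-sided Hann-windowed periodogram of the mean-removed signal,
# DC bin excluded
clip_psd <- function(x, rate) {
  W <- length(x)
  w <- 0.5 * (1 - cos(2 * pi * (0:(W - 1)) / (W - 1)))
  X <- fft((x - mean(x)) * w)
  nb <- floor(W / 2)
  psd <- (2 * Mod(X[2:(nb + 1)])^2) / (rate * sum(w^2))
  list(freq = (1:nb) * rate / W, psd = psd)
}

#' Frequency-domain features of a signal
#'
#' Computes a Hann-windowed periodogram of the mean-removed clip (a Welch
#' estimate with a single full-length segment) and summarizes it with the
#' dominant frequency (argmax bin, DC excluded), the relative magnitude
#' (power in the dominant bin and its two immediate neighbors -- the main
#' lobe of a windowed tone -- as a fraction of total power), and the
#' spectral moments of frequency treating the normalized power spectral
#' density as a probability mass over bins: spectral centroid, spread (SD),
#' skew, and excess kurtosis. A zero-power signal returns all zeros by
#' convention.
#'
#' @param x Numeric vector, length >= 8.
#' @param rate Sampling rate in Hz.
#' @return Named numeric vector `dom_freq`, `rel_mag`, `psd_mean`,
#'   `psd_sd`, `psd_skew`, `psd_kurtosis`.
#' @export
frequency_features <- function(x, rate) {
  if (length(x) < 8) abort("frequency features need >= 8 samples", class = "wp_data_error")
  stopifnot(rate > 0)
  sp <- clip_psd(x, rate)
  tot <- sum(sp$psd)
  if (tot <= 0 || !is.finite(tot)) {
    return(c(dom_freq = 0, rel_mag = 0, psd_mean = 0, psd_sd = 0,
             psd_skew = 0, psd_kurtosis = 0))
  }
  i <- which.max(sp$psd)
  lobe <- max(1, i - 1):min(length(sp$psd), i + 1)
  p <- sp$psd / tot
  mu <- sum(p * sp$freq)
  m2 <- sum(p * (sp$freq - mu)^2)
  if (m2 <= .Machine$double.eps * mu^2) {
    sk <- 0; ku <- 0; m2 <- max(m2, 0)
  } else {
    sk <- sum(p * (sp$freq - mu)^3) / m2^1.5
    ku <- sum(p * (sp$freq - mu)^4) / m2^2 - 3
  }
  c(dom_freq = sp$freq[i], rel_mag = sum(sp$psd[lobe]) / tot, psd_mean = mu,
    psd_sd = sqrt(m2), psd_skew = sk, psd_kurtosis = ku)
}

#' Sample entropy of a signal
#'
#' SampEn(m, r) = -ln(A / B), where B counts template pairs of length `m`
#' within Chebyshev tolerance `r` and A counts the same pairs still matching
#' at length m + 1; self-matches are excluded and both counts range over the
#' N - m templates that admit an (m+1)-length extension. Higher values mean
#' less self-similarity (more irregularity). When no pair matches at either
#' length the value is undefined; it is capped at `log((N-m) * (N-m-1))`,
#' the -ln of the smallest expressible nonzero conditional probability.
#' A constant signal returns 0 (every pair matches at both lengths).
#'
#' @param x Numeric vector, length > m + 1.
#' @param m Template length (default 2).
#' @param r Tolerance; default 0.2 x population SD of `x`.
#' @return A single non-negative number.
#' @export
sample_entropy <- function(x, m = 2, r = 0.2 * sqrt(mean((x - mean(x))^2))) {
  n <- length(x)
  if (n <= m + 1) abort("sample entropy needs length > m + 1", class = "wp_data_error")
  cnt <- sampen_counts(as.numeric(x), as.integer(m), r)
  cap <- log((n - m) * (n - m - 1))
  if (cnt$B == 0 || cnt$A == 0) return(cap)
  min(-log(cnt$A / cnt$B), cap)
}

# full-lag normalized cross-correlation peak from precomputed spectra;
# ties toward smallest |lag|
xcorr_pick <- function(z, W, den, rate) {
  if (den <= 0) return(c(peak = 0, lag = 0))
  z <- z / den
  best <- max(z)
  cand <- which(z >= best - 1e-12)
  lags <- cand - W
  pick <- cand[order(abs(lags), lags)][1]
  c(peak = z[pick], lag = (pick - W) / rate)
}

# cross-correlations of all three axis pairs sharing one FFT per axis;
# linear cross-correlation sum_t x[t] y[t - d] at lags d = -(W-1)..(W-1),
# laid out as index k = d + W in 1..2W-1
xcorr_triple <- function(mat, rate) {
  W <- nrow(mat)
  L <- stats::nextn(2 * W - 1, c(2, 3, 5))
  pad <- matrix(0, L, 3)
  pad[1:W, 1] <- mat[, 1] - sum(mat[, 1]) / W
  pad[1:W, 2] <- mat[, 2] - sum(mat[, 2]) / W
  pad[1:W, 3] <- mat[, 3] - sum(mat[, 3]) / W
  ss <- colSums(pad^2)
  Fx <- stats::mvfft(pad)
  P <- cbind(Fx[, 1] * Conj(Fx[, 2]), Fx[, 1] * Conj(Fx[, 3]),
             Fx[, 2] * Conj(Fx[, 3]))
  full <- Re(stats::mvfft(P, inverse = TRUE)) / L
  grab <- function(col, den)
    xcorr_pick(c(full[(L - W + 2):L, col], full[1:W, col]), W, den, rate)
  list(xy = grab(1, sqrt(ss[1] * ss[2])), xz = grab(2, sqrt(ss[1] * ss[3])),
       yz = grab(3, sqrt(ss[2] * ss[3])))
}

#' Cross-correlation features of a tri-axial signal
#'
#' For each axis pair (XY, XZ, YZ): the peak of the normalized (unit-energy)
#' cross-correlation of the mean-removed axes over all lags, and the signed
#' lag in seconds at that peak. Ties are broken toward the smallest absolute
#' lag; a zero-variance axis yields peak 0 and lag 0 by convention.
#'
#' @param mat A W x 3 numeric matrix (W >= 2).
#' @param rate Sampling rate in Hz (lag unit conversion).
#' @return Named numeric vector `peak_xy`, `peak_xz`, `peak_yz`, `lag_xy`,
#'   `lag_xz`, `lag_yz`.
#' @export
correlation_features <- function(mat, rate) {
  stopifnot(is.matrix(mat), ncol(mat) == 3)
  if (nrow(mat) < 2) abort("correlation features need >= 2 samples", class = "wp_data_error")
  tr <- xcorr_triple(mat, rate)
  c(peak_xy = unname(tr$xy["peak"]), peak_xz = unname(tr$xz["peak"]),
    peak_yz = unname(tr$yz["peak"]), lag_xy = unname(tr$xy["lag"]),
    lag_xz = unname(tr$xz["lag"]), lag_yz = unname(tr$yz["lag"]))
}

#' Derivative features of a signal
#'
#' Moments (mean, SD, skew, excess kurtosis) of the first forward
#' difference scaled by the sampling rate (a discrete derivative in units
#' per second). Population-moment conventions as in [time_features()].
#'
#' @param x Numeric vector, length >= 3.
#' @param rate Sampling rate in Hz.
#' @return Named numeric vector `mean`, `sd`, `skew`, `kurtosis`.
#' @export
derivative_features <- function(x, rate) {
  if (length(x) < 3) abort("derivative features need >= 3 samples", class = "wp_data_error")
  d <- diff(x) * rate
  mo <- pop_moments(d)
  c(mean = mo$mean, sd = mo$sd, skew = mo$skew, kurtosis = mo$kurt)
}

CATEGORIES <- c("T", "F", "E", "C", "D")
cat_stats <- list(
  T = c("rms", "range", "mean", "variance", "skew", "kurtosis"),
  F = c("dom_freq", "rel_mag", "psd_mean", "psd_sd", "psd_skew", "psd_kurtosis"),
  E = "sampen",
  C = c("peak_xy", "peak_xz", "peak_yz", "lag_xy", "lag_xz", "lag_yz"),
  D = c("mean", "sd", "skew", "kurtosis")
)

#' Canonical feature names
#'
#' Enumerates the engineered feature set in its stable canonical order:
#' modalities (accel, gyro) x categories (T time, F frequency, E entropy,
#' C correlation, D derivative) x sources (axes x/y/z and magnitude; axis
#' pairs for C) x statistic. The full set is 74 features per modality
#' (57 tri-axial + 17 magnitude) and 148 for both. With
#' `magnitude_only = TRUE` the tri-axial features are dropped except the six
#' cross-correlation features, which have no magnitude counterpart and are
#' kept as-is (17 + 6 = 23 per modality).
#'
#' @param categories Subset of `c("T", "F", "E", "C", "D")`.
#' @param modalities Subset of `c("accel", "gyro")`.
#' @param magnitude_only Keep only magnitude-based features (plus the
#'   retained correlation features)?
#' @return Character vector of feature names like `accel_x_T_rms`.
#' @examples
#' length(feature_names())                      # 148
#' length(feature_names(modalities = "accel"))  # 74
#' @export
feature_names <- function(categories = CATEGORIES,
                          modalities = c("accel", "gyro"),
                          magnitude_only = FALSE) {
  categories <- match.arg(categories, CATEGORIES, several.ok = TRUE)
  modalities <- match.arg(modalities, c("accel", "gyro"), several.ok = TRUE)
  categories <- CATEGORIES[CATEGORIES %in% categories]
  out <- character(0)
  for (mod in modalities) {
    for (cat in categories) {
      if (cat == "C") {
        out <- c(out, sprintf("%s_%s_C_%s", mod,
                              c("xy", "xz", "yz", "xy", "xz", "yz"),
                              cat_stats$C))
      } else {
        src <- if (magnitude_only) "mag" else c("x", "y", "z", "mag")
        for (s in src)
          out <- c(out, sprintf("%s_%s_%s_%s", mod, s, cat, cat_stats[[cat]]))
      }
    }
  }
  out
}

# features for one modality matrix (W x 3) for the requested categories;
# `mag_source` is the matrix the magnitude channel is computed from (the
# unfiltered accelerometer, where available)
modality_features <- function(mat, rate, mod, categories, magnitude_only,
                              sampen_m = 2, sampen_r_factor = 0.2,
                              mag_source = mat) {
  chans <- if (magnitude_only) list(mag = magnitude(mag_source)) else
    list(x = mat[, 1], y = mat[, 2], z = mat[, 3], mag = magnitude(mag_source))
  out <- numeric(0)
  for (cat in CATEGORIES[CATEGORIES %in% categories]) {
    vals <- switch(cat,
      T = unlist(lapply(chans, time_features)),
      F = unlist(lapply(chans, frequency_features, rate = rate)),
      E = unlist(lapply(chans, function(ch) {
        c(sampen = sample_entropy(ch, m = sampen_m,
                                  r = sampen_r_factor * sqrt(mean((ch - mean(ch))^2))))
      })),
      C = correlation_features(mat, rate),
      D = unlist(lapply(chans, derivative_features, rate = rate))
    )
    out <- c(out, vals)
  }
  unname(out)
}

#' Extract the engineered feature set from clips
#'
#' Computes the requested feature categories for each valid clip across the
#' requested sensor modalities, in the canonical order of
#' [feature_names()]. Accelerometer axis features are computed on the
#' high-pass filtered channels (orientation removed); the accelerometer
#' magnitude channel is the Euclidean norm of the unfiltered signal
#' (`accel_raw`), which is orientation-invariant by construction and keeps
#' oscillatory power at the oscillation frequency rather than folding it to
#' twice the frequency. Gyroscope channels are used as-is.
#'
#' @param clips Clips tibble from [segment_clips()]. Invalid clips are
#'   dropped with a message.
#' @param categories Feature categories, subset of
#'   `c("T", "F", "E", "C", "D")`.
#' @param modalities `"accel"`, `"gyro"`, or both. Requesting gyro features
#'   on clips without gyroscope channels (watch) is an error.
#' @param magnitude_only Keep only magnitude-based features plus the six
#'   retained tri-axial cross-correlation features.
#' @param sampen_m,sampen_r_factor Sample-entropy template length and
#'   tolerance factor (r = factor x clip SD).
#' @return A tibble with provenance columns (`clip_id`, `device`,
#'   `participant`, `task`, `repetition`, `start_time`), score columns when
#'   present on the clips, and one column per feature.
#' @export
extract_features <- function(clips, categories = CATEGORIES,
                             modalities = c("accel", "gyro"),
                             magnitude_only = FALSE,
                             sampen_m = 2, sampen_r_factor = 0.2) {
  categories <- match.arg(categories, CATEGORIES, several.ok = TRUE)
  modalities <- match.arg(modalities, c("accel", "gyro"), several.ok = TRUE)
  if (any(!clips$valid)) {
    message(sprintf("dropping %d invalid clip(s)", sum(!clips$valid)))
    clips <- dplyr::filter(clips, .data$valid)
  }
  if (nrow(clips) == 0) abort("no valid clips", class = "wp_data_error")
  if ("gyro" %in% modalities &&
      any(vapply(clips$gyro, is.null, logical(1))))
    abort("gyroscope features requested but some clips have no gyro channels",
          class = "wp_missing_modality")
  nm <- feature_names(categories, modalities, magnitude_only)
  mat <- matrix(NA_real_, nrow(clips), length(nm), dimnames = list(NULL, nm))
  has_raw <- "accel_raw" %in% names(clips)
  for (i in seq_len(nrow(clips))) {
    row <- numeric(0)
    for (mod in modalities) {
      m <- if (mod == "accel") clips$accel[[i]] else clips$gyro[[i]]
      mag_src <- if (mod == "accel" && has_raw) clips$accel_raw[[i]] else m
      row <- c(row, modality_features(m, clips$rate[i], mod, categories,
                                      magnitude_only, sampen_m, sampen_r_factor,
                                      mag_source = mag_src))
    }
    mat[i, ] <- row
  }
  prov_cols <- intersect(c("clip_id", "device", "participant", "task",
                           "repetition", "start_time", "rate",
                           "tremor_score", "brady_score"), names(clips))
  dplyr::bind_cols(clips[prov_cols], tibble::as_tibble(mat))
}

all_category_subsets <- function(categories = CATEGORIES) {
  n <- length(categories)
  combos <- list()
  for (k in seq_len(n))
    combos <- c(combos, utils::combn(categories, k, simplify = FALSE))
  combos
}

combo_label <- function(cats) paste(sort(cats), collapse = "")

#' Time feature-category combinations on a clip batch
#'
#' Measures the wall-clock cost of extracting each requested combination of
#' feature categories over a fixed batch of clips, as the median over
#' `repeats` runs. Shared preliminaries (the FFT behind frequency features,
#' the differencing behind derivative features) are computed once per
#' combination, so combination cost is subadditive. Timing is
#' hardware-dependent; only relative values are meaningful.
#'
#' @param clips Clips tibble (a small fixed batch; all must be valid).
#' @param combos List of category subsets; default all 31 non-empty subsets
#'   of the five categories. An empty subset costs 0 ms.
#' @param repeats Number of timing repeats (median taken). Default 3.
#' @param modalities,magnitude_only Passed to [extract_features()].
#' @return A tibble `label` (sorted category letters, e.g. `"CEFT"`),
#'   `categories` (list), `mean_time_ms` (median wall-clock per batch, ms).
#' @export
time_feature_sets <- function(clips, combos = all_category_subsets(),
                              repeats = 3, modalities = c("accel", "gyro"),
                              magnitude_only = FALSE) {
  stopifnot(nrow(clips) >= 1)
  rows <- purrr::map(combos, function(cats) {
    if (length(cats) == 0)
      return(tibble::tibble(label = "", categories = list(character(0)),
                            mean_time_ms = 0))
    times <- vapply(seq_len(repeats), function(r) {
      t0 <- proc.time()[["elapsed"]]
      extract_features(clips, categories = cats, modalities = modalities,
                       magnitude_only = magnitude_only)
      (proc.time()[["elapsed"]] - t0) * 1000
    }, numeric(1))
    tibble::tibble(label = combo_label(cats), categories = list(cats),
                   mean_time_ms = median(times))
  })
  dplyr::bind_rows(rows)
}
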