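#' One-way repeated-measures ANOVA
#'
#' Within-subjects ANOVA on a complete folds x conditions matrix (each fold
#' -- a left-out participant -- evaluated under every condition):
#' F = MS_condition / MS_(fold x condition) with degrees of freedom (k - 1,
#' (n - 1)(k - 1)). No sphericity correction is applied.
#'
#' @param mat Numeric matrix, rows = folds (subjects), columns = conditions.
#' @return A list `F`, `p`, `df1`, `df2`. Identical condition columns give
#'   F = 0, p = 1.
#' @export
rm_anova <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat); k <- ncol(mat)
  if (k < 2 || n < 3) abort("rmANOVA needs >= 2 conditions and >= 3 folds",
                            class = "wp_data_error")
  if (anyNA(mat)) abort("rmANOVA needs a complete matrix", class = "wp_data_error")
  g <- mean(mat)
  ss_cond <- n * sum((colMeans(mat) - g)^2)
  ss_subj <- k * sum((rowMeans(mat) - g)^2)
  ss_tot <- sum((mat - g)^2)
  ss_err <- max(ss_tot - ss_cond - ss_subj, 0)
  df1 <- k - 1; df2 <- (n - 1) * (k - 1)
  scale <- sum(mat^2) + 1
  if (ss_cond <= .Machine$double.eps * scale)
    return(list(F = 0, p = 1, df1 = df1, df2 = df2))
  if (ss_err <= .Machine$double.eps * scale)
    return(list(F = Inf, p = 0, df1 = df1, df2 = df2))
  f <- (ss_cond / df1) / (ss_err / df2)
  list(F = f, p = pf(f, df1, df2, lower.tail = FALSE), df1 = df1, df2 = df2)
}

#' Paired t-test with explicit tail
#'
#' t statistic on the paired differences `a - b`. `tail = "greater"` tests
#' whether `a` exceeds `b` (p = P(T_df >= t)); `tail = "two_sided"` is the
#' usual two-tailed test. Zero-variance differences have no finite t; the
#' documented sentinel is t = 0, p = 0.5 (one-tailed) or 1 (two-tailed)
#' when the common difference is 0, and t = +/-Inf with p = 0 or 1
#' accordingly otherwise.
#'
#' @param a,b Numeric vectors of equal length >= 3.
#' @param tail `"greater"` or `"two_sided"`.
#' @return A list `t`, `p`, `df`, `mean_diff`.
#' @export
paired_t <- function(a, b, tail = c("greater", "two_sided")) {
  tail <- match.arg(tail)
  stopifnot(length(a) == length(b))
  d <- a - b
  n <- length(d)
  if (n < 3) abort("paired t-test needs >= 3 pairs", class = "wp_data_error")
  md <- mean(d); s <- sd(d)
  if (s == 0) {
    if (md == 0)
      return(list(t = 0, p = if (tail == "greater") 0.5 else 1,
                  df = n - 1, mean_diff = 0))
    tt <- sign(md) * Inf
    p <- if (tail == "greater") as.numeric(md < 0) else 0
    return(list(t = tt, p = p, df = n - 1, mean_diff = md))
  }
  tt <- md / (s / sqrt(n))
  p <- if (tail == "greater") pt(tt, n - 1, lower.tail = FALSE)
       else 2 * pt(-abs(tt), n - 1)
  list(t = tt, p = p, df = n - 1, mean_diff = md)
}

#' Holm-Bonferroni step-down correction
#'
#' Adjusted p-values by the Holm step-down procedure (running maximum of
#' (m - i + 1) p_(i), capped at 1, via [stats::p.adjust()]), with rejection
#' flags at family-wise level `alpha`.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @param alpha Family-wise error rate (default 0.05).
#' @return A tibble `raw_p`, `adjusted_p`, `significant`.
#' @examples
#' holm_bonferroni(c(0.01, 0.04, 0.03))
#' @export
holm_bonferroni <- function(p, alpha = 0.05) {
  stopifnot(all(p >= 0 & p <= 1))
  adj <- stats::p.adjust(p, method = "holm")
  tibble::tibble(raw_p = p, adjusted_p = adj, significant = adj <= alpha)
}

#' Pareto filter on computation time versus AUROC
#'
#' Implements the discard rule of the feature-cost analysis: a feature-set
#' entry is retained iff its mean AUROC strictly exceeds the AUROC of every
#' entry with lower computation time (comparison at full floating
#' precision). Entries are ordered by time with a stable lexicographic
#' label tie-break, and times tied at timer resolution are perturbed by a
#' nanosecond ladder in that order so stored times are distinct; the
#' retained entries then strictly increase in both time and AUROC.
#'
#' @param entries Tibble with columns `label`, `mean_time_ms`, `mean_auroc`.
#' @return The entries sorted by time with a logical `retained` column,
#'   class `wp_pareto`.
#' @examples
#' pareto_filter(tibble::tibble(label = c("C", "D", "T", "DT"),
#'                              mean_time_ms = c(4.4, 6.5, 8.2, 11.3),
#'                              mean_auroc = c(.68, .73, .72, .74)))
#' @export
pareto_filter <- function(entries) {
  stopifnot(all(c("label", "mean_time_ms", "mean_auroc") %in% names(entries)))
  out <- entries[order(entries$mean_time_ms, entries$label), ]
  # measured times can tie at timer resolution; perturb ties by a nanosecond
  # ladder in label order so stored times are distinct and the retained
  # frontier is strictly increasing in both coordinates
  pos_in_tie <- stats::ave(seq_len(nrow(out)), out$mean_time_ms,
                           FUN = seq_along)
  out$mean_time_ms <- out$mean_time_ms + (pos_in_tie - 1) * 1e-6
  best <- -Inf
  retained <- logical(nrow(out))
  for (i in seq_len(nrow(out))) {
    retained[i] <- out$mean_auroc[i] > best
    if (retained[i]) best <- out$mean_auroc[i]
  }
  out$retained <- retained
  structure(out, class = c("wp_pareto", class(entries)))
}

#' @export
print.wp_pareto <- function(x, ...) {
  cat(sprintf("<wearpd Pareto frontier: %d of %d feature sets retained>\n",
              sum(x$retained), nrow(x)))
  NextMethod()
}

new_comparison <- function(factor, mat, anova, pairwise) {
  structure(list(factor = factor, conditions = colnames(mat), auroc = mat,
                 anova = anova, pairwise = pairwise),
            class = "wp_comparison")
}

#' @export
print.wp_comparison <- function(x, ...) {
  cat(sprintf("<wearpd comparison: %s, %d folds x %d conditions>\n",
              x$factor, nrow(x$auroc), ncol(x$auroc)))
  cat(sprintf("  rmANOVA F(%d, %d) = %.3f, p = %.4g\n",
              x$anova$df1, x$anova$df2, x$anova$F, x$anova$p))
  means <- colMeans(x$auroc)
  cat("  mean AUROC:", paste(sprintf("%s %.3f", names(means), means),
                             collapse = ", "), "\n")
  if (nrow(x$pairwise) > 0) {
    cat("  post-hoc pairwise tests:\n")
    print(x$pairwise)
  }
  invisible(x)
}

#' Tidiers for comparison results
#'
#' `tidy()` returns the post-hoc pairwise tests (one row per comparison);
#' `glance()` returns the one-row rmANOVA summary with per-condition mean
#' AUROCs.
#'
#' @param x A `wp_comparison` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.wp_comparison <- function(x, ...) x$pairwise

#' @rdname tidy.wp_comparison
#' @export
glance.wp_comparison <- function(x, ...) {
  means <- colMeans(x$auroc)
  dplyr::bind_cols(
    tibble::tibble(factor = x$factor, statistic = x$anova$F,
                   p.value = x$anova$p, df1 = x$anova$df1, df2 = x$anova$df2,
                   n_folds = nrow(x$auroc)),
    tibble::as_tibble(as.list(stats::setNames(means, paste0("auroc_", names(means)))))
  )
}

# per-fold AUROC for a named list of condition feature tibbles, aligned by
# left-out participant; folds unevaluable under any condition are dropped
# so the paired design stays complete
fold_auroc_matrix <- function(condition_features, symptom, mode,
                              condition_cols = NULL, n_trees = 50, seed = 1L) {
  conds <- names(condition_features)
  evals <- lapply(conds, function(cn) {
    evaluate_lopo(condition_features[[cn]], symptom, mode,
                  feature_cols = condition_cols[[cn]],
                  n_trees = n_trees, seed = seed)
  })
  parts <- sort(Reduce(intersect, lapply(evals, function(e) e$left_out)))
  mat <- vapply(evals, function(e) e$auroc[match(parts, e$left_out)],
                numeric(length(parts)))
  dimnames(mat) <- list(parts, conds)
  keep <- stats::complete.cases(mat)
  if (any(!keep))
    warn(sprintf("dropping %d fold(s) unevaluable under some condition",
                 sum(!keep)))
  mat[keep, , drop = FALSE]
}

posthoc_tests <- function(mat, pairs, alpha = 0.05) {
  res <- purrr::map(pairs, function(pr) {
    tt <- paired_t(mat[, pr$a], mat[, pr$b], tail = pr$tail)
    tibble::tibble(pair = sprintf("%s vs %s", pr$a, pr$b), tail = pr$tail,
                   t = tt$t, raw_p = tt$p, mean_diff = tt$mean_diff)
  })
  out <- dplyr::bind_rows(res)
  hb <- holm_bonferroni(out$raw_p, alpha)
  out$adjusted_p <- hb$adjusted_p
  out$significant <- hb$significant
  out
}

#' Sensor-set comparison experiment
#'
#' Compares LOPO model performance across four sensor sets: the hand
#' sensor's accelerometer + gyroscope features combined (Combo, 148
#' features), its accelerometer alone (Accel, 74), its gyroscope alone
#' (Gyro, 74), and the wrist watch accelerometer (Watch, 74). A one-way
#' repeated-measures ANOVA tests for an effect of sensor set; if
#' significant at `alpha`, post-hoc paired t-tests run exactly the planned
#' comparisons -- Combo > Accel, Combo > Gyro, Combo > Watch (one-tailed:
#' does the combination buy anything?) and Accel vs Watch (two-tailed:
#' hardware/placement difference) -- with Holm-Bonferroni correction.
#'
#' @param dataset A `wp_dataset` with both devices.
#' @param symptom,mode Model configuration.
#' @param n_trees,seed Forest parameters.
#' @param alpha Significance level for the ANOVA gate and the family-wise
#'   rate.
#' @param hand_features,watch_features Optional precomputed feature tibbles
#'   (full 148-feature hand set and 74-feature watch set) to avoid
#'   recomputation across model configurations.
#' @return A `wp_comparison`.
#' @export
sensor_set_experiment <- function(dataset, symptom = c("tremor", "bradykinesia"),
                                  mode = c("binary", "multiclass"),
                                  n_trees = 50, seed = 1L, alpha = 0.05,
                                  hand_features = NULL, watch_features = NULL) {
  symptom <- match.arg(symptom)
  mode <- match.arg(mode)
  devs <- unique(dataset$recordings$device)
  if (!all(c("hand_sensor", "watch") %in% devs))
    abort("sensor-set experiment needs hand_sensor and watch recordings",
          class = "wp_data_error")
  if (is.null(hand_features)) {
    hand_clips <- preprocess(dataset, devices = "hand_sensor")
    hand_features <- extract_features(hand_clips)
  }
  if (is.null(watch_features)) {
    watch_clips <- preprocess(dataset, devices = "watch")
    watch_features <- extract_features(watch_clips, modalities = "accel")
  }
  feats <- list(Combo = hand_features, Accel = hand_features,
                Gyro = hand_features, Watch = watch_features)
  cols <- list(
    Combo = feature_names(),
    Accel = feature_names(modalities = "accel"),
    Gyro = feature_names(modalities = "gyro"),
    Watch = feature_names(modalities = "accel")
  )
  mat <- fold_auroc_matrix(feats, symptom, mode, cols, n_trees, seed)
  an <- rm_anova(mat)
  pairwise <- if (an$p < alpha) {
    posthoc_tests(mat, list(
      list(a = "Combo", b = "Accel", tail = "greater"),
      list(a = "Combo", b = "Gyro", tail = "greater"),
      list(a = "Combo", b = "Watch", tail = "greater"),
      list(a = "Accel", b = "Watch", tail = "two_sided")
    ), alpha)
  } else tibble::tibble()
  new_comparison("sensor_set", mat, an, pairwise)
}

# symptom-specific sensor set used downstream of the sensor-set analysis:
# accelerometer alone suffices for tremor, Combo for bradykinesia
symptom_modalities <- function(symptom, device) {
  if (device == "watch") return("accel")
  if (symptom == "tremor") "accel" else c("accel", "gyro")
}

#' Sampling-rate comparison experiment
#'
#' Evaluates LOPO performance of one symptom model at the device's original
#' rate and a ladder of lower rates (down to 5 Hz), re-running downsample ->
#' high-pass -> segment -> extract at each rate. The sensor set is fixed to
#' the one identified by the sensor-set analysis (Accel for tremor, Combo
#' for bradykinesia; the watch always contributes accelerometer only).
#' rmANOVA tests for a rate effect; if significant, one-tailed paired
#' t-tests compare the original rate against every lower rate
#' (Holm-Bonferroni corrected).
#'
#' @param dataset A `wp_dataset`.
#' @param symptom,mode Model configuration.
#' @param rates Candidate rates in Hz; rates above the device nominal rate
#'   are dropped (the watch ladder starts at 50 Hz).
#' @param device `"hand_sensor"` or `"watch"`.
#' @param n_trees,seed,alpha As elsewhere.
#' @return A `wp_comparison` with one condition per rate (labels like
#'   `"62.5"`).
#' @export
sampling_rate_experiment <- function(dataset,
                                     symptom = c("tremor", "bradykinesia"),
                                     mode = c("binary", "multiclass"),
                                     rates = c(62.5, 50, 40, 30, 20, 10, 7.5, 5),
                                     device = "hand_sensor",
                                     n_trees = 50, seed = 1L, alpha = 0.05) {
  symptom <- match.arg(symptom)
  mode <- match.arg(mode)
  recs <- dplyr::filter(dataset$recordings, .data$device == !!device)
  if (nrow(recs) == 0) abort("no recordings for requested device",
                             class = "wp_data_error")
  nominal <- recs$nominal_rate[1]
  rates <- sort(rates[rates <= nominal], decreasing = TRUE)
  mods <- symptom_modalities(symptom, device)
  reg <- regularize(recs)
  feats <- lapply(rates, function(r) {
    clips <- segment_clips(highpass_accel(downsample(reg, r)),
                           dataset$annotations)
    extract_features(dplyr::filter(clips, .data$valid), modalities = mods)
  })
  names(feats) <- format(rates, trim = TRUE, drop0trailing = TRUE)
  mat <- fold_auroc_matrix(feats, symptom, mode, n_trees = n_trees, seed = seed)
  an <- rm_anova(mat)
  orig <- colnames(mat)[1]
  pairwise <- if (an$p < alpha) {
    posthoc_tests(mat, lapply(colnames(mat)[-1], function(r) {
      list(a = orig, b = r, tail = "greater")
    }), alpha)
  } else tibble::tibble()
  new_comparison("sampling_rate", mat, an, pairwise)
}

#' Feature-category cost/performance experiment
#'
#' At a 30 Hz working rate, trains one LOPO model for each of the 31
#' non-empty subsets of the five feature categories, measures each subset's
#' computation time on a fixed clip batch, and applies the Pareto discard
#' rule: any subset that does not beat every cheaper subset's mean AUROC is
#' discarded. The retained frontier (strictly increasing in both time and
#' AUROC) then enters a repeated-measures ANOVA; if significant, one-tailed
#' paired t-tests compare the costliest retained set against each other
#' retained set, Holm-Bonferroni corrected. With `magnitude_only = TRUE`
#' the analysis is repeated using only magnitude-based features (the six
#' tri-axial cross-correlation features are kept, having no magnitude
#' counterpart).
#'
#' @param dataset A `wp_dataset`.
#' @param symptom,mode Model configuration; the sensor set follows the
#'   symptom (Accel for tremor, Combo for bradykinesia).
#' @param magnitude_only Restrict to magnitude-based features?
#' @param target_rate Working sampling rate (default 30 Hz).
#' @param timing_clips Number of clips in the timing batch (default 100).
#' @param timing_repeats Timing repeats (median taken, default 3).
#' @param n_trees,seed,alpha As elsewhere.
#' @return A list with `pareto` (a `wp_pareto` over all 31 subsets),
#'   `comparison` (a `wp_comparison` over the retained subsets), and
#'   `fold_auroc` (the full folds x 31-subsets matrix).
#' @export
feature_set_experiment <- function(dataset,
                                   symptom = c("tremor", "bradykinesia"),
                                   mode = c("binary", "multiclass"),
                                   magnitude_only = FALSE, target_rate = 30,
                                   timing_clips = 100, timing_repeats = 3,
                                   n_trees = 50, seed = 1L, alpha = 0.05) {
  symptom <- match.arg(symptom)
  mode <- match.arg(mode)
  mods <- symptom_modalities(symptom, "hand_sensor")
  clips <- preprocess(dataset, target_rate = target_rate,
                      devices = "hand_sensor")
  clips <- dplyr::filter(clips, .data$valid)
  full <- extract_features(clips, modalities = mods,
                           magnitude_only = magnitude_only)
  combos <- all_category_subsets()
  timing <- time_feature_sets(head(clips, timing_clips), combos,
                              repeats = timing_repeats, modalities = mods,
                              magnitude_only = magnitude_only)
  feats <- stats::setNames(rep(list(full), length(combos)),
                           vapply(combos, combo_label, character(1)))
  cols <- stats::setNames(lapply(combos, function(cats) {
    feature_names(cats, mods, magnitude_only)
  }), names(feats))
  mat <- fold_auroc_matrix(feats, symptom, mode, cols, n_trees, seed)
  entries <- tibble::tibble(
    label = timing$label, mean_time_ms = timing$mean_time_ms,
    mean_auroc = colMeans(mat)[timing$label]
  )
  pareto <- pareto_filter(entries)
  kept <- pareto$label[pareto$retained]
  sub <- mat[, kept, drop = FALSE]
  an <- rm_anova(sub)
  ref <- kept[length(kept)]  # costliest retained set
  pairwise <- if (an$p < alpha && length(kept) > 1) {
    posthoc_tests(sub, lapply(setdiff(kept, ref), function(cn) {
      list(a = ref, b = cn, tail = "greater")
    }), alpha)
  } else tibble::tibble()
  list(pareto = pareto, comparison = new_comparison("feature_set", sub, an, pairwise),
       fold_auroc = mat)
}
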