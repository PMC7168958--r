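#' Build classification labels from clip scores
#'
#' Binary mode: the symptom is present (1) when the clinician score is 1-4
#' and absent (0) at score 0. Multiclass mode: the 0-4 score itself. Clips
#' without a score for the requested symptom (e.g. bradykinesia during
#' low-movement tasks) are excluded.
#'
#' @param features Feature tibble from [extract_features()] (any tibble
#'   with `tremor_score` / `brady_score` columns).
#' @param symptom `"tremor"` or `"bradykinesia"`.
#' @param mode `"binary"` or `"multiclass"`.
#' @return The input rows that carry a score, with a `label` factor column
#'   appended.
#' @export
make_labels <- function(features, symptom = c("tremor", "bradykinesia"),
                        mode = c("binary", "multiclass")) {
  symptom <- match.arg(symptom)
  mode <- match.arg(mode)
  col <- if (symptom == "tremor") "tremor_score" else "brady_score"
  stopifnot(col %in% names(features))
  out <- dplyr::filter(features, !is.na(.data[[col]]))
  score <- out[[col]]
  out$label <- if (mode == "binary")
    factor(as.integer(score >= 1), levels = c(0, 1))
  else
    factor(score, levels = 0:4)
  out
}

#' Leave-one-participant-out folds
#'
#' One fold per participant: the fold's test set is every clip from that
#' participant (including overlapping windows) and its training set is
#' every clip from all other participants, so no participant's data ever
#' appears on both sides.
#'
#' @param features A tibble with a `participant` column.
#' @return A tibble `left_out`, `train_idx`, `test_idx` (row-index list
#'   columns into `features`).
#' @export
lopo_folds <- function(features) {
  parts <- sort(unique(features$participant))
  if (length(parts) < 2)
    abort("leave-one-participant-out needs >= 2 participants",
          class = "wp_config_error")
  tibble::tibble(
    left_out = parts,
    train_idx = lapply(parts, function(p) which(features$participant != p)),
    test_idx = lapply(parts, function(p) which(features$participant == p))
  )
}

#' Binary AUROC by pairwise concordance
#'
#' The probability that a randomly chosen positive receives a higher score
#' than a randomly chosen negative, counting ties as 1/2 -- equivalent to
#' the trapezoidal area under the ROC curve. Computed from midranks.
#'
#' @param scores Numeric classifier scores (higher = more positive).
#' @param labels Binary labels (0/1, logical, or a 2-level factor whose
#'   second level is positive).
#' @return AUROC in `[0, 1]`.
#' @examples
#' binary_auroc(c(.9, .8, .1, .2), c(1, 1, 0, 0))  # 1
#' @export
binary_auroc <- function(scores, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0)
    abort("both classes must be present to compute AUROC",
          class = "wp_data_error")
  r <- rank(scores)  # midranks handle ties as 1/2
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Weighted multiclass AUROC (one-vs-rest)
#'
#' For each class present in the test labels, a one-vs-rest binary AUROC is
#' computed from that class's predicted probability; the per-class values
#' are averaged with weights equal to the class prevalence in the test set,
#' renormalized over the classes present. Classes absent from the test set
#' (score 4 is never observed under the default generator) are skipped.
#'
#' @param prob Matrix of class probabilities, columns named by class.
#' @param labels Factor (or vector) of true classes.
#' @return A list `auroc` (weighted average), `per_class` (named vector),
#'   `weights` (named vector summing to 1).
#' @export
multiclass_auroc <- function(prob, labels) {
  labels <- as.character(labels)
  present <- sort(unique(labels))
  if (length(present) < 2)
    abort("multiclass AUROC needs >= 2 classes present",
          class = "wp_data_error")
  per <- vapply(present, function(cl) {
    binary_auroc(prob[, cl], labels == cl)
  }, numeric(1))
  w <- vapply(present, function(cl) mean(labels == cl), numeric(1))
  w <- w / sum(w)
  list(auroc = sum(w * per), per_class = per, weights = w)
}

#' Fit and score a random forest on one fold
#'
#' Trains a probability random forest (50 trees by default) on the training
#' clips and scores the held-out clips with the binary or weighted
#' multiclass AUROC. A binary fold whose test set contains a single class
#' has no defined AUROC; it is marked unevaluable (`NA`) with a warning and
#' is excluded from fold averages upstream.
#'
#' @param train,test Labeled feature tibbles (from [make_labels()]).
#' @param feature_cols Character vector of feature column names.
#' @param n_trees Number of trees (default 50).
#' @param seed Integer seed for the forest.
#' @return A list `auroc`, `per_class`, `weights` (the last two `NULL` in
#'   binary mode).
#' @export
fit_and_score <- function(train, test, feature_cols, n_trees = 50, seed = 1L) {
  if (length(unique(train$label)) < 2)
    abort("training data contains a single class", class = "wp_data_error")
  fit <- ranger::ranger(
    x = as.data.frame(train[feature_cols]), y = droplevels(train$label),
    num.trees = n_trees, probability = TRUE, seed = seed, num.threads = 1
  )
  prob <- stats::predict(fit, data = as.data.frame(test[feature_cols]))$predictions
  binary <- nlevels(train$label) == 2 && all(levels(train$label) %in% c("0", "1"))
  test_classes <- unique(as.character(test$label))
  if (binary) {
    if (length(test_classes) < 2) {
      warn("fold test set has a single class; marked unevaluable")
      return(list(auroc = NA_real_, per_class = NULL, weights = NULL))
    }
    list(auroc = binary_auroc(prob[, "1"], test$label == "1"),
         per_class = NULL, weights = NULL)
  } else {
    if (length(test_classes) < 2) {
      warn("fold test set has a single class; marked unevaluable")
      return(list(auroc = NA_real_, per_class = NULL, weights = NULL))
    }
    multiclass_auroc(prob, test$label)
  }
}

#' Leave-one-participant-out evaluation of a symptom classifier
#'
#' Runs the full LOPO cross-validation for one model configuration: builds
#' labels, splits by participant, fits a 50-tree probability random forest
#' per fold, and scores each held-out participant with the binary or
#' weighted multiclass AUROC.
#'
#' @param features Feature tibble from [extract_features()].
#' @param symptom `"tremor"` or `"bradykinesia"`.
#' @param mode `"binary"` or `"multiclass"`.
#' @param feature_cols Feature columns to use; default every canonical
#'   feature name present in `features`.
#' @param n_trees,seed Forest size and seed.
#' @return A `wp_lopo` object: tibble `left_out`, `auroc`, `n_test` with
#'   attributes recording the configuration. Methods: [tidy()],
#'   [glance()] (mean AUROC with a 95% t-interval across folds),
#'   [autoplot()].
#' @export
evaluate_lopo <- function(features, symptom = c("tremor", "bradykinesia"),
                          mode = c("binary", "multiclass"),
                          feature_cols = NULL, n_trees = 50, seed = 1L) {
  symptom <- match.arg(symptom)
  mode <- match.arg(mode)
  if (is.null(feature_cols))
    feature_cols <- intersect(feature_names(), names(features))
  stopifnot(length(feature_cols) > 0)
  labeled <- make_labels(features, symptom, mode)
  folds <- lopo_folds(labeled)
  res <- purrr::pmap(folds, function(left_out, train_idx, test_idx) {
    r <- fit_and_score(labeled[train_idx, ], labeled[test_idx, ],
                       feature_cols, n_trees, seed)
    tibble::tibble(left_out = left_out, auroc = r$auroc,
                   n_test = length(test_idx))
  })
  out <- dplyr::bind_rows(res)
  structure(out, class = c("wp_lopo", class(out)),
            symptom = symptom, mode = mode, n_trees = n_trees, seed = seed,
            n_features = length(feature_cols))
}

lopo_summary <- function(auroc) {
  auroc <- auroc[!is.na(auroc)]
  n <- length(auroc)
  m <- mean(auroc)
  half <- if (n > 1) qt(0.975, n - 1) * sd(auroc) / sqrt(n) else NA_real_
  tibble::tibble(mean_auroc = m, ci_lo = m - half, ci_hi = m + half,
                 n_folds = n)
}

#' @export
print.wp_lopo <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<wearpd LOPO evaluation: %s, %s, %d folds>\n",
              attr(x, "symptom"), attr(x, "mode"), nrow(x)))
  cat(sprintf("  mean AUROC %.3f (95%% CI %.3f-%.3f)\n",
              g$mean_auroc, g$ci_lo, g$ci_hi))
  invisible(x)
}

#' @rdname evaluate_lopo
#' @param x A `wp_lopo` object.
#' @param ... Unused.
#' @export
tidy.wp_lopo <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname evaluate_lopo
#' @export
glance.wp_lopo <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(symptom = attr(x, "symptom"), mode = attr(x, "mode")),
    lopo_summary(x$auroc)
  )
}
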