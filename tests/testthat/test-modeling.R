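test_that("labels binarize at score >= 1 and keep the 0-4 scale in multiclass", {
  fx <- tibble::tibble(participant = "P01", tremor_score = c(0L, 1L, 3L),
                       brady_score = c(NA, 0L, 2L))
  bin <- make_labels(fx, "tremor", "binary")
  expect_equal(as.character(bin$label), c("0", "1", "1"))
  mc <- make_labels(fx, "tremor", "multiclass")
  expect_equal(as.character(mc$label), c("0", "1", "3"))
  expect_equal(levels(mc$label), as.character(0:4))
  # clips without a bradykinesia score are excluded from bradykinesia models
  br <- make_labels(fx, "bradykinesia", "multiclass")
  expect_equal(nrow(br), 2)
  expect_equal(as.character(br$label), c("0", "2"))
})

test_that("LOPO folds are one-per-participant with no leakage", {
  fx <- separable_features(n_participants = 13)
  folds <- lopo_folds(fx)
  expect_equal(nrow(folds), 13)
  all_test <- integer(0)
  for (i in seq_len(nrow(folds))) {
    tr_p <- unique(fx$participant[folds$train_idx[[i]]])
    te_p <- unique(fx$participant[folds$test_idx[[i]]])
    expect_length(te_p, 1)
    expect_length(intersect(tr_p, te_p), 0)
    all_test <- c(all_test, folds$test_idx[[i]])
  }
  expect_setequal(all_test, seq_len(nrow(fx)))

  two <- lopo_folds(separable_features(n_participants = 2))
  expect_equal(nrow(two), 2)
  expect_setequal(two$train_idx[[1]], two$test_idx[[2]])

  expect_error(lopo_folds(separable_features(n_participants = 1)),
               class = "wp_config_error")
})

test_that("binary AUROC equals pairwise concordance with tie handling", {
  expect_equal(binary_auroc(c(.9, .8, .1, .2), c(1, 1, 0, 0)), 1)
  expect_equal(binary_auroc(c(.9, .2, .8, .4), c(1, 0, 0, 1)), 0.75)
  expect_equal(binary_auroc(rep(0.3, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_error(binary_auroc(c(.1, .2), c(1, 1)), class = "wp_data_error")

  set.seed(1)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    lab <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(lab)) < 2) next
    sc <- round(runif(n), 2)  # rounded to force ties
    expect_equal(binary_auroc(sc, lab), auroc_oracle(sc, lab))
  }
})

test_that("AUROC is invariant under strictly monotone score transforms", {
  set.seed(2)
  lab <- sample(c(0, 1), 40, replace = TRUE)
  sc <- rnorm(40)
  a <- binary_auroc(sc, lab)
  expect_equal(binary_auroc(exp(sc), lab), a)
  expect_equal(binary_auroc(rank(sc), lab), a)
  expect_equal(binary_auroc(2 * sc - 7, lab), a)
})

test_that("binary AUROC agrees with an established ROC implementation", {
  set.seed(3)
  lab <- sample(c(0, 1), 60, replace = TRUE)
  sc <- rnorm(60) + lab
  expect_equal(binary_auroc(sc, lab),
               as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE))))
})

test_that("weighted multiclass AUROC uses prevalence over present classes", {
  # two balanced, separated classes
  prob <- cbind(`0` = c(.9, .8, .1, .2), `1` = c(.1, .2, .9, .8))
  r <- multiclass_auroc(prob, factor(c(0, 0, 1, 1)))
  expect_equal(r$auroc, 1)
  expect_equal(sum(r$weights), 1)

  # uniform probabilities are uninformative
  pu <- matrix(1 / 3, 6, 3, dimnames = list(NULL, c("0", "1", "2")))
  expect_equal(multiclass_auroc(pu, factor(c(0, 0, 1, 1, 2, 2)))$auroc, 0.5)

  # three-class toy fixture vs hand-computed weighted one-vs-rest
  prob3 <- rbind(c(.7, .2, .1), c(.5, .3, .2), c(.2, .6, .2),
                 c(.3, .4, .3), c(.1, .2, .7), c(.25, .35, .4))
  colnames(prob3) <- c("0", "1", "2")
  lab3 <- factor(c(0, 0, 1, 1, 2, 2), levels = 0:2)
  r3 <- multiclass_auroc(prob3, lab3)
  expected <- (2 / 6) * auroc_oracle(prob3[, "0"], as.integer(lab3 == 0)) +
    (2 / 6) * auroc_oracle(prob3[, "1"], as.integer(lab3 == 1)) +
    (2 / 6) * auroc_oracle(prob3[, "2"], as.integer(lab3 == 2))
  expect_equal(r3$auroc, expected)
  # absent classes are skipped and weights renormalized
  r_sub <- multiclass_auroc(prob3[1:4, ], lab3[1:4])
  expect_named(r_sub$per_class, c("0", "1"))
  expect_equal(sum(r_sub$weights), 1)

  expect_error(multiclass_auroc(prob3[1:2, ], lab3[1:2]),
               class = "wp_data_error")
})

test_that("separable features give near-perfect LOPO AUROC, shuffled labels chance", {
  fx <- separable_features(n_participants = 6, clips_per = 60)
  ev <- evaluate_lopo(fx, "tremor", "binary",
                      feature_cols = c("accel_x_T_rms", "accel_x_T_mean"))
  expect_gte(glance(ev)$mean_auroc, 0.99)

  set.seed(9)
  fx_null <- fx
  fx_null$tremor_score <- sample(fx_null$tremor_score)
  ev_null <- evaluate_lopo(fx_null, "tremor", "binary",
                           feature_cols = c("accel_x_T_rms", "accel_x_T_mean"))
  m <- glance(ev_null)$mean_auroc
  expect_gt(m, 0.4); expect_lt(m, 0.6)
})

test_that("fold scoring is deterministic and degenerate folds are handled", {
  fx <- separable_features(n_participants = 4, clips_per = 30)
  lab <- make_labels(fx, "tremor", "binary")
  folds <- lopo_folds(lab)
  cols <- c("accel_x_T_rms", "accel_x_T_mean")
  r1 <- fit_and_score(lab[folds$train_idx[[1]], ], lab[folds$test_idx[[1]], ],
                      cols, n_trees = 50, seed = 42)
  r2 <- fit_and_score(lab[folds$train_idx[[1]], ], lab[folds$test_idx[[1]], ],
                      cols, n_trees = 50, seed = 42)
  expect_identical(r1$auroc, r2$auroc)

  single_train <- lab[folds$train_idx[[1]], ]
  single_train$label <- factor("1", levels = c("0", "1"))
  expect_error(fit_and_score(single_train, lab[folds$test_idx[[1]], ], cols),
               class = "wp_data_error")

  one_class_test <- lab[folds$test_idx[[1]], ]
  one_class_test$label <- factor("1", levels = c("0", "1"))
  expect_warning(
    r3 <- fit_and_score(lab[folds$train_idx[[1]], ], one_class_test, cols),
    "single class")
  expect_true(is.na(r3$auroc))
})

test_that("LOPO evaluation returns tidy fold results with a t-interval", {
  fx <- separable_features(n_participants = 5, clips_per = 30)
  ev <- evaluate_lopo(fx, "tremor", "binary",
                      feature_cols = c("accel_x_T_rms", "accel_x_T_mean"))
  td <- tidy(ev)
  expect_named(td, c("left_out", "auroc", "n_test"))
  expect_equal(nrow(td), 5)
  g <- glance(ev)
  expect_true(g$ci_lo <= g$mean_auroc && g$mean_auroc <= g$ci_hi)
})
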