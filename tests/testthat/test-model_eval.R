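# printed cross-validation confusion counts and metric tables for the
# four subjects (second count row is FN by the marginal totals)
subject_cv_cells <- list(
  list(cm = list(TP = 3584, FN = 717, FP = 1213, TN = 3088),
       expected = c(accuracy = 0.78, precision = 0.75, recall = 0.83,
                    f1 = 0.79),
       digits = c(2, 2, 2, 2)),
  list(cm = list(TP = 1914, FN = 649, FP = 499, TN = 2064),
       expected = c(accuracy = 0.78, precision = 0.8, recall = 0.75,
                    f1 = 0.77),
       digits = c(2, 1, 2, 2)),
  list(cm = list(TP = 6499, FN = 2459, FP = 1652, TN = 7309),
       expected = c(accuracy = 0.77, precision = 0.8, recall = 0.73,
                    f1 = 0.76),
       digits = c(2, 1, 2, 2)),
  list(cm = list(TP = 1850, FN = 175, FP = 342, TN = 1683),
       expected = c(accuracy = 0.87, precision = 0.84, recall = 0.91,
                    f1 = 0.88),
       digits = c(2, 2, 2, 2))
)

test_that("metrics reproduce all printed CV cells at their printed precision", {
  for (s in subject_cv_cells) {
    m <- metrics_from_confusion(s$cm)
    got <- unlist(m[c("accuracy", "precision", "recall", "f1")])
    for (j in seq_along(got)) {
      expect_equal(round(got[[j]], s$digits[j]), unname(s$expected[j]),
                   label = names(s$expected)[j])
    }
  }
})

test_that("degenerate confusion matrices are handled explicitly", {
  m <- metrics_from_confusion(list(TP = 1, FN = 0, FP = 0, TN = 1))
  expect_equal(unlist(m[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))

  m0 <- metrics_from_confusion(list(TP = 0, FN = 5, FP = 0, TN = 5))
  expect_true(is.na(m0$precision))   # zero denominator -> missing, not 0
  expect_true(is.na(m0$f1))
  expect_equal(m0$recall, 0)

  expect_error(metrics_from_confusion(list(TP = 0, FN = 0, FP = 0, TN = 0)),
               class = "deceptrf_argument_error")
})

test_that("confusion_matrix counts the four cells", {
  truth <- c(1, 1, 1, 0, 0, 0)
  pred <- c(1, 0, 1, 0, 1, 0)
  cm <- confusion_matrix(truth, pred)
  expect_identical(unclass(cm)[c("TP", "FN", "FP", "TN")],
                   list(TP = 2L, FN = 1L, FP = 1L, TN = 2L))
})

sep_data <- function(n = 200, seed = 5) {
  withr::with_seed(seed, {
    y <- rep(0:1, length.out = n)
    x <- data.frame(signal = y * 2 + rnorm(n, 0, 0.1),
                    noise1 = rnorm(n), noise2 = rnorm(n))
    list(x = x, y = y)
  })
}

test_that("the forest fits separable data and is deterministic under seed", {
  d <- sep_data()
  m <- train_classifier(d$x, d$y, num_trees = 50, seed = 3)
  expect_equal(mean(predict(m, d$x) == d$y), 1.0)

  m2 <- train_classifier(d$x, d$y, num_trees = 50, seed = 3)
  expect_identical(predict(m, d$x, type = "prob"),
                   predict(m2, d$x, type = "prob"))

  expect_error(train_classifier(d$x, rep(1L, 200)),
               class = "deceptrf_training_error")
  xna <- d$x; xna$signal[1] <- NA
  expect_error(train_classifier(xna, d$y), class = "deceptrf_argument_error")
})

test_that("pure-noise features give chance-level CV accuracy over 10 seeds", {
  accs <- vapply(1:10, function(s) {
    d <- withr::with_seed(100 + s, {
      list(x = data.frame(matrix(rnorm(400 * 6), 400, 6)),
           y = rep(0:1, 200))
    })
    cv <- cross_validate_10fold(d$x, d$y, seed = s, num_trees = 30)
    cv$metrics$accuracy
  }, numeric(1))
  expect_gt(mean(accs), 0.45)
  expect_lt(mean(accs), 0.55)
})

test_that("10-fold CV is a stratified partition with pooled bookkeeping", {
  d <- sep_data(100)
  cv <- cross_validate_10fold(d$x, d$y, seed = 2, num_trees = 20)
  expect_identical(sort(unique(cv$folds)), 1:10)
  expect_true(all(table(cv$folds) == 10))
  # stratification: each fold has 5 of each class
  for (f in 1:10) expect_equal(sum(d$y[cv$folds == f]), 5)
  pooled <- cv$pooled
  expect_identical(pooled$TP + pooled$FN + pooled$FP + pooled$TN, 100L)
  expect_error(cross_validate_10fold(d$x[1:12, ], d$y[1:12]),
               class = "deceptrf_argument_error")
})

test_that("fold-averaged and pooled metrics agree on balanced data", {
  d <- sep_data(400, seed = 8)
  d$x$signal <- d$y * 1 + rnorm(400, 0, 0.8)  # moderate signal
  cv <- cross_validate_10fold(d$x, d$y, seed = 4, num_trees = 50)
  fold_acc <- vapply(cv$fold_metrics, function(m) m$accuracy, numeric(1))
  expect_lt(abs(mean(fold_acc) - cv$metrics$accuracy), 0.02)
})

test_that("holdout evaluation predicts without refitting and checks the schema", {
  d <- sep_data()
  m <- train_classifier(d$x, d$y, num_trees = 50, seed = 3)
  res <- evaluate_holdout(m, d$x, d$y)
  expect_equal(res$metrics$accuracy, 1.0)

  # label permutation drives accuracy to chance on balanced data
  perm <- withr::with_seed(9, sample(d$y))
  res_p <- evaluate_holdout(m, d$x, perm)
  expect_lt(abs(res_p$metrics$accuracy - 0.5), 0.1)

  bad <- d$x[, 1:2]
  expect_error(evaluate_holdout(m, bad, d$y), class = "deceptrf_schema_error")
})

test_that("importance recovers an injected signal and stays flat on noise", {
  hits <- 0
  for (s in 1:10) {
    d <- withr::with_seed(200 + s, {
      y <- rep(0:1, 150)
      x <- data.frame(matrix(rnorm(300 * 10), 300, 10))
      x$X1 <- y + rnorm(300, 0, 0.5)
      list(x = x, y = y)
    })
    m <- train_classifier(d$x, d$y, num_trees = 50, seed = s)
    imp <- feature_importance(m)
    expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
    expect_true(all(diff(imp$importance) <= 0))
    if (imp$feature[1] == "X1") hits <- hits + 1
  }
  expect_gte(hits, 9)

  ratios <- vapply(1:10, function(s) {
    d <- withr::with_seed(300 + s, {
      list(x = data.frame(matrix(rnorm(300 * 10), 300, 10)),
           y = rep(0:1, 150))
    })
    m <- train_classifier(d$x, d$y, num_trees = 50, seed = s)
    imp <- feature_importance(m)
    max(imp$importance) / mean(imp$importance)
  }, numeric(1))
  expect_lt(mean(ratios), 3)
})

test_that("models serialize to text and predict identically after reload", {
  d <- sep_data(100)
  m <- train_classifier(d$x, d$y, num_trees = 20, seed = 6)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(predict(m, d$x, type = "prob"),
                   predict(m2, d$x, type = "prob"))
  expect_equal(feature_importance(m2), feature_importance(m))
})
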