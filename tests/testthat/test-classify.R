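test_that("hold-out splits partition the cohort deterministically", {
  ids <- sprintf("s%03d", 1:100)
  labels <- setNames(rep(c("A", "B"), each = 50), ids)
  spec <- classification_task("grade_binary", seed = 5L)
  sp <- split_holdout(ids, labels, spec, repeat_index = 1L)
  expect_identical(length(sp$test), 20L)
  expect_identical(length(sp$train), 80L)
  expect_identical(sort(c(sp$train, sp$test)), sort(ids))
  expect_length(intersect(sp$train, sp$test), 0L)
  sp2 <- split_holdout(ids, labels, spec, repeat_index = 1L)
  expect_identical(sp, sp2)
  sp3 <- split_holdout(ids, labels, spec, repeat_index = 2L)
  expect_false(identical(sp$test, sp3$test))
  # single class and singleton class are rejected
  expect_error(split_holdout(ids[1:10], setNames(rep("A", 10), ids[1:10]), spec),
               "2 classes")
  expect_error(split_holdout(ids[1:11],
                             setNames(c(rep("A", 10), "B"), ids[1:11]), spec),
               "single sample")
})

test_that("class balancing undersamples to the minority count", {
  ids <- sprintf("s%03d", 1:60)
  labels <- setNames(rep(c("A", "B", "C"), times = c(30, 20, 10)), ids)
  bal <- balance_classes(ids, labels, seed = 3L)
  expect_true(all(table(labels[bal]) == 10L))
  # binary 30/10 case
  bal2 <- balance_classes(ids[1:40], labels[1:40], seed = 3L)
  expect_true(all(table(labels[bal2]) == 10L))
  # already balanced: same set
  ids2 <- ids[labels %in% c("B", "C")][1:20]
  labs2 <- setNames(rep(c("B", "C"), each = 10), ids2)
  expect_setequal(balance_classes(ids2, labs2, seed = 1L), ids2)
  # deterministic under seed
  expect_identical(balance_classes(ids, labels, seed = 3L), bal)
})

test_that("confusion metrics match hand arithmetic", {
  # 2x2 confusion TP=3, FP=1, FN=1, TN=5 for the positive class
  truth <- c(rep("pos", 4), rep("neg", 6))
  pred <- c("pos", "pos", "pos", "neg", "pos", rep("neg", 5))
  m <- decoNEN:::confusion_metrics(truth, pred)
  expect_equal(m$sensitivity[["pos"]], 0.75)
  expect_equal(m$ppv[["pos"]], 0.75)
  expect_equal(m$accuracy, 0.8)
  # perfect predictions
  mp <- decoNEN:::confusion_metrics(truth, truth)
  expect_equal(mp$accuracy, 1)
  expect_equal(mp$balanced_accuracy, 1)
  expect_true(all(mp$f1 == 1))
  # all-majority predictor on an 80/20 test set
  truth2 <- c(rep("maj", 16), rep("min", 4))
  mm <- decoNEN:::confusion_metrics(truth2, rep("maj", 20))
  expect_equal(mm$accuracy, 0.8)
  expect_equal(mm$balanced_accuracy, 0.5)
})

test_that("a separable one-dimensional problem is fit perfectly", {
  x <- matrix(c(-2, -1.5, 1.2, 2), ncol = 1,
              dimnames = list(paste0("s", 1:4), "f"))
  labels <- c("A", "A", "B", "B")
  model <- train_deconvolution_classifier(x, labels,
                                          classification_task("status"))
  expect_identical(predict(model, x), labels)
})

test_that("standardization statistics come from the training data only", {
  withr::with_seed(8L, {
    x <- matrix(rnorm(40), 20, 2, dimnames = list(sprintf("s%02d", 1:20),
                                                  c("f1", "f2")))
  })
  labels <- setNames(rep(c("A", "B"), 10), rownames(x))
  train <- rownames(x)[1:16]
  test <- rownames(x)[17:20]
  x[test, ] <- 1e6  # sentinels: would wreck the scaler if leaked
  model <- train_deconvolution_classifier(x[train, ], labels[train],
                                          classification_task("status"))
  expect_equal(model$center, colMeans(x[train, ]))
  expect_equal(model$scale, apply(x[train, ], 2, sd))
})

test_that("constant and perfectly correlated features are pruned", {
  withr::with_seed(2L, {
    g1 <- rnorm(30)
    expr <- rbind(gA = g1, gB = 2 * g1 + 3, gC = rnorm(30))
  })
  colnames(expr) <- sprintf("s%02d", 1:30)
  labels <- setNames(rep(c("A", "B"), 15), colnames(expr))
  model <- train_baseline_classifier(expr, labels, classification_task("status"))
  # gA and gB are perfectly correlated: the lexicographically smaller survives
  expect_true("gA" %in% model$features)
  expect_false("gB" %in% model$features)
  expect_true("gC" %in% model$features)
  # single-gene matrix: no pruning, model fits
  m1 <- train_baseline_classifier(expr[1, , drop = FALSE], labels,
                                  classification_task("status"))
  expect_identical(m1$features, "gA")
  expect_warning(
    train_deconvolution_classifier(cbind(x = c(-1, -1, 1, 1), k = rep(2, 4)),
                                   c("A", "A", "B", "B"),
                                   classification_task("status")),
    "constant")
})

test_that("feature importance isolates the informative feature", {
  withr::with_seed(4L, {
    n <- 60
    sig <- c(rnorm(n / 2, -2), rnorm(n / 2, 2))
    x <- cbind(informative = sig, noise1 = rnorm(n), noise2 = rnorm(n))
    rownames(x) <- sprintf("s%03d", 1:n)
  })
  labels <- setNames(rep(c("A", "B"), each = 30), rownames(x))
  model <- train_deconvolution_classifier(x, labels,
                                          classification_task("status"))
  imp <- feature_importance(model)
  expect_identical(names(imp)[1], "informative")
  # identical refits give identical rankings
  model2 <- train_deconvolution_classifier(x, labels,
                                           classification_task("status"))
  expect_identical(feature_importance(model2), imp)
})

test_that("repeated hold-out evaluation aggregates across repeats", {
  withr::with_seed(6L, {
    n <- 80
    x <- cbind(f1 = c(rnorm(n / 2, -1.5), rnorm(n / 2, 1.5)), f2 = rnorm(n))
    rownames(x) <- sprintf("s%03d", 1:n)
  })
  labels <- setNames(rep(c("A", "B"), each = 40), rownames(x))
  spec <- classification_task("status", n_repeats = 5L, seed = 2L)
  rep <- run_classification(x, labels, spec)
  expect_identical(nrow(rep$per_repeat), 5L)
  expect_true(all(rep$per_repeat$accuracy >= 0 & rep$per_repeat$accuracy <= 1))
  agg_acc <- rep$aggregate$mean[rep$aggregate$metric == "accuracy"]
  expect_equal(agg_acc, mean(rep$per_repeat$accuracy))
  expect_gt(agg_acc, 0.8)  # well-separated single feature
  expect_identical(names(rep$importance)[1], "f1")
  # reruns are identical (fixed seeds throughout)
  rep2 <- run_classification(x, labels, spec)
  expect_identical(rep$per_repeat, rep2$per_repeat)
})

test_that("task labels map the cohort table correctly", {
  cohort <- data.frame(sample_id = paste0("s", 1:4),
                       grading = c("G1", "G2", "G3", NA),
                       status = c("NET", NA, "NEC", "NET"))
  expect_identical(unname(task_labels(cohort, "grade_binary")),
                   c("G1-G2", "G1-G2", "G3"))
  expect_identical(unname(task_labels(cohort, "grade_ternary")),
                   c("G1", "G2", "G3"))
  lab <- task_labels(cohort, "status")
  expect_identical(names(lab), c("s1", "s3", "s4"))
})
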