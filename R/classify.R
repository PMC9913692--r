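#' Specification of a classification task
#'
#' Three tasks are supported: `grade_binary` separates low/medium (G1, G2)
#' from high-grade (G3) tumors, `grade_ternary` assigns the exact G1/G2/G3
#' class, `status` discriminates well-differentiated tumors (NET) from
#' carcinomas (NEC). Evaluation is by repeated random hold-out: train on
#' 80% of the samples, predict the withheld 20%, without any stratification
#' by study membership; class imbalance is corrected at training time by
#' undersampling.
#'
#' @param task One of `"grade_binary"`, `"grade_ternary"`, `"status"`.
#' @param holdout_fraction Withheld fraction in (0, 1).
#' @param n_repeats Number of repeated random splits (performance is
#'   reported as mean and standard deviation across them).
#' @param balance Undersample majority classes on the training split.
#' @param seed Integer seed; split `i` is seeded by (`seed`, `i`).
#' @param decay L2 regularization strength of the softmax regression
#'   (weight decay on standardized features). The default of 1 keeps the
#'   coefficient decomposition well-determined when features are exactly
#'   collinear, as the relative proportions are (they sum to 1).
#' @return A `task_spec` list.
#' @export
classification_task <- function(task = c("grade_binary", "grade_ternary", "status"),
                                holdout_fraction = 0.2, n_repeats = 25L,
                                balance = TRUE, seed = 1L, decay = 1) {
  task <- match.arg(task)
  if (holdout_fraction <= 0 || holdout_fraction >= 1) {
    stop("holdout_fraction must be in (0, 1)")
  }
  if (n_repeats < 1L) stop("n_repeats must be >= 1")
  structure(list(task = task, holdout_fraction = holdout_fraction,
                 n_repeats = as.integer(n_repeats), balance = balance,
                 seed = as.integer(seed), decay = decay),
            class = "task_spec")
}

#' Derive task labels from a cohort table
#'
#' Samples with a missing label for the task are dropped.
#'
#' @param cohort Cohort data.frame (see [read_cohort_table()]).
#' @param task Task name as in [classification_task()].
#' @return Named character vector of labels (names = sample_id).
#' @export
task_labels <- function(cohort, task) {
  lab <- switch(task,
    grade_binary = ifelse(cohort$grading %in% c("G1", "G2"), "G1-G2",
                          ifelse(cohort$grading %in% "G3", "G3", NA)),
    grade_ternary = ifelse(cohort$grading %in% c("G1", "G2", "G3"),
                           cohort$grading, NA),
    status = ifelse(cohort$status %in% c("NET", "NEC"), cohort$status, NA),
    stop("unknown task: ", task))
  keep <- !is.na(lab)
  stats::setNames(lab[keep], cohort$sample_id[keep])
}

#' Random hold-out split
#'
#' Uniform random split seeded by (`spec$seed`, `repeat_index`); no
#' stratification. The split is redrawn (bounded retries) until every class
#' is represented in the training portion.
#'
#' @param sample_ids Sample identifiers.
#' @param labels Class labels, parallel to `sample_ids`.
#' @param spec A [classification_task()].
#' @param repeat_index Index of the repeat (>= 1).
#' @return List with `train` and `test` identifier vectors.
#' @export
split_holdout <- function(sample_ids, labels, spec, repeat_index = 1L) {
  counts <- table(labels)
  if (length(counts) < 2L) stop("need >= 2 classes, got: ", paste(names(counts), collapse = ", "))
  if (any(counts < 2L)) {
    stop("class(es) with a single sample: ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  }
  n <- length(sample_ids)
  n_test <- max(1L, round(spec$holdout_fraction * n))
  split_seed <- as.integer((spec$seed * 2654435761 + repeat_index * 40503) %% 2147483647)
  withr::with_seed(split_seed, {
    for (try in 1:100) {
      test_idx <- sample.int(n, n_test)
      train <- sample_ids[-test_idx]
      if (all(names(counts) %in% labels[-test_idx])) break
    }
  })
  if (!all(names(counts) %in% labels[match(train, sample_ids)])) {
    stop("could not draw a split with every class in training")
  }
  list(train = train, test = sample_ids[test_idx])
}

#' Undersample majority classes to the minority class size
#'
#' @param train_ids Training sample identifiers.
#' @param labels Named labels covering `train_ids`.
#' @param seed Integer seed.
#' @return Balanced subset of `train_ids`.
#' @export
balance_classes <- function(train_ids, labels, seed = 1L) {
  lab <- labels[train_ids]
  counts <- table(lab)
  if (length(counts) < 2L) stop("need >= 2 classes to balance")
  m <- min(counts)
  withr::with_seed(as.integer(seed), {
    keep <- unlist(lapply(names(counts), function(cl) {
      ids <- train_ids[lab == cl]
      if (length(ids) > m) sample(ids, m) else ids
    }), use.names = FALSE)
  })
  keep
}

# Core fitting routine shared by both classifiers: per-column z-scoring with
# training statistics (frozen for prediction), constant-column drop, optional
# greedy collinearity pruning, multinomial logistic regression with softmax
# link and L2 weight decay.
fit_softmax <- function(x, labels, decay = 1, prune_collinear = FALSE,
                        cor_threshold = 0.9) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  all_na <- apply(x, 2L, function(col) all(is.na(col)))
  if (any(all_na)) {
    warning("dropping all-NA feature(s): ",
            paste(colnames(x)[all_na], collapse = ", "))
    x <- x[, !all_na, drop = FALSE]
  }
  keep_rows <- stats::complete.cases(x)
  x <- x[keep_rows, , drop = FALSE]
  labels <- labels[keep_rows]
  kept <- colnames(x)
  if (prune_collinear && ncol(x) > 1L) {
    kept <- prune_correlated(x, threshold = cor_threshold)
    x <- x[, kept, drop = FALSE]
  }
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant feature(s): ",
            paste(colnames(x)[sds == 0], collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
    kept <- colnames(x)
  }
  if (!ncol(x)) stop("no usable features left")
  center <- colMeans(x)
  scale_ <- apply(x, 2L, stats::sd)
  xs <- scale(x, center = center, scale = scale_)
  df <- data.frame(.y = factor(labels), xs, check.names = FALSE)
  fit <- nnet::multinom(.y ~ ., data = df, decay = decay, trace = FALSE,
                        maxit = 500, MaxNWts = 1e5)
  structure(list(fit = fit, features = colnames(x), center = center,
                 scale = scale_, levels = levels(df$.y), decay = decay),
            class = "softmax_classifier")
}

# Greedy deterministic pruning: visit genes in lexicographic order, keep a
# gene unless it correlates above the threshold with an already-kept gene
# (so the lexicographically smaller member of a correlated pair survives).
prune_correlated <- function(x, threshold = 0.9) {
  ord <- order(colnames(x))
  cm <- abs(stats::cor(x))
  cm[is.na(cm)] <- 0
  kept_idx <- integer(0)
  for (j in ord) {
    if (!length(kept_idx) || all(cm[j, kept_idx] <= threshold)) {
      kept_idx <- c(kept_idx, j)
    }
  }
  colnames(x)[sort(kept_idx)]
}

#' Train the deconvolution-feature classifier
#'
#' Softmax (multinomial) logistic regression on the deconvolution feature
#' matrix (see [extract_features()]): the model-type proportions plus the
#' empirical p-value, reconstruction RMSE and correlation r. Features are
#' z-scored with training-set statistics, which are frozen inside the model
#' and reused at prediction time. Samples with missing features are dropped.
#'
#' @param features Samples x features matrix.
#' @param labels Class labels, parallel to the rows of `features`.
#' @param spec A [classification_task()].
#' @return A `softmax_classifier`.
#' @export
train_deconvolution_classifier <- function(features, labels, spec) {
  fit_softmax(features, labels, decay = spec$decay)
}

#' Train the expression baseline classifier
#'
#' The comparison model: softmax regression directly on expression values of
#' genes shared across cohorts (including the proliferation marker MKI67
#' when present). Of every gene pair with absolute Pearson correlation above
#' 0.9 on the training data one gene is dropped (the lexicographically
#' smaller identifier is kept), then the same softmax model is fitted on
#' z-scored values.
#'
#' @param expr Genes x samples expression matrix (training samples only).
#' @param labels Class labels, parallel to the columns of `expr`.
#' @param spec A [classification_task()].
#' @param cor_threshold Collinearity pruning threshold.
#' @return A `softmax_classifier`.
#' @export
train_baseline_classifier <- function(expr, labels, spec, cor_threshold = 0.9) {
  if (!nrow(expr)) stop("empty gene set for the baseline classifier")
  fit_softmax(t(expr), labels, decay = spec$decay, prune_collinear = nrow(expr) > 1L,
              cor_threshold = cor_threshold)
}

#' @export
predict.softmax_classifier <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  miss <- setdiff(object$features, colnames(newdata))
  if (length(miss)) stop("missing feature(s): ", paste(miss, collapse = ", "))
  xs <- scale(newdata[, object$features, drop = FALSE],
              center = object$center, scale = object$scale)
  as.character(stats::predict(object$fit, newdata = as.data.frame(xs)))
}

#' Confusion-matrix metrics on a hold-out set
#'
#' Sensitivity (recall) is per true class, positive predictive value
#' (precision) per predicted class; balanced accuracy and the class-averaged
#' metrics are macro means over the classes observed in the truth. A test
#' class the model never saw counts as errors (with a warning).
#'
#' @param model A `softmax_classifier`.
#' @param newdata Test samples x features (or genes x samples with
#'   `transpose = TRUE` for the baseline model).
#' @param labels True test labels.
#' @param transpose Transpose `newdata` first.
#' @return List with `accuracy`, `balanced_accuracy`, per-class
#'   `sensitivity`, `ppv`, `f1`, their macro averages and the confusion
#'   matrix.
#' @export
evaluate <- function(model, newdata, labels, transpose = FALSE) {
  if (transpose) newdata <- t(newdata)
  newdata <- as.matrix(newdata)
  used <- intersect(model$features, colnames(newdata))
  ok <- stats::complete.cases(newdata[, used, drop = FALSE])
  newdata <- newdata[ok, , drop = FALSE]
  labels <- labels[ok]
  if (!length(labels)) stop("empty test set")
  pred <- predict(model, newdata)
  unseen <- setdiff(unique(labels), model$levels)
  if (length(unseen)) {
    warning("test class(es) unseen in training counted as errors: ",
            paste(unseen, collapse = ", "))
  }
  confusion_metrics(labels, pred)
}

confusion_metrics <- function(truth, pred) {
  classes <- sort(unique(c(truth, pred)))
  truth_f <- factor(truth, levels = classes)
  pred_f <- factor(pred, levels = classes)
  cm <- table(truth = truth_f, predicted = pred_f)
  tp <- diag(cm)
  sens <- tp / rowSums(cm)
  ppv <- tp / colSums(cm)
  f1 <- 2 * sens * ppv / (sens + ppv)
  f1[is.nan(f1)] <- 0
  observed <- classes[classes %in% truth]
  list(accuracy = mean(pred == truth),
       balanced_accuracy = mean(sens[observed], na.rm = TRUE),
       sensitivity = sens, ppv = ppv, f1 = f1,
       macro_sensitivity = mean(sens[observed], na.rm = TRUE),
       macro_ppv = mean(ppv[observed], na.rm = TRUE),
       macro_f1 = mean(f1[observed], na.rm = TRUE),
       confusion = cm)
}

#' Feature importance of a softmax classifier
#'
#' Mean absolute softmax coefficient per feature across the class contrasts,
#' on the standardized feature scale, ranked descending.
#'
#' @param model A `softmax_classifier`.
#' @return Named numeric vector, most important feature first.
#' @export
feature_importance <- function(model) {
  co <- stats::coef(model$fit)
  if (is.null(dim(co))) co <- matrix(co, nrow = 1L, dimnames = list(NULL, names(co)))
  co <- co[, colnames(co) != "(Intercept)", drop = FALSE]
  imp <- colMeans(abs(co))
  names(imp) <- model$features
  sort(imp, decreasing = TRUE)
}

#' Repeated hold-out evaluation of a classifier
#'
#' Orchestrates the full protocol: for each repeat a fresh random 80/20
#' split, optional class balancing of the training portion, model fit with
#' training-only standardization (and, for the baseline, training-only
#' collinearity pruning), and evaluation on the withheld samples.
#'
#' @param x Samples x features matrix (deconvolution features, or transposed
#'   expression for the baseline).
#' @param labels Named class labels (names = rownames of `x`).
#' @param spec A [classification_task()].
#' @param prune_collinear Apply the baseline model's collinearity pruning
#'   inside each training fold.
#' @return List with `per_repeat` (data.frame of accuracy, balanced
#'   accuracy, macro sensitivity/PPV/F1 per repeat), `aggregate` (mean and
#'   sd of each), and `importance` (mean feature importance across repeats,
#'   ranked).
#' @export
run_classification <- function(x, labels, spec, prune_collinear = FALSE) {
  x <- as.matrix(x)
  ids <- rownames(x)
  stopifnot(!is.null(ids), all(ids %in% names(labels)))
  lab <- labels[ids]
  per <- vector("list", spec$n_repeats)
  imp_sum <- NULL
  for (r in seq_len(spec$n_repeats)) {
    sp <- split_holdout(ids, lab, spec, r)
    train <- sp$train
    if (spec$balance) {
      train <- balance_classes(train, lab, seed = spec$seed + r)
    }
    model <- fit_softmax(x[train, , drop = FALSE], lab[train],
                         decay = spec$decay, prune_collinear = prune_collinear)
    met <- evaluate(model, x[sp$test, , drop = FALSE], lab[sp$test])
    per[[r]] <- data.frame(repeat_index = r, accuracy = met$accuracy,
                           balanced_accuracy = met$balanced_accuracy,
                           macro_sensitivity = met$macro_sensitivity,
                           macro_ppv = met$macro_ppv, macro_f1 = met$macro_f1)
    imp <- feature_importance(model)
    if (is.null(imp_sum)) {
      imp_sum <- stats::setNames(numeric(length(imp)), names(imp))
    }
    imp_sum[names(imp)] <- imp_sum[names(imp)] + imp
  }
  per <- do.call(rbind, per)
  metric_cols <- setdiff(colnames(per), "repeat_index")
  agg <- data.frame(metric = metric_cols,
                    mean = vapply(per[metric_cols], mean, numeric(1)),
                    sd = vapply(per[metric_cols], stats::sd, numeric(1)),
                    row.names = NULL)
  list(per_repeat = per, aggregate = agg,
       importance = sort(imp_sum / spec$n_repeats, decreasing = TRUE))
}
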