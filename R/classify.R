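# Cohort splitting, linear SVM training, confusion-matrix metrics,
# cross-validation and the end-to-end leakage-guarded evaluation pipeline.
# NR (nonresponder) is the positive class throughout.

#' Stratified train/test split
#'
#' Draws `round(test_fraction * N)` test patients, deterministically under
#' `seed`. Stratified splits allocate per-class test counts by largest
#' remainder (ties toward the larger class), preserving the cohort's class
#' ratio within rounding: a 174-patient 37/137 cohort yields a 35-patient
#' test set with 7 NR and 28 RR.
#'
#' @param labels Cohort labels (factor with levels NR, RR).
#' @param test_fraction Fraction of patients held out (default 0.2), in
#'   (0, 1).
#' @param stratified Preserve class proportions (default TRUE).
#' @param seed Integer seed.
#' @return A `split_plan` with `test_ids` and `train_ids` (integer indices).
#' @export
split_cohort <- function(labels, test_fraction = 0.2, stratified = TRUE,
                         seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop_qus("test_fraction must lie in (0, 1)", "qus_validation_error")
  }
  y <- factor(labels, levels = c("NR", "RR"))
  n <- length(y)
  if (n < 4L || nlevels(droplevels(y)) < 2L) {
    stop_qus("need at least 4 patients and both classes", "qus_validation_error")
  }
  n_test <- as.integer(round_half_up(test_fraction * n))
  test_ids <- with_local_seed(seed, {
    if (stratified) {
      counts <- table(y)
      ideal <- test_fraction * as.numeric(counts)
      base <- floor(ideal)
      left <- n_test - sum(base)
      if (left > 0) {
        # largest remainder first; ties broken toward the larger class
        pref <- order(-(ideal - base), -as.numeric(counts))
        base[pref[seq_len(left)]] <- base[pref[seq_len(left)]] + 1
      }
      unlist(lapply(seq_along(counts), function(i) {
        ids <- which(y == names(counts)[i])
        if (base[i] > 0) sample(ids, base[i]) else integer()
      }), use.names = FALSE)
    } else {
      sample.int(n, n_test)
    }
  })
  test_ids <- sort(test_ids)
  structure(
    list(test_fraction = test_fraction, stratified = stratified, seed = seed,
         test_ids = test_ids, train_ids = setdiff(seq_len(n), test_ids)),
    class = "split_plan"
  )
}

#' Train a linear support vector machine
#'
#' Linear-kernel SVM (regularization constant `cost`, default 1, no feature
#' scaling); prediction is the sign of the decision function. A feature
#' matrix that is constant in every column cannot orient a boundary: the fit
#' is reported as degenerate and predicts the majority class explicitly.
#'
#' @param X Training feature matrix.
#' @param y Training labels (both classes required).
#' @param cost SVM regularization constant.
#' @return A `qus_svm` model usable with [predict()].
#' @export
train_svm <- function(X, y, cost = 1) {
  X <- as.matrix(X)
  y <- factor(y, levels = c("NR", "RR"))
  if (nlevels(droplevels(y)) < 2L) {
    stop_qus("SVM training needs both classes", "qus_validation_error")
  }
  if (!all(is.finite(X))) {
    stop_qus("SVM features must be finite", "qus_validation_error")
  }
  if (all(matrixStats_colVars(X) == 0)) {
    maj <- names(which.max(table(y)))
    return(structure(list(model = NULL, degenerate = TRUE, majority = maj),
                     class = "qus_svm"))
  }
  model <- e1071::svm(X, y, kernel = "linear", cost = cost, scale = FALSE)
  structure(list(model = model, degenerate = FALSE), class = "qus_svm")
}

# column variances without an extra dependency
matrixStats_colVars <- function(X) {
  n <- nrow(X)
  if (n < 2L) return(rep(0, ncol(X)))
  (colSums(X^2) - n * colMeans(X)^2) / (n - 1)
}

#' @export
predict.qus_svm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (object$degenerate) {
    return(factor(rep(object$majority, nrow(newdata)), levels = c("NR", "RR")))
  }
  factor(as.character(predict(object$model, newdata)), levels = c("NR", "RR"))
}

#' Confusion matrix of true versus predicted labels
#'
#' @param truth,predicted Label vectors (levels NR, RR).
#' @return A 2 x 2 integer matrix, rows = true class, columns = predicted.
#' @export
confusion_matrix <- function(truth, predicted) {
  t_ <- factor(truth, levels = c("NR", "RR"))
  p_ <- factor(predicted, levels = c("NR", "RR"))
  cm <- table(true = t_, predicted = p_)
  matrix(as.integer(cm), 2, 2, dimnames = list(true = c("NR", "RR"),
                                               predicted = c("NR", "RR")))
}

#' Per-class metrics and balanced accuracy from a confusion matrix
#'
#' For each class: precision = TP / predicted-as-class, recall = TP / actual,
#' F1 = harmonic mean. Balanced accuracy is the mean of the two recalls
#' (computed before rounding). Percentages are rounded to the nearest
#' integer (halves away from zero); zero-denominator cases are reported as
#' `NA` (undefined), never as 0.
#'
#' @param cm A 2 x 2 confusion matrix (rows true NR/RR, columns predicted).
#' @return A `metrics_report`: `per_class` data frame with integer-percent
#'   `precision`, `recall`, `f1`, the unrounded `*_raw` columns, and
#'   `balanced_accuracy` (integer percent) plus `balanced_accuracy_raw`.
#' @export
metrics_from_confusion <- function(cm) {
  cm <- matrix(as.numeric(cm), 2, 2)
  if (sum(cm) <= 0) {
    stop_qus("confusion matrix has no counts", "qus_validation_error")
  }
  classes <- c("NR", "RR")
  prec <- rec <- f1 <- numeric(2)
  for (i in 1:2) {
    tp <- cm[i, i]
    prec[i] <- if (sum(cm[, i]) > 0) tp / sum(cm[, i]) else NA_real_
    rec[i] <- if (sum(cm[i, ]) > 0) tp / sum(cm[i, ]) else NA_real_
    f1[i] <- if (is.na(prec[i]) || is.na(rec[i]) || (prec[i] + rec[i]) == 0) {
      NA_real_
    } else {
      2 * prec[i] * rec[i] / (prec[i] + rec[i])
    }
  }
  # a class absent from the test set (no actual members) contributes no
  # recall; balanced accuracy averages the recalls that exist
  ba_raw <- mean(rec, na.rm = TRUE)
  structure(
    list(per_class = data.frame(
           class = classes,
           precision = round_half_up(100 * prec),
           recall = round_half_up(100 * rec),
           f1 = round_half_up(100 * f1),
           precision_raw = prec, recall_raw = rec, f1_raw = f1),
         balanced_accuracy = round_half_up(100 * ba_raw),
         balanced_accuracy_raw = ba_raw,
         confusion = cm),
    class = "metrics_report"
  )
}

#' Five-fold cross-validation with per-fold SMOTE
#'
#' Randomly partitions the training cohort into `folds` subsets; for each
#' fold, SMOTE-balances the remaining folds, trains the linear SVM on them
#' and evaluates on the held-out fold. SMOTE never sees the held-out fold.
#'
#' @param train A [cohort_table()] with `role = "train"`.
#' @param folds Number of folds (default 5).
#' @param seed Integer seed (fold assignment and SMOTE).
#' @param k_neighbors SMOTE neighbourhood size.
#' @param cost SVM regularization constant.
#' @return A list with `fold_reports` (one `metrics_report` per fold) and
#'   `mean_balanced_accuracy` (unrounded mean over folds).
#' @export
crossvalidate <- function(train, folds = 5L, seed = 1L, k_neighbors = 5L,
                          cost = 1) {
  stopifnot(inherits(train, "cohort_table"))
  if (folds < 2L) stop_qus("folds must be >= 2", "qus_validation_error")
  n <- nrow(train$X)
  assignment <- with_local_seed(seed, {
    sample(rep_len(seq_len(folds), n))
  })
  reports <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- assignment != f
    if (nlevels(droplevels(train$y[tr])) < 2L) {
      stop_qus("a fold's training part lost one class", "qus_fold_degeneracy_error")
    }
    bal <- smote_balance(cohort_table(train$X[tr, , drop = FALSE],
                                      train$y[tr], "train"),
                         seed = derive_seed(seed, f), k_neighbors = k_neighbors)
    model <- train_svm(bal$X, bal$y, cost = cost)
    pred <- predict(model, train$X[!tr, , drop = FALSE])
    reports[[f]] <- metrics_from_confusion(
      confusion_matrix(train$y[!tr], pred))
  }
  list(fold_reports = reports,
       mean_balanced_accuracy = mean(vapply(reports, function(r)
         r$balanced_accuracy_raw, numeric(1))))
}

#' End-to-end evaluation of a feature cohort
#'
#' Splits the cohort (stratified 80/20 by default), fits the
#' nonzero-prevalence filter, the ANOVA k-best selector (k from [k_rule()] on
#' the full cohort size) and SMOTE on the training rows only, trains the
#' linear SVM and reports the test-set confusion matrix and metrics. All
#' seeds and selected indices are returned for provenance.
#'
#' @param X Patients x features matrix.
#' @param y Labels (NR/RR).
#' @param parameter Name of the QUS parameter the features came from
#'   (bookkeeping).
#' @param seed Integer seed driving the split, SMOTE and cross-validation.
#' @param test_fraction,stratified Split controls (see [split_cohort()]).
#' @param nonzero_threshold Prevalence-filter threshold.
#' @param k Number of features to select; default `k_rule(length(y))`.
#' @param k_neighbors SMOTE neighbourhood size.
#' @param cost SVM regularization constant.
#' @param run_cv Also run 5-fold cross-validation inside the training set.
#' @return A list of class `pipeline_result`: `report` (a `metrics_report`),
#'   `confusion`, `selection` (a `selection_record`), `split`, and
#'   optionally `cv`.
#' @export
evaluate_pipeline <- function(X, y, parameter = "SS", seed = 1L,
                              test_fraction = 0.2, stratified = TRUE,
                              nonzero_threshold = 0.90, k = NULL,
                              k_neighbors = 5L, cost = 1, run_cv = FALSE) {
  X <- as.matrix(X)
  y <- factor(y, levels = c("NR", "RR"))
  split <- split_cohort(y, test_fraction, stratified, seed)
  train_tab <- cohort_table(X[split$train_ids, , drop = FALSE],
                            y[split$train_ids], "train")
  kept <- nonzero_filter(train_tab, nonzero_threshold)
  if (is.null(k)) k <- k_rule(length(y))
  sel <- select_k_best(train_tab, k, candidates = kept)

  train_sel <- cohort_table(train_tab$X[, sel$kbest_indices, drop = FALSE],
                            train_tab$y, "train")
  bal <- smote_balance(train_sel, seed = derive_seed(seed, 7L),
                       k_neighbors = k_neighbors)
  model <- train_svm(bal$X, bal$y, cost = cost)
  X_test <- X[split$test_ids, sel$kbest_indices, drop = FALSE]
  pred <- predict(model, X_test)
  cm <- confusion_matrix(y[split$test_ids], pred)
  out <- list(report = metrics_from_confusion(cm), confusion = cm,
              selection = sel, split = split, parameter = parameter,
              seed = seed)
  if (run_cv) {
    out$cv <- crossvalidate(train_sel, folds = 5L,
                            seed = derive_seed(seed, 11L),
                            k_neighbors = k_neighbors, cost = cost)
  }
  structure(out, class = "pipeline_result")
}
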