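# Feature-table reduction: nonzero-prevalence filter and ANOVA F-score
# k-best selection, both fit on training rows only to prevent leakage.

#' Labeled feature table
#'
#' @param X Numeric matrix, patients x features.
#' @param y Per-patient labels, coercible to a factor with levels
#'   `c("NR", "RR")`.
#' @param role `"train"` or `"test"`.
#' @return An object of class `cohort_table`.
#' @export
cohort_table <- function(X, y, role = c("train", "test")) {
  role <- match.arg(role)
  X <- as.matrix(X)
  y <- factor(y, levels = c("NR", "RR"))
  if (nrow(X) != length(y)) {
    stop_qus("rows of X must align 1:1 with y", "qus_validation_error")
  }
  if (anyNA(y)) {
    stop_qus("labels must be NR or RR", "qus_validation_error")
  }
  structure(list(X = X, y = y, role = role), class = "cohort_table")
}

#' Nonzero-prevalence feature filter
#'
#' Keeps feature `j` when the fraction of training rows with a nonzero value
#' in column `j` is at least `threshold`. "Nonzero" means exactly `!= 0`
#' (rectified backbone activations make exact zeros common); there is no
#' epsilon tolerance.
#'
#' @param train A `cohort_table` with `role = "train"`.
#' @param threshold Minimum nonzero fraction (default 0.90).
#' @return Integer indices of the kept features.
#' @export
nonzero_filter <- function(train, threshold = 0.90) {
  stopifnot(inherits(train, "cohort_table"))
  if (train$role != "train") {
    stop_qus("prevalence filter must be fit on training rows only",
             "qus_validation_error")
  }
  if (nrow(train$X) == 0L || ncol(train$X) == 0L) {
    stop_qus("empty feature table", "qus_validation_error")
  }
  which(colMeans(train$X != 0) >= threshold)
}

#' Number of features to select from a cohort of n patients
#'
#' `k = round(sqrt(n))`, at least 1: the square-root-of-cohort-size rule
#' (174 patients gives k = 13).
#'
#' @param n_patients Total number of patients (>= 1).
#' @return Integer k.
#' @export
k_rule <- function(n_patients) {
  if (length(n_patients) != 1L || !is.finite(n_patients) || n_patients < 1) {
    stop_qus("n_patients must be a single value >= 1", "qus_validation_error")
  }
  max(1L, as.integer(round_half_up(sqrt(n_patients))))
}

# Vectorized per-feature one-way ANOVA F statistic for a two-class label.
# Constant (zero within- and between-group variance) columns score 0.
anova_f_scores <- function(X, y) {
  n <- nrow(X)
  g <- levels(y)
  n1 <- sum(y == g[1]); n2 <- sum(y == g[2])
  m1 <- colMeans(X[y == g[1], , drop = FALSE])
  m2 <- colMeans(X[y == g[2], , drop = FALSE])
  m <- colMeans(X)
  ss_between <- n1 * (m1 - m)^2 + n2 * (m2 - m)^2
  ss_total <- colSums(X^2) - n * m^2
  ss_within <- pmax(ss_total - ss_between, 0)
  f <- (ss_between / 1) / (ss_within / (n - 2))
  # perfect separators (SSW = 0, SSB > 0) stay at +Inf and rank first;
  # constant columns (SSB = 0, including 0/0) score 0
  f[is.nan(f) | ss_between == 0] <- 0
  f
}

#' ANOVA k-best feature selection
#'
#' Scores every feature with the one-way ANOVA F statistic between the NR and
#' RR training rows and keeps the k largest scores; ties are broken toward
#' the lower feature index.
#'
#' @param train A `cohort_table` with `role = "train"` and both classes
#'   present.
#' @param k Number of features to keep (see [k_rule()]).
#' @param candidates Optional feature indices to restrict scoring to (e.g.
#'   the output of [nonzero_filter()]).
#' @return A list of class `selection_record`: `kbest_indices` (in original
#'   column coordinates), `F_scores` on the candidate set, `k`, and the
#'   candidate (`nonzero_kept`) indices.
#' @export
select_k_best <- function(train, k, candidates = seq_len(ncol(train$X))) {
  stopifnot(inherits(train, "cohort_table"))
  if (train$role != "train") {
    stop_qus("feature selection must be fit on training rows only",
             "qus_validation_error")
  }
  if (nlevels(droplevels(train$y)) < 2L) {
    stop_qus("F statistic undefined with a single class", "qus_undefined_f_error")
  }
  if (k > length(candidates)) {
    stop_qus("k exceeds the number of candidate features", "qus_validation_error")
  }
  Xc <- train$X[, candidates, drop = FALSE]
  f <- anova_f_scores(Xc, train$y)
  ord <- order(-f, seq_along(f))
  keep_local <- sort(ord[seq_len(k)])
  structure(
    list(nonzero_kept = candidates,
         k = as.integer(k),
         kbest_indices = candidates[keep_local],
         F_scores = stats::setNames(f, candidates)),
    class = "selection_record"
  )
}

#' Serialize a selection record as JSON
#'
#' @param record A `selection_record`.
#' @param file Output path.
#' @param extra Named list of extra reproducibility fields (threshold, seed,
#'   ...).
#' @export
write_selection_record <- function(record, file, extra = list()) {
  payload <- c(list(nonzero_kept = record$nonzero_kept,
                    k = record$k,
                    kbest_indices = record$kbest_indices,
                    F_scores = unname(record$F_scores)),
               extra)
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
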