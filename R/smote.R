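# SMOTE: synthetic minority oversampling on the training set only.
# Synthetic rows are convex combinations x + u * (x_nn - x) with
# u ~ Uniform(0, 1) and x_nn one of the k nearest minority neighbours of x.

#' Balance training classes with SMOTE
#'
#' Generates synthetic minority rows until the class counts are equal.
#' Original training rows are preserved verbatim and come first in the
#' output; synthetic rows are appended. Deterministic under `seed`.
#' `k_neighbors` is reduced automatically to `minority_size - 1` when the
#' minority class is small; a minority class of size 1 cannot be
#' interpolated and raises an error rather than being silently duplicated.
#'
#' @param train A [cohort_table()] with `role = "train"`.
#' @param seed Integer seed.
#' @param k_neighbors Number of nearest minority neighbours to interpolate
#'   towards (default 5).
#' @return A `cohort_table` with equal class counts.
#' @export
smote_balance <- function(train, seed = 1L, k_neighbors = 5L) {
  stopifnot(inherits(train, "cohort_table"))
  if (train$role != "train") {
    stop_qus("SMOTE must only be applied to training rows", "qus_validation_error")
  }
  counts <- table(train$y)
  if (any(counts == 0L)) {
    stop_qus("both classes must be present", "qus_validation_error")
  }
  minority <- names(counts)[which.min(counts)]
  n_needed <- max(counts) - min(counts)
  if (n_needed == 0L) return(train)
  if (min(counts) < 2L) {
    stop_qus("minority class of size 1 cannot be interpolated",
             "qus_cannot_interpolate_error")
  }
  Xm <- train$X[train$y == minority, , drop = FALSE]
  n_min <- nrow(Xm)
  k_use <- min(k_neighbors, n_min - 1L)

  d2 <- as.matrix(stats::dist(Xm))^2
  diag(d2) <- Inf
  nn <- do.call(rbind, lapply(seq_len(n_min),
                              function(i) order(d2[i, ])[seq_len(k_use)]))

  synth <- with_local_seed(seed, {
    base_idx <- sample.int(n_min, n_needed, replace = TRUE)
    nn_pick <- nn[cbind(base_idx, sample.int(k_use, n_needed, replace = TRUE))]
    u <- stats::runif(n_needed)
    Xm[base_idx, , drop = FALSE] +
      u * (Xm[nn_pick, , drop = FALSE] - Xm[base_idx, , drop = FALSE])
  })
  cohort_table(rbind(train$X, synth),
               c(as.character(train$y), rep(minority, n_needed)),
               role = "train")
}
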