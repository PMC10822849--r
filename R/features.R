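# Frozen-backbone feature extraction. The backbone is injected behind a small
# interface: any function mapping a 224x224x3 array to a 7x7x2048 activation
# block qualifies. The packaged default is a frozen random-feature
# convolutional extractor: fixed-seed Gaussian projections of average-pooled
# 32x32 patches followed by a ReLU. Random frozen projections are a
# legitimate, deterministic feature family with the same output contract
# (7 x 7 x 2048, rectified) as an ImageNet-pretrained ResNet50V2 final
# convolutional stage; a pretrained network can be injected through the same
# interface when one is available.

FEATURE_GRID <- 7L
FEATURE_CHANNELS <- 2048L
FEATURE_LENGTH <- FEATURE_GRID * FEATURE_GRID * FEATURE_CHANNELS  # 100,352

#' Construct a frozen backbone feature extractor
#'
#' @param forward A function taking a 224 x 224 x 3 numeric array (values in
#'   `[-1, 1]` after canonical preprocessing) and returning a 7 x 7 x 2048
#'   activation array. Must be deterministic.
#' @param name Identifier stored with extracted features.
#' @return An object of class `qus_backbone`.
#' @export
backbone <- function(forward, name = "custom") {
  stopifnot(is.function(forward))
  structure(list(forward = forward, name = name, frozen = TRUE),
            class = "qus_backbone")
}

#' Default frozen random-projection backbone
#'
#' Splits the 224 x 224 input into the 7 x 7 lattice of 32 x 32 patches,
#' average-pools each patch (and channel) to 8 x 8, and maps the resulting
#' 192-dimensional patch descriptor through a fixed Gaussian projection
#' (weights drawn once from the given seed and then frozen) with a ReLU,
#' yielding 2048 rectified channels per lattice cell. Deterministic,
#' continuous in the input, and non-negative.
#'
#' @param seed Seed fixing the projection weights (the network's "training").
#' @return A `qus_backbone`.
#' @export
random_projection_backbone <- function(seed = 1907L) {
  d_in <- 3L * 64L  # 8x8 pooled patch x 3 channels
  wb <- with_local_seed(seed, {
    list(W = matrix(stats::rnorm(FEATURE_CHANNELS * d_in, sd = 1 / sqrt(d_in)),
                    nrow = FEATURE_CHANNELS),
         b = stats::rnorm(FEATURE_CHANNELS, sd = 0.1))
  })
  pool <- function(patch) {  # 32x32 -> 8x8 average pooling
    m <- matrix(patch, nrow = 4L)
    col_pooled <- colMeans(m)                       # length 8*32
    m2 <- matrix(col_pooled, nrow = 8L)             # 8 x 32
    t(rowsum(t(m2), rep(seq_len(8L), each = 4L)) / 4)  # 8 x 8
  }
  forward <- function(x) {
    desc <- matrix(0, nrow = d_in, ncol = FEATURE_GRID^2)
    cell <- 1L
    for (r in seq_len(FEATURE_GRID)) {
      rows <- ((r - 1L) * 32L + 1L):(r * 32L)
      for (cc in seq_len(FEATURE_GRID)) {
        cols <- ((cc - 1L) * 32L + 1L):(cc * 32L)
        desc[, cell] <- c(
          pool(x[rows, cols, 1L]), pool(x[rows, cols, 2L]), pool(x[rows, cols, 3L]))
        cell <- cell + 1L
      }
    }
    h <- pmax(wb$W %*% desc + wb$b, 0)              # 2048 x 49
    out <- array(0, dim = c(FEATURE_GRID, FEATURE_GRID, FEATURE_CHANNELS))
    cell <- 1L
    for (r in seq_len(FEATURE_GRID)) {
      for (cc in seq_len(FEATURE_GRID)) {
        out[r, cc, ] <- h[, cell]
        cell <- cell + 1L
      }
    }
    out
  }
  backbone(forward, name = sprintf("random_projection_%d", seed))
}

as_backbone_input <- function(image) {
  px <- if (inherits(image, "map_image")) image$pixels else image
  if (is.matrix(px)) {
    px <- array(rep(px, 3L), dim = c(dim(px), 3L))
  }
  if (!is.array(px) || !all(dim(px) == c(224L, 224L, 3L))) {
    stop_qus("backbone input must be 224 x 224 (x3) after replication",
             "qus_validation_error")
  }
  if (!all(is.finite(px))) {
    stop_qus("backbone input must be finite", "qus_validation_error")
  }
  px
}

#' Extract a frozen-backbone feature vector from a map image
#'
#' Replicates the single-parameter map image to 3 channels, applies the
#' canonical input scaling to `[-1, 1]`, runs the frozen backbone forward to
#' its final 7 x 7 x 2048 activation block and flattens it row-major in
#' `(row, column, channel)` order to a length-100,352 vector. Deterministic
#' for fixed backbone weights; the flattening order is fixed because
#' downstream k-best indices depend on it.
#'
#' @param image A `map_image` (or a 224 x 224 matrix / 224 x 224 x 3 array).
#' @param bb A `qus_backbone` (default [random_projection_backbone()]).
#' @return Numeric feature vector of length 100,352.
#' @export
extract_features <- function(image, bb = random_projection_backbone()) {
  px <- as_backbone_input(image)
  act <- bb$forward(px * 2 - 1)
  if (!all(dim(act) == c(FEATURE_GRID, FEATURE_GRID, FEATURE_CHANNELS))) {
    stop_qus("backbone must return a 7 x 7 x 2048 activation array",
             "qus_validation_error")
  }
  # aperm(c(3,2,1)) + as.vector enumerates channel fastest, then column, then
  # row: exactly (row, column, channel) row-major.
  as.vector(aperm(act, c(3L, 2L, 1L)))
}

#' Average per-slice feature vectors into one tumor feature vector
#'
#' @param vectors A list of 1-7 length-100,352 feature vectors from the
#'   image planes of one tumor (same patient and parameter).
#' @return The element-wise arithmetic mean, with attribute
#'   `n_slices_averaged`.
#' @export
average_tumor_features <- function(vectors) {
  if (!is.list(vectors) || length(vectors) == 0L) {
    stop_qus("need at least one feature vector", "qus_validation_error")
  }
  lens <- vapply(vectors, length, integer(1))
  if (any(lens != lens[1])) {
    stop_qus("feature vectors must share one length", "qus_validation_error")
  }
  out <- Reduce(`+`, vectors) / length(vectors)
  attr(out, "n_slices_averaged") <- length(vectors)
  out
}
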