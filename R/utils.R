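#' @keywords internal
"_PACKAGE"

# Round to nearest integer, halves away from zero (reporting convention for
# integer percentages).
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards. All stochastic package functions route their
# randomness through this so that a seed argument never clobbers the session RNG.
with_local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed; kept below 2^31 - 1.
derive_seed <- function(seed, offset) {
  (as.integer(seed) * 48271 + as.integer(offset)) %% 2147483647L
}

next_pow2 <- function(n) {
  2L^ceiling(log2(max(n, 1L)))
}

stop_qus <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "qus_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
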