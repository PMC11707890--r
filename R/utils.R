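# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a per-repetition seed from a master seed
#'
#' Experiment drivers draw all randomness from a single master seed; each
#' repetition uses `derive_seed(master, i)` so any single repetition can be
#' re-run in isolation. The derivation is `(master + 104729 * i) mod (2^31 - 1)`
#' (104729 is the 10000th prime; the modulus keeps seeds in 32-bit range).
#'
#' @param master integer master seed.
#' @param i repetition index (1-based).
#' @return An integer seed.
#' @export
derive_seed <- function(master, i) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master),
            is.numeric(i), length(i) == 1L, i >= 0)
  as.integer((as.double(master) + 104729 * as.double(i)) %% 2147483647)
}

# Run code under an explicit seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# Soft-thresholding operator used by the lasso solvers.
soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

# Consistent dimension-mismatch message.
check_length <- function(x, expected, what) {
  if (length(x) != expected) {
    stop(sprintf("%s has length %d, expected %d", what, length(x), expected),
         call. = FALSE)
  }
  invisible(x)
}

as_numeric_matrix <- function(m, what) {
  if (is.data.frame(m)) m <- as.matrix(m)
  if (!is.matrix(m) || !is.numeric(m)) {
    stop(sprintf("%s must be a numeric matrix", what), call. = FALSE)
  }
  storage.mode(m) <- "double"
  m
}
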