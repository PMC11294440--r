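#' Derive a reproducible child seed from a base seed and a label
#'
#' The pipeline uses one user-facing seed; each stage (and each restart,
#' repeat or permutation inside a stage) draws its own RNG stream from a
#' seed derived deterministically from that base seed and a short label,
#' so stages can be re-run in isolation without disturbing one another.
#'
#' @param seed integer base seed.
#' @param label character scalar naming the consumer.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "thin") != derive_seed(1, "pno")
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 31 + k) %% 1000003
  as.integer((abs(as.numeric(seed)) * 7919 + h * 2654435.0) %% 2147483646)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# numeric near-equality used for grid geometry comparisons
.near <- function(a, b, tol = 1e-9) abs(a - b) <= tol * pmax(1, abs(a), abs(b))
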