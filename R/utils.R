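# Internal helpers shared across modules.

#' Canonicalize an unordered compound pair
#'
#' Orders the two identifiers lexicographically so that every unordered pair
#' has a single canonical representation across the package.
#'
#' @param a,b character vectors of equal length.
#' @return A two-column character matrix with columns `id1`, `id2`,
#'   `id1 < id2` row-wise.
#' @keywords internal
canonical_pair <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  stopifnot(length(a) == length(b))
  swap <- a > b
  id1 <- ifelse(swap, b, a)
  id2 <- ifelse(swap, a, b)
  cbind(id1 = id1, id2 = id2)
}

#' Derive a per-stage child seed from a global seed
#'
#' Counter-based expansion: each named stage owns a fixed counter so adding a
#' new stage never perturbs the draws of earlier stages.
#'
#' @param seed integer global seed.
#' @param stage integer stage counter (>= 0).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(stage))
  as.integer((abs(seed) * 7919 + stage * 104729) %% 2147483647)
}

# stop() with a consistent error class so callers/tests can distinguish
# user-input problems from programming errors
ctg_error <- function(msg, class) {
  stop(structure(
    class = c(class, "chemtoxgraph_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
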