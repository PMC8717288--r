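# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All stochastic functions in the package route their randomness through this
# so that a recorded seed reproduces a run exactly.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Hashes `(seed, stage, unit)` to an integer below 2^31 so that each
#' stochastic stage of a pipeline run gets its own stream: adding or removing
#' one analysis unit does not shift the randomness of the others.
#'
#' @param seed master integer seed.
#' @param stage character stage label (e.g. `"pcf_envelope"`).
#' @param unit character unit label (e.g. a species code); default `""`.
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
sub_seed <- function(seed, stage, unit = "") {
  key <- paste0(stage, "\r", unit)
  h <- as.double(seed) %% 2147483647
  for (k in utf8ToInt(key)) h <- (h * 31 + k) %% 2147483647
  as.integer(h %% 2147483645 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# upper-triangle (i < j) index pairs of an n x n matrix
upper_pairs <- function(n) {
  j <- rep.int(seq_len(n), seq_len(n) - 1L)
  i <- sequence(seq_len(n) - 1L)
  cbind(i = i, j = j)
}
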