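#' Evaluate an expression under a temporary RNG state
#'
#' Runs `code` with the RNG seeded to `seed`, then restores whatever global
#' RNG state existed before the call, so package functions are deterministic
#' given their `seed` argument without clobbering the caller's stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
local_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed must be a single finite number")
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

`%||%` <- function(a, b) if (is.null(a)) b else a
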