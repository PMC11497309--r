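#' @keywords internal
"_PACKAGE"

# Seed handling -----------------------------------------------------------

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded helpers do not disturb
#' the caller's RNG state.
#'
#' @param seed integer seed, or NULL to leave the RNG state untouched.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a sub-stream seed from a master seed
#'
#' One master seed feeds every stage; each operation (a unit's spike train,
#' an electrode's noise, a replicate) draws from its own derived stream so
#' sub-components are independently reproducible. The derivation is a fixed
#' affine hash modulo 2^31 - 1 (exact in double arithmetic).
#'
#' @param seed master integer seed.
#' @param stream small non-negative integer identifying the stream.
#' @return an integer seed in [1, 2^31 - 2].
#' @export
derive_seed <- function(seed, stream = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(stream), length(stream) == 1L, stream >= 0)
  m <- 2147483647 # 2^31 - 1, prime
  s <- ((abs(as.double(seed)) %% m) * 48271 + as.double(stream) * 7919 + 1) %% m
  as.integer(s %% (m - 2) + 1)
}

# Validation helpers ------------------------------------------------------

#' @keywords internal
stop_param <- function(key, msg) {
  stop(sprintf("invalid parameter '%s': %s", key, msg), call. = FALSE)
}

#' @keywords internal
check_positive <- function(x, key) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_param(key, "must be a single finite value > 0")
  invisible(x)
}

#' @keywords internal
check_nonneg <- function(x, key) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    stop_param(key, "must be a single finite value >= 0")
  invisible(x)
}
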