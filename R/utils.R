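# Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed, restoring RNG state afterwards
#'
#' All user-facing stochastic operations route their randomness through this
#' helper so that a given seed yields byte-identical results regardless of the
#' caller's RNG state.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
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

# Derive a reproducible child seed from a parent seed and a stream index,
# staying below .Machine$integer.max.
child_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 1103L + as.double(stream) * 7919L) %% 2147483629)
}

# Polynomial rolling hash (mod 2^31 - 1) of a character scalar; used to stamp
# provenance records so reruns under the same config are recognisable.
config_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- as.integer(charToRaw(x))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(sprintf(...), call. = FALSE)
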