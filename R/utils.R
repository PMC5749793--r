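`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Expands one master seed into per-subject / per-stage substreams via a
#' counter, keeping the result a valid 32-bit integer seed.
#'
#' @param master integer master seed.
#' @param counter non-negative integer stream index.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, counter = 0L) {
  m <- abs(as.numeric(master)) %% 2147483647
  s <- (m * 48271 + as.numeric(counter) * 16807 + 1) %% 2147483647
  as.integer(s + (s == 0))
}

stop_docsleep <- function(...) stop(..., call. = FALSE)

assert_that <- function(ok, ...) if (!isTRUE(ok)) stop_docsleep(...)
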