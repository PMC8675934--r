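`%||%` <- function(x, y) if (is.null(x)) y else x

#' @keywords internal
stop_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("commstack_validation_error", "error")))
}

#' Derive a reproducible sub-seed
#'
#' Deterministically maps a base seed and an offset to a new seed, kept
#' within the 32-bit integer range so it can be passed to [set.seed()].
#'
#' @param seed integer base seed.
#' @param offset integer offset distinguishing the consumer.
#' @return an integer seed.
#' @keywords internal
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483587L + 1L)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Wrap a pipeline stage so failures carry the stage name.
with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(errorCondition(sprintf("[stage: %s] %s", stage, conditionMessage(e)),
                        class = c(class(e)[1], "commstack_stage_error", "error")))
  })
}

# Polynomial rolling hash of a character vector, for provenance stamping.
content_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
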