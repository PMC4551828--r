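# Internal helpers shared across modules.

#' Evaluate an expression with a temporarily fixed RNG state
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded package functions do not disturb the session RNG.
#'
#' @param seed Integer seed (must stay below 2^31).
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-participant sub-seed fan-out: a fixed stride keeps seeds
# for existing participants stable when more participants are added.
participant_seed <- function(master_seed, participant, stream = 0L) {
  (as.integer(master_seed) + 100003L * as.integer(participant) +
     7919L * as.integer(stream)) %% .Machine$integer.max
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(sprintf(...), call. = FALSE)
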