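# Classed condition helpers: every user-facing failure carries a class so
# callers (and tests) can distinguish contract violations from bad files etc.

abort <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "hsib_error", "error", "condition")))
}
abort_contract     <- function(msg) abort(msg, "hsib_contract_error")
abort_parameter    <- function(msg) abort(msg, "hsib_parameter_error")
abort_format       <- function(msg) abort(msg, "hsib_format_error")
abort_corrupt      <- function(msg) abort(msg, "hsib_corrupt_error")
abort_degenerate   <- function(msg) abort(msg, "hsib_degenerate_error")
abort_insufficient <- function(msg) abort(msg, "hsib_insufficient_error")

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded helpers never perturb the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
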