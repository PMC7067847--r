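# Internal helpers: typed conditions, seeded evaluation, light logging.

lx_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "lexicross_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

lx_assert <- function(cond, class, msg) {
  if (!isTRUE(cond)) lx_error(class, msg)
  invisible(TRUE)
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` after `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded package internals never disturb user-level
#' random-number streams.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Stage seeds are derived from one user seed with fixed offsets so that
# resampling one stage (e.g. the null events) cannot shift any other stream.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset) * 10007L) %% .Machine$integer.max
}

lx_log <- function(..., verbose = getOption("lexicross.verbose", TRUE)) {
  if (isTRUE(verbose)) message("[lexicross] ", ...)
  invisible(NULL)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == as.integer(x) && x > 0
}

`%||%` <- function(a, b) if (is.null(a)) b else a
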