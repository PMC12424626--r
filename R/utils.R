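#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded at `seed`, then restores the
#' prior RNG state so package functions never clobber a user's random
#' stream. All exported functions that take a `seed` argument route
#' their randomness through this helper.
#'
#' @param seed single integer seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)

check_columns <- function(df, cols, context = "input table") {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop_input(sprintf("%s is missing required column(s): %s",
                       context, paste(missing, collapse = ", ")))
  invisible(df)
}
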