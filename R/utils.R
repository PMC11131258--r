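# Shared helpers: condition classes, seeded evaluation, small utilities.

ff_error <- function(class, message, call. = FALSE, ...) {
  stop(structure(class = c(class, "ff_error", "error", "condition"),
                 list(message = message, call = NULL, ...)))
}

usage_error <- function(message) ff_error("ff_usage_error", message)
input_error <- function(message) ff_error("ff_input_error", message)
format_error <- function(message) ff_error("ff_format_error", message)
processing_error <- function(message) ff_error("ff_processing_error", message)

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` with the random number generator seeded to `seed`, restoring
#' the caller's RNG state afterwards so generators are pure functions of
#' their arguments.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    usage_error("seed must be a single integer")
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

# Reverse each string in a character vector.
str_rev <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)
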