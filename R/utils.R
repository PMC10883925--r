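# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded package internals never
#' perturb the caller's RNG stream.
#'
#' @param seed integer seed, or `NULL` to leave the RNG stream alone.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# C-locale (byte-order) sort: deterministic regardless of the session locale.
sort_c <- function(x) sort(x, method = "radix")

order_c <- function(...) order(..., method = "radix")

# stderr logging, silenced via options(nadescreen.verbose = FALSE)
log_msg <- function(...) {
  if (isTRUE(getOption("nadescreen.verbose", TRUE)))
    message(sprintf(...))
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample from a value set; immune to base sample()'s scalar expansion
sample_vec <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

stop_ns <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_flag01 <- function(x, what = "label") {
  if (!all(x %in% c(0L, 1L)))
    stop_ns("%s values must be 0 or 1 (got: %s)", what,
            paste(utils::head(unique(x[!x %in% c(0L, 1L)]), 3L), collapse = ", "))
  invisible(as.integer(x))
}
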