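#' Run an expression with a temporary RNG state
#'
#' Seeds the generator, evaluates `expr`, and restores whatever RNG state
#' the caller had, so generators are pure functions of (spec, seed) without
#' clobbering the session RNG.
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
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# round-half-up to integer; base round() is round-half-even
round_half_up <- function(x) floor(x + 0.5)

stop_input <- function(...) stop(..., call. = FALSE)
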