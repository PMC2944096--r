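#' Round half away from zero
#'
#' Commercial ("round half up") rounding used for all integer MOS arithmetic:
#' 4.5 rounds to 5, unlike base R's banker's rounding. Negative inputs round
#' half away from zero.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @examples
#' round_half_up(c(1.5, 2.5, 4.91))
#' @export
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# stop() without the call, with sprintf formatting
abort <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort("'%s' must be a single number", name)
  }
  if (x < lower || x > upper) {
    abort("'%s' must be in [%s, %s], got %s", name, lower, upper, x)
  }
  invisible(x)
}

# deterministic RNG scope: run expr under set.seed(seed), restore global state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
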