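#' @import data.table
#' @importFrom stats rpois runif rnorm dnorm sd median quantile fft optim
#'   ppois qpois spline rbinom binom.test approx uniroot aggregate
#'   setNames qnorm
#' @importFrom utils write.csv read.csv head tail
NULL

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Wrap angles into a half-open interval
#'
#' @param x angles in degrees.
#' @param lower lower bound of the target interval; the interval is
#'   `[lower, lower + 360)`.
#' @return wrapped angles in degrees.
#' @export
wrap_deg <- function(x, lower = 0) {
  ((x - lower) %% 360) + lower
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
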