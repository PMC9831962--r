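#' @importFrom rlang abort %||%
#' @importFrom stats rnorm runif qnorm pnorm pf qf pbeta qbeta cor sd var
#'   quantile integrate pt cor.test lm coef setNames complete.cases
#' @importFrom utils head tail
NULL

# Run `expr` under a local RNG state seeded with `seed`, restoring the caller's
# RNG afterwards. All stochastic operations in the package funnel through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv())) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

stopf <- function(fmt, ...) abort(sprintf(fmt, ...))

check_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stopf("`%s` must be a finite scalar in [%s, %s]", name,
          format(lower), format(upper))
  }
  invisible(x)
}

check_points <- function(x, name = "points") {
  if (!is.matrix(x) || ncol(x) != 3L || !is.numeric(x)) {
    stopf("`%s` must be a numeric n x 3 matrix", name)
  }
  if (!all(is.finite(x))) stopf("`%s` contains non-finite coordinates", name)
  invisible(x)
}

# Flatten a p x 3 point matrix into the (x1..xp, y1..yp, z1..zp) shape vector.
flatten_shape <- function(points) as.numeric(points)

unflatten_shape <- function(v, p = length(v) / 3L) {
  matrix(v, nrow = p, ncol = 3L, dimnames = list(NULL, c("x", "y", "z")))
}
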