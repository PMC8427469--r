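#' @importFrom stats rnorm runif rbinom qnorm pnorm dnorm var sd cor
#'   quantile optim nlminb p.adjust pchisq qchisq complete.cases
#'   qnbinom pnbinom plogis qlogis cov rt setNames
#' @importFrom methods new validObject is slot show
#' @importFrom utils head modifyList
#' @importFrom graphics abline
NULL

## Run an expression under a temporary RNG seed, restoring the caller's
## RNG state afterwards. All stochastic entry points funnel through this
## so that a user-level seed fully determines every output.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

## Deterministically derive a per-stage seed from a global seed, keeping
## the result in the 32-bit integer range R requires.
derive_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 2654435.0 + h * 97.0) %% 2147483647)
}

## Sample standard deviation scaling (n - 1 denominator), erroring on
## degenerate input rather than returning NaN.
standardise_vector <- function(x, what = "vector") {
  if (length(x) < 2L)
    stop(what, ": need at least 2 values to standardise", call. = FALSE)
  s <- stats::sd(x)
  if (!is.finite(s) || s <= 0)
    stop(what, ": zero variance, cannot standardise", call. = FALSE)
  (x - mean(x)) / s
}

## Central-difference Jacobian of a vector-valued function; step scaled
## per coordinate. Used for delta-method standard errors.
num_jacobian <- function(fn, x, eps = 1e-6) {
  f0 <- fn(x)
  J <- matrix(0, length(f0), length(x))
  for (k in seq_along(x)) {
    h <- eps * max(1, abs(x[k]))
    xp <- x; xp[k] <- xp[k] + h
    xm <- x; xm[k] <- xm[k] - h
    J[, k] <- (fn(xp) - fn(xm)) / (2 * h)
  }
  J
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x == round(x) && x > 0
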