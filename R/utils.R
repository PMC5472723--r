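## Small internal helpers shared across the package.

#' Logistic function
#'
#' Numerically stable evaluation of the logistic sigmoid
#' \eqn{\sigma(x) = 1/(1+e^{-x})}, the subunit output nonlinearity.
#'
#' @param x numeric vector.
#' @return values in (0, 1).
#' @examples
#' logistic(0)    # 0.5
#' logistic(2)    # ~0.8808
#' @export
logistic <- function(x) {
  out <- numeric(length(x))
  pos <- !is.na(x) & x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out[is.na(x)] <- NA_real_
  dim(out) <- dim(x)
  out
}

#' Soft-plus rectifier
#'
#' Numerically stable \eqn{R_+(x) = \log(1+e^x)}: approaches \eqn{x} for
#' large \eqn{x} and \eqn{e^x} for very negative \eqn{x}.  This is the output
#' rectifier that converts the pooled subunit drive into a firing rate.
#'
#' @param x numeric vector.
#' @return nonnegative values.
#' @examples
#' softplus(0)   # log(2)
#' softplus(50)  # ~50
#' @export
softplus <- function(x) {
  out <- numeric(length(x))
  hi <- !is.na(x) & x > 30
  out[hi] <- x[hi]
  out[!hi] <- log1p(exp(x[!hi]))
  out[is.na(x)] <- NA_real_
  dim(out) <- dim(x)
  out
}

## log(softplus(x)) without underflow: for x << 0, softplus(x) ~ e^x.
log_softplus <- function(x) {
  out <- numeric(length(x))
  lo <- !is.na(x) & x < -30
  out[lo] <- x[lo]
  out[!lo] <- log(softplus(x[!lo]))
  out
}

## Evaluate expr with a temporary RNG state seeded by `seed`; the caller's
## RNG stream is untouched.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## axial (orientation) difference in degrees, result in [0, 90]
axial_diff_deg <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

## wrap angle in degrees to (-180, 180]
wrap_deg <- function(a) {
  a <- a %% 360
  a[a > 180] <- a[a > 180] - 360
  a
}
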