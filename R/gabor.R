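## Gabor wavelets on the patch pixel grid, and kernel synthesis from
## weighted Gabor outer products.
##
## A Gabor is an oriented Gaussian-windowed sinusoid
##   g(x, y) = A exp(-(x'^2 + gamma^2 y'^2) / (2 sigma^2)) cos(2 pi x'/lambda + phi)
## with rotated coordinates
##   x' = (x - x0) cos(theta) + (y - y0) sin(theta)
##   y' = -(x - x0) sin(theta) + (y - y0) cos(theta).
## theta is the carrier direction (orientation is axial, mod 180 degrees),
## gamma the aspect ratio, sigma the envelope size (px), lambda the spatial
## wavelength (px), phi the spatial phase.  A is fixed by unit norm.
## Pixel coordinates are 0-based: x = column, y = row.

#' Gabor parameter table
#'
#' Builds/validates a data.frame of Gabor parameters, one row per Gabor,
#' with columns \code{x0, y0, theta, gamma, sigma, lam, phi, w} (signed
#' weight).  \code{theta} and \code{phi} are reduced to (-pi, pi].
#'
#' @param x0,y0 center position in pixels (0-based).
#' @param theta orientation in radians.
#' @param gamma aspect ratio (> 0).
#' @param sigma envelope size in pixels (> 0).
#' @param lam spatial wavelength in pixels (> 0).
#' @param phi spatial phase in radians.
#' @param w signed weight (positive excitatory, negative suppressive).
#' @return data.frame of class \code{c("gabor_set", "data.frame")}.
#' @export
gabor_set <- function(x0, y0, theta, gamma, sigma, lam, phi, w = 1) {
  df <- data.frame(x0 = x0, y0 = y0, theta = wrap_rad(theta),
                   gamma = gamma, sigma = sigma, lam = lam,
                   phi = wrap_rad(phi), w = w)
  if (any(df$gamma <= 0) || any(df$sigma <= 0) || any(df$lam <= 0))
    stop("gamma, sigma and lam must be strictly positive")
  class(df) <- c("gabor_set", "data.frame")
  df
}

## wrap radians to (-pi, pi]
wrap_rad <- function(a) {
  a <- a %% (2 * pi)
  a[a > pi] <- a[a > pi] - 2 * pi
  a
}

#' Render a Gabor as a unit-norm patch vector
#'
#' @param g one-row Gabor parameter set (or a list with the same fields).
#' @param dims patch dimensions c(height, width) in pixels.
#' @param flatten return the row-major patch vector (default) or the
#'   height x width image matrix.
#' @return unit-norm numeric vector of length prod(dims) (or matrix).
#' @export
gabor_image <- function(g, dims, flatten = TRUE) {
  h <- dims[1]; w <- dims[2]
  y <- matrix(0:(h - 1), h, w)           # row index
  x <- matrix(0:(w - 1), h, w, byrow = TRUE)  # column index
  xr <- (x - g$x0) * cos(g$theta) + (y - g$y0) * sin(g$theta)
  yr <- -(x - g$x0) * sin(g$theta) + (y - g$y0) * cos(g$theta)
  img <- exp(-(xr^2 + g$gamma^2 * yr^2) / (2 * g$sigma^2)) *
    cos(2 * pi * xr / g$lam + g$phi)
  nrm <- sqrt(sum(img^2))
  if (nrm > 0) img <- img / nrm
  if (flatten) flatten_rowmajor(img) else img
}

#' Kernel synthesized from weighted Gabor outer products
#'
#' \eqn{J = \sum_i w_i g_i g_i'} with each \eqn{g_i} a unit-norm Gabor
#' patch vector; symmetric by construction.
#'
#' @param gabors a \code{\link{gabor_set}} (weights in column \code{w}).
#' @param dims patch dimensions c(height, width).
#' @return P x P symmetric matrix.
#' @export
gabor_sum_J <- function(gabors, dims) {
  if (nrow(gabors) < 1) stop("need at least one Gabor")
  P <- prod(dims)
  J <- matrix(0, P, P)
  for (i in seq_len(nrow(gabors))) {
    gi <- gabor_image(gabors[i, ], dims)
    J <- J + gabors$w[i] * tcrossprod(gi)
  }
  J
}
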