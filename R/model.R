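## The quadratic convolutional (QC) model and its reduced variants.
##
## One quadratic logistic subunit (QLS) maps a patch x to
##     y = logistic(a1 + v1.x + x' J x),
## the identical subunit is applied at every grid position and lag, the
## outputs are pooled with weights v2 and rectified:
##     rate_t = softplus(d * sum_k v2_k y_{k,t} + a2)
## (or rate_t = d * logistic(sum_k v2_k y_{k,t} + a2) for the saturating
## output variant).

#' QC model parameters
#'
#' Full parameter set of one quadratic convolutional model: subunit bias
#' \code{a1}, linear filter \code{v1} (length P = patch pixels), symmetric
#' quadratic kernel \code{J} (P x P), pooling weights \code{v2} (length
#' Gy*Gx*n_lags in canonical lag-major order), output bias \code{a2} and
#' output scale \code{d}.  \code{J} is symmetrized on construction: the
#' quadratic form only sees the symmetric part, and a symmetric J keeps the
#' eigen-analysis of its features valid.
#'
#' @param a1,a2 scalar biases.
#' @param v1 numeric vector, length P.
#' @param J P x P matrix (symmetrized as (J + t(J))/2).
#' @param v2 numeric pooling weight vector.
#' @param d positive output scaling factor.
#' @return an object of class \code{"qc_params"}.
#' @export
qc_params <- function(a1, v1, J, v2, a2, d = 1) {
  v1 <- as.numeric(v1); v2 <- as.numeric(v2)
  P <- length(v1)
  if (!is.matrix(J) || nrow(J) != P || ncol(J) != P)
    stop(sprintf("J must be %d x %d to match v1", P, P))
  vals <- c(a1, v1, J, v2, a2, d)
  if (!all(is.finite(vals))) stop("non-finite value in QC parameters")
  if (d <= 0) stop("scaling factor d must be positive")
  structure(list(a1 = as.numeric(a1), v1 = v1, J = (J + t(J)) / 2,
                 v2 = v2, a2 = as.numeric(a2), d = as.numeric(d)),
            class = "qc_params")
}

#' @export
print.qc_params <- function(x, ...) {
  cat(sprintf("<qc_params> P = %d, pooling length = %d, d = %.3g\n",
              length(x$v1), length(x$v2), x$d))
  invisible(x)
}

#' Model structure flags
#'
#' Selects the full QC model or one of its reduced variants: with
#' \code{quadratic = FALSE} the kernel J is fixed at zero (linear models);
#' with \code{convolutional = FALSE} the grid collapses to a single centered
#' patch position per lag.  \code{final_nonlinearity} chooses the soft-plus
#' rectifier (default) or the saturating logistic output
#' \code{d * logistic(pooled + a2)}.
#'
#' @param quadratic logical.
#' @param convolutional logical.
#' @param final_nonlinearity \code{"softplus"} or \code{"logistic"}.
#' @return an object of class \code{"model_spec"}.
#' @export
model_spec <- function(quadratic = TRUE, convolutional = TRUE,
                       final_nonlinearity = c("softplus", "logistic")) {
  structure(list(quadratic = isTRUE(quadratic),
                 convolutional = isTRUE(convolutional),
                 final_nonlinearity = match.arg(final_nonlinearity)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s%s, %s output\n",
              if (x$quadratic) "quadratic" else "linear",
              if (x$convolutional) " convolutional" else " non-convolutional",
              x$final_nonlinearity))
  invisible(x)
}

## short codes used by the CLI: qc, qnc, lc, lnc
model_spec_from_code <- function(code) {
  switch(code,
         qc  = model_spec(TRUE, TRUE),
         qnc = model_spec(TRUE, FALSE),
         lc  = model_spec(FALSE, TRUE),
         lnc = model_spec(FALSE, FALSE),
         stop("unknown model code: ", code, " (expected qc|qnc|lc|lnc)"))
}

#' Quadratic logistic subunit response
#'
#' Response of one subunit to one patch:
#' \code{logistic(a1 + v1.x + x' J x)}.  The same parameters are used for
#' every patch position and lag ("identical subunits").
#'
#' @param patch numeric patch vector of length P.
#' @param params a \code{\link{qc_params}}.
#' @return scalar in (0, 1).
#' @export
qls_response <- function(patch, params) {
  stopifnot(inherits(params, "qc_params"))
  P <- length(params$v1)
  if (length(patch) != P)
    stop(sprintf("patch length %d does not match filter length %d",
                 length(patch), P))
  logistic(params$a1 + sum(params$v1 * patch) +
             drop(crossprod(patch, params$J %*% patch)))
}

## Forward pass on a precomputed design.  idx subsets rows (frames).
## Returns what the gradient needs: subunit outputs Y (N x K), pooled drive,
## z (pre-output), and rate.
qc_forward <- function(design, params, spec, idx = NULL) {
  K <- design$K
  if (length(params$v2) != K)
    stop(sprintf("v2 has length %d but geometry gives pooling length %d",
                 length(params$v2), K))
  n <- if (is.null(idx)) design$N else length(idx)
  Y <- matrix(0, n, K)
  for (k in seq_len(K)) {
    Xk <- if (is.null(idx)) design$X[[k]] else design$X[[k]][idx, , drop = FALSE]
    s <- params$a1 + drop(Xk %*% params$v1)
    if (spec$quadratic) s <- s + rowSums((Xk %*% params$J) * Xk)
    Y[, k] <- logistic(s)
  }
  pooled <- drop(Y %*% params$v2)
  if (spec$final_nonlinearity == "softplus") {
    z <- params$d * pooled + params$a2
    rate <- softplus(z)
    lograte <- log_softplus(z)
  } else {
    z <- pooled + params$a2
    sz <- logistic(z)
    rate <- params$d * sz
    lograte <- log(params$d) + ifelse(z > -30, log(sz), z)
  }
  list(Y = Y, pooled = pooled, z = z, rate = rate, lograte = lograte)
}

#' Predicted firing rate of a QC model
#'
#' Evaluates the model on every frame with a full lag history; the first
#' \code{n_lags - 1} frames are dropped, so the output has length
#' \code{T - (n_lags - 1)} and element i is the rate at stimulus frame
#' \code{i + n_lags - 1} (spikes/bin).
#'
#' @param movie a \code{\link{stimulus_movie}}.
#' @param params a \code{\link{qc_params}}.
#' @param cfg a \code{\link{patch_config}}.
#' @param spec a \code{\link{model_spec}}.
#' @return numeric vector of nonnegative rates.
#' @export
predict_rate <- function(movie, params, cfg, spec = model_spec()) {
  stopifnot(inherits(movie, "stimulus_movie"), inherits(params, "qc_params"),
            inherits(cfg, "patch_config"), inherits(spec, "model_spec"))
  design <- model_design(movie, cfg, spec)
  qc_forward(design, params, spec)$rate
}

## design honouring the convolutional flag
model_design <- function(movie, cfg, spec) {
  pos <- if (spec$convolutional) NULL else center_position(dim(movie)[2:3], cfg)
  patch_design(movie, cfg, positions = pos)
}

## number of pooling weights implied by geometry + spec
model_pool_length <- function(frame_dims, cfg, spec) {
  if (spec$convolutional) pooling_vector_length(frame_dims, cfg) else cfg$n_lags
}
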