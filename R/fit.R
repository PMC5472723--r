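## Poisson maximum-likelihood fitting of the QC model.
##
## Plain minibatch SGD (optional momentum) on the mean-per-frame Poisson
## negative log-likelihood; four contiguous temporal folds, each serving once
## as the early-stopping validation set; the four fold models are averaged
## element-wise.

#' Fit configuration
#'
#' @param learning_rate SGD step size on the mean-per-frame NLL.
#' @param batch_size frames per gradient step.
#' @param max_epochs maximum passes over the training fold.
#' @param patience epochs of non-improving validation NLL before stopping.
#' @param momentum classical momentum coefficient (0 = plain SGD).
#' @param init_sd standard deviation of the small Gaussian initialization of
#'   v1, J and v2.
#' @param seed integer seed; the whole fit is reproducible given the seed.
#' @param n_folds number of cross-validation folds; the fitting protocol is
#'   four contiguous temporal fourths and \code{n_folds} is fixed at 4.
#' @return an object of class \code{"fit_config"}.
#' @export
fit_config <- function(learning_rate = 0.02, batch_size = 500L,
                       max_epochs = 50L, patience = 3L, momentum = 0.9,
                       init_sd = 1e-3, seed = 1L, n_folds = 4L) {
  if (n_folds != 4L) stop("the fitting protocol uses n_folds = 4")
  if (patience < 1L) stop("patience must be >= 1")
  if (learning_rate <= 0 || batch_size < 1L || max_epochs < 1L)
    stop("invalid fit configuration")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 momentum = momentum, init_sd = init_sd,
                 seed = as.integer(seed), n_folds = 4L),
            class = "fit_config")
}

#' Poisson negative log-likelihood
#'
#' \eqn{\sum_t (r_t - c_t \log r_t)}, dropping the count-factorial constant.
#'
#' @param rates predicted rates, strictly positive wherever the count is
#'   nonzero.
#' @param counts observed nonnegative integer spike counts.
#' @param mean_per_frame divide by the number of frames (default FALSE).
#' @return scalar NLL.
#' @examples
#' poisson_nll(1, 0)        # 1
#' poisson_nll(c(2, 2), c(2, 2))  # 2*(2 - 2*log(2))
#' @export
poisson_nll <- function(rates, counts, mean_per_frame = FALSE) {
  if (length(rates) != length(counts))
    stop("rates and counts must have equal length")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (any(rates < 0)) stop("rates must be nonnegative")
  if (any(rates == 0 & counts > 0))
    stop("zero rate with nonzero count: likelihood undefined")
  ll <- rates - ifelse(counts > 0, counts * log(rates), 0)
  if (mean_per_frame) mean(ll) else sum(ll)
}

## mean-per-frame NLL from a forward pass (stable log-rate)
nll_from_forward <- function(fwd, counts) {
  mean(fwd$rate - counts * fwd$lograte)
}

## ---- gradient ------------------------------------------------------------

## Analytic gradient of the mean-per-frame Poisson NLL on a precomputed
## design, restricted to rows idx.  Returns a list with the same fields as
## qc_params (gradients; J symmetric).
qc_gradient_core <- function(design, params, spec, counts, idx = NULL) {
  fwd <- qc_forward(design, params, spec, idx)
  cts <- if (is.null(idx)) counts else counts[idx]
  n <- length(fwd$rate)
  u <- 1 - cts / fwd$rate                      # dNLL/drate per frame
  if (spec$final_nonlinearity == "softplus") {
    dz <- u * logistic(fwd$z)                  # drate/dz = logistic(z)
    g_a2 <- sum(dz)
    g_d <- sum(dz * fwd$pooled)
    dpool <- params$d * dz
  } else {
    sz <- fwd$rate / params$d
    g_d <- sum(u * sz)
    dz <- u * params$d * sz * (1 - sz)
    g_a2 <- sum(dz)
    dpool <- dz
  }
  g_v2 <- drop(crossprod(fwd$Y, dpool))
  ## subunit drive gradient: ds = dpool v2_k * y (1-y)
  dS <- (dpool %*% t(params$v2)) * fwd$Y * (1 - fwd$Y)   # n x K
  g_a1 <- sum(dS)
  P <- design$P
  g_v1 <- numeric(P)
  g_J <- matrix(0, P, P)
  for (k in seq_len(design$K)) {
    Xk <- if (is.null(idx)) design$X[[k]] else design$X[[k]][idx, , drop = FALSE]
    g_v1 <- g_v1 + drop(crossprod(Xk, dS[, k]))
    if (spec$quadratic) g_J <- g_J + crossprod(Xk, dS[, k] * Xk)
  }
  if (spec$quadratic) g_J <- (g_J + t(g_J)) / 2
  g <- list(a1 = g_a1 / n, v1 = g_v1 / n, J = g_J / n,
            v2 = g_v2 / n, a2 = g_a2 / n, d = g_d / n)
  bad <- names(g)[!vapply(g, function(x) all(is.finite(x)), logical(1))]
  if (length(bad))
    stop("non-finite gradient in parameter block(s): ",
         paste(bad, collapse = ", "))
  g
}

#' Analytic NLL gradient
#'
#' Gradient of the mean-per-frame Poisson negative log-likelihood with
#' respect to all QC parameters (a1, v1, J, v2, a2, d), by the chain rule
#' through the subunit, pooling and output nonlinearities.
#'
#' @param params a \code{\link{qc_params}}.
#' @param spec a \code{\link{model_spec}}.
#' @param movie a \code{\link{stimulus_movie}}.
#' @param counts spike counts aligned to frames (length T).
#' @param batch optional indices into the usable frames (those with full lag
#'   history); default all.
#' @param cfg a \code{\link{patch_config}}.
#' @return a list with fields a1, v1, J, v2, a2, d holding the gradient.
#' @export
nll_gradient <- function(params, spec, movie, counts, cfg, batch = NULL) {
  design <- model_design(movie, cfg, spec)
  cts <- usable_counts(counts, design)
  if (!is.null(batch) && length(batch) == 0) stop("empty batch")
  qc_gradient_core(design, params, spec, cts, idx = batch)
}

usable_counts <- function(counts, design) {
  Tall <- design$N + design$t_first - 1L
  if (length(counts) == design$N) return(counts)
  if (length(counts) != Tall)
    stop(sprintf("counts length %d does not match %d frames", length(counts), Tall))
  counts[design$t_first:Tall]
}

## ---- parameter (un)flattening (used by tests and finite differences) -----

#' @export
as.vector.qc_params <- function(x, mode = "any") {
  c(x$a1, x$v1, as.vector(x$J), x$v2, x$a2, x$d)
}

param_from_vector <- function(v, P, K) {
  i <- 1
  a1 <- v[i]; i <- i + 1
  v1 <- v[i:(i + P - 1)]; i <- i + P
  J <- matrix(v[i:(i + P * P - 1)], P, P); i <- i + P * P
  v2 <- v[i:(i + K - 1)]; i <- i + K
  a2 <- v[i]; d <- v[i + 1]
  qc_params(a1, v1, J, v2, a2, d)
}

## ---- fitting -------------------------------------------------------------

init_params <- function(P, K, mean_count, spec, init_sd) {
  ## near-linear start: subunits near 0.5, output bias set so that the
  ## initial rate matches the mean spike count
  a2 <- if (spec$final_nonlinearity == "softplus") {
    if (mean_count > 30) mean_count else log(expm1(max(mean_count, 1e-3)))
  } else 0
  d <- if (spec$final_nonlinearity == "softplus") 1 else max(2 * mean_count, 0.1)
  qc_params(a1 = 0,
            v1 = rnorm(P, sd = init_sd),
            J = if (spec$quadratic) {
              m <- matrix(rnorm(P * P, sd = init_sd), P, P); (m + t(m)) / 2
            } else matrix(0, P, P),
            v2 = rnorm(K, sd = init_sd),
            a2 = a2, d = d)
}

sgd_step <- function(params, grad, vel, lr, momentum, quadratic) {
  for (f in c("a1", "v1", "J", "v2", "a2", "d")) {
    if (f == "J" && !quadratic) next
    vel[[f]] <- momentum * vel[[f]] - lr * grad[[f]]
    params[[f]] <- params[[f]] + vel[[f]]
  }
  if (params$d <= 0) params$d <- 1e-6   # keep the output scale positive
  list(params = params, vel = vel)
}

fit_one_fold <- function(design, counts, spec, fitcfg, idx_train, idx_val) {
  P <- design$P; K <- design$K
  params <- init_params(P, K, mean(counts[idx_train]), spec, fitcfg$init_sd)
  vel <- list(a1 = 0, v1 = numeric(P), J = matrix(0, P, P),
              v2 = numeric(K), a2 = 0, d = 0)
  best <- params
  best_val <- Inf
  bad_epochs <- 0L
  trace_train <- trace_val <- numeric(0)
  nb <- max(1L, length(idx_train) %/% fitcfg$batch_size)
  for (epoch in seq_len(fitcfg$max_epochs)) {
    ord <- sample(idx_train)
    splits <- split(ord, rep(seq_len(nb), length.out = length(ord)))
    for (b in splits) {
      g <- qc_gradient_core(design, params, spec, counts, idx = b)
      st <- sgd_step(params, g, vel, fitcfg$learning_rate, fitcfg$momentum,
                     spec$quadratic)
      params <- st$params; vel <- st$vel
    }
    tr <- nll_from_forward(qc_forward(design, params, spec, idx_train),
                           counts[idx_train])
    vl <- nll_from_forward(qc_forward(design, params, spec, idx_val),
                           counts[idx_val])
    if (!is.finite(tr) || !is.finite(vl))
      stop(sprintf("fold diverged at epoch %d (train NLL %g, val NLL %g)",
                   epoch, tr, vl))
    trace_train <- c(trace_train, tr)
    trace_val <- c(trace_val, vl)
    if (vl < best_val) {
      best_val <- vl; best <- params; bad_epochs <- 0L
    } else {
      bad_epochs <- bad_epochs + 1L
      if (bad_epochs >= fitcfg$patience) break
    }
  }
  list(params = canonicalize_params(best, spec), val_nll = best_val,
       trace_train = trace_train, trace_val = trace_val)
}

## The subunit stage has an exact sign symmetry:
## (a1, v1, J, v2) -> (-a1, -v1, -J, -v2) with the output bias shifted by
## the pooled constant leaves every predicted rate unchanged
## (logistic(-s) = 1 - logistic(s)).  Folds are mapped to the orientation
## with nonnegative total pooling weight before averaging, so that fold
## averages do not cancel and "excitatory" (positive-eigenvalue) features
## are features that increase the rate.
canonicalize_params <- function(p, spec) {
  if (sum(p$v2) >= 0) return(p)
  shift <- if (spec$final_nonlinearity == "softplus") p$d * sum(p$v2)
           else sum(p$v2)
  qc_params(-p$a1, -p$v1, -p$J, -p$v2, p$a2 + shift, p$d)
}

#' Fit a QC model by Poisson maximum likelihood
#'
#' Divides the usable frames into four contiguous temporal fourths; each
#' fourth serves once as the early-stopping validation set while SGD runs on
#' the other three.  The best-validation parameters of each fold are kept and
#' the four fold models are averaged element-wise.  Fully reproducible given
#' \code{fitcfg$seed}.
#'
#' @param movie a \code{\link{stimulus_movie}}.
#' @param counts spike counts, one per stimulus frame (length T), or one per
#'   usable frame (length T - n_lags + 1).
#' @param cfg a \code{\link{patch_config}}.
#' @param spec a \code{\link{model_spec}}.
#' @param fitcfg a \code{\link{fit_config}}.
#' @return an object of class \code{"qc_fit"}: fields \code{params} (the
#'   averaged \code{\link{qc_params}}), \code{folds} (list of 4 per-fold
#'   results with parameters and NLL traces), \code{spec}, \code{cfg},
#'   \code{fitcfg}.
#' @export
fit_qc <- function(movie, counts, cfg, spec = model_spec(),
                   fitcfg = fit_config()) {
  stopifnot(inherits(movie, "stimulus_movie"), inherits(cfg, "patch_config"))
  design <- model_design(movie, cfg, spec)
  counts <- usable_counts(counts, design)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (all(counts == 0)) stop("all-zero spike train: nothing to fit")
  N <- design$N
  if (N < 8L * fitcfg$batch_size)
    warning("fewer than 8 batches of usable frames; consider a smaller batch_size")
  fold_id <- cut(seq_len(N), breaks = 4, labels = FALSE)  # contiguous fourths
  folds <- with_seed(fitcfg$seed, {
    lapply(1:4, function(f) {
      fit_one_fold(design, counts, spec, fitcfg,
                   idx_train = which(fold_id != f),
                   idx_val = which(fold_id == f))
    })
  })
  avg <- average_params(lapply(folds, `[[`, "params"))
  structure(list(params = avg, folds = folds, spec = spec, cfg = cfg,
                 fitcfg = fitcfg,
                 n_frames = N, mean_count = mean(counts)),
            class = "qc_fit")
}

## element-wise arithmetic mean of fold parameters
average_params <- function(plist) {
  out <- plist[[1]]
  for (f in c("a1", "v1", "J", "v2", "a2", "d")) {
    out[[f]] <- Reduce(`+`, lapply(plist, `[[`, f)) / length(plist)
  }
  qc_params(out$a1, out$v1, out$J, out$v2, out$a2, out$d)
}

#' @export
print.qc_fit <- function(x, ...) {
  cat(sprintf("<qc_fit> %s%s model, P = %d, pooling length = %d\n",
              if (x$spec$quadratic) "quadratic" else "linear",
              if (x$spec$convolutional) " convolutional" else " non-convolutional",
              length(x$params$v1), length(x$params$v2)))
  vn <- vapply(x$folds, `[[`, numeric(1), "val_nll")
  cat(sprintf("  fold validation NLL (mean/frame): %s\n",
              paste(sprintf("%.4f", vn), collapse = ", ")))
  invisible(x)
}

#' @export
predict.qc_fit <- function(object, movie, ...) {
  predict_rate(movie, object$params, object$cfg, object$spec)
}

## ---- evaluation ----------------------------------------------------------

#' Noise-corrected prediction correlation
#'
#' Pearson correlation between the model prediction and the trial-averaged
#' response on a repeated-trial block, divided by an estimate of the maximum
#' attainable correlation given trial-to-trial variability.  The ceiling is
#' obtained from split-half reliability (interleaved odd/even trial split)
#' extrapolated to the full trial count by Spearman-Brown:
#' \code{ceiling = sqrt(n rho1 / (1 + (n-1) rho1))} where rho1 is the
#' implied single-trial reliability.  The corrected value is clipped to
#' [0, 1].
#'
#' @param params a \code{\link{qc_params}}.
#' @param spec a \code{\link{model_spec}}.
#' @param movie_test a \code{\link{stimulus_movie}}.
#' @param repeats n_trials x T matrix of spike counts (>= 2 trials).
#' @param cfg a \code{\link{patch_config}}.
#' @return corrected correlation in [0, 1], with attributes \code{raw}
#'   (uncorrected correlation) and \code{ceiling}.
#' @export
evaluate <- function(params, spec, movie_test, repeats, cfg) {
  if (!is.matrix(repeats) || nrow(repeats) < 2)
    stop("repeats must be a matrix with at least 2 trials")
  rate <- predict_rate(movie_test, params, cfg, spec)
  Tall <- ncol(repeats)
  t_first <- Tall - length(rate) + 1L
  rep_use <- repeats[, t_first:Tall, drop = FALSE]
  avg <- colMeans(rep_use)
  if (stats::sd(rate) == 0) {
    warning("zero-variance prediction; correlation undefined, returning 0")
    return(structure(0, raw = 0, ceiling = NA_real_))
  }
  raw <- stats::cor(rate, avg)
  n <- nrow(rep_use)
  half1 <- colMeans(rep_use[seq(1, n, by = 2), , drop = FALSE])
  half2 <- colMeans(rep_use[seq(2, n, by = 2), , drop = FALSE])
  r_half <- stats::cor(half1, half2)
  k <- n / 2
  ## invert Spearman-Brown at k trials, extrapolate to n
  rho1 <- r_half / (k - (k - 1) * r_half)
  ceiling_r <- if (is.na(rho1) || rho1 <= 0) NA_real_ else
    sqrt(n * rho1 / (1 + (n - 1) * rho1))
  corrected <- if (is.na(ceiling_r)) max(0, raw) else raw / ceiling_r
  structure(min(1, max(0, corrected)), raw = raw, ceiling = ceiling_r)
}
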