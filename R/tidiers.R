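## broom-style tidiers for the package's fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.eigen_features <- function(x, ...) {
  data.frame(feature = seq_along(x$values),
             eigenvalue = x$values,
             p_value = x$p_values,
             label = x$labels)
}

#' @export
tidy.gabor_fit <- function(x, ...) {
  df <- as.data.frame(x$gabors)
  df$gabor <- seq_len(nrow(df))
  df[, c("gabor", "x0", "y0", "theta", "gamma", "sigma", "lam", "phi", "w")]
}

#' @export
glance.gabor_fit <- function(x, ...) {
  data.frame(n_gabors = nrow(x$gabors), quadrature = x$quadrature,
             mse = x$mse, nmse = x$nmse, correlation = x$correlation,
             de_iterations = sum(x$de$iterations),
             de_converged = all(x$de$converged))
}

#' @export
tidy.qc_fit <- function(x, ...) {
  do.call(rbind, lapply(seq_along(x$folds), function(f) {
    tr <- x$folds[[f]]
    data.frame(fold = f, epoch = seq_along(tr$trace_val),
               train_nll = tr$trace_train, val_nll = tr$trace_val)
  }))
}

#' @export
glance.qc_fit <- function(x, ...) {
  data.frame(P = length(x$params$v1), pool_length = length(x$params$v2),
             quadratic = x$spec$quadratic,
             convolutional = x$spec$convolutional,
             final_nonlinearity = x$spec$final_nonlinearity,
             n_frames = x$n_frames, mean_count = x$mean_count,
             mean_val_nll = mean(vapply(x$folds, `[[`, numeric(1), "val_nll")))
}
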