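## Dataset and model containers.
##
## Datasets are single-file serialized containers (.rds) holding a named
## list with keys `stimulus` (T x H x W array), `spikes` (length T),
## `bin_ms`, and optionally `repeats` (n_trials x T).  Models hold the
## QC parameter blocks (`a1`, `v1`, `J`, `v2`, `a2`, `d`) plus geometry and
## model-structure flags, and the full fit configuration for provenance.

#' Write a stimulus/response dataset
#'
#' @param path output file path.
#' @param movie a \code{\link{stimulus_movie}}.
#' @param spikes spike counts, one per frame.
#' @param repeats optional n_trials x T matrix of repeated-trial counts.
#' @return the path, invisibly.
#' @export
write_dataset <- function(path, movie, spikes, repeats = NULL) {
  stopifnot(inherits(movie, "stimulus_movie"))
  d <- dim(movie$frames)
  if (length(spikes) != d[1])
    stop("`spikes` must have one count per stimulus frame")
  if (!is.null(repeats) && ncol(repeats) != d[1])
    stop("`repeats` must have one column per stimulus frame")
  saveRDS(list(stimulus = movie$frames, spikes = as.integer(spikes),
               bin_ms = movie$bin_ms, repeats = repeats),
          path)
  invisible(path)
}

#' Read a stimulus/response dataset
#'
#' Validates the container, mean-centers the movie on load, and enforces
#' integer nonnegative counts and matching shapes.
#'
#' @param path dataset file written by \code{\link{write_dataset}}.
#' @return list with \code{movie} (a \code{\link{stimulus_movie}}),
#'   \code{spikes}, \code{repeats} (possibly NULL).
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- readRDS(path)
  for (key in c("stimulus", "spikes", "bin_ms")) {
    if (is.null(x[[key]])) stop("dataset is missing key `", key, "`")
  }
  if (!all(is.finite(x$stimulus)))
    stop("key `stimulus` contains non-finite values")
  d <- dim(x$stimulus)
  if (length(d) != 3) stop("key `stimulus` must be a T x H x W array")
  if (length(x$spikes) != d[1])
    stop("key `spikes` has length ", length(x$spikes),
         " but `stimulus` has ", d[1], " frames")
  if (any(x$spikes < 0) || any(x$spikes != round(x$spikes)))
    stop("key `spikes` must hold nonnegative integer counts")
  if (!is.null(x$repeats)) {
    if (!is.matrix(x$repeats) || ncol(x$repeats) != d[1])
      stop("key `repeats` must be an n_trials x T matrix")
  }
  list(movie = stimulus_movie(x$stimulus, x$bin_ms),
       spikes = as.integer(x$spikes), repeats = x$repeats)
}

#' Write a fitted model
#'
#' Serializes the averaged parameters, the per-fold parameters and traces,
#' the geometry, model-structure flags and fit configuration (full
#' provenance, seed included).
#'
#' @param path output file path.
#' @param fit a \code{\link{fit_qc}} result (or a bare
#'   \code{\link{qc_params}} plus \code{cfg}/\code{spec}).
#' @param cfg,spec required when \code{fit} is a bare parameter set.
#' @return the path, invisibly.
#' @export
write_model <- function(path, fit, cfg = NULL, spec = NULL) {
  if (inherits(fit, "qc_fit")) {
    obj <- list(params = unclass(fit$params), cfg = unclass(fit$cfg),
                spec = unclass(fit$spec), fitcfg = unclass(fit$fitcfg),
                folds = lapply(fit$folds, function(f)
                  list(params = unclass(f$params), val_nll = f$val_nll,
                       trace_train = f$trace_train, trace_val = f$trace_val)))
  } else {
    stopifnot(inherits(fit, "qc_params"), !is.null(cfg), !is.null(spec))
    obj <- list(params = unclass(fit), cfg = unclass(cfg),
                spec = unclass(spec), fitcfg = NULL, folds = NULL)
  }
  saveRDS(obj, path)
  invisible(path)
}

#' Read a fitted model
#'
#' @param path model file written by \code{\link{write_model}}.
#' @return list with \code{params} (\code{\link{qc_params}}), \code{cfg},
#'   \code{spec}, \code{fitcfg}, \code{folds}.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- readRDS(path)
  p <- x$params
  list(params = qc_params(p$a1, p$v1, p$J, p$v2, p$a2, p$d),
       cfg = do.call(patch_config,
                     x$cfg[c("patch_h", "patch_w", "stride", "n_lags")]),
       spec = model_spec(x$spec$quadratic, x$spec$convolutional,
                         x$spec$final_nonlinearity),
       fitcfg = x$fitcfg, folds = x$folds)
}
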