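## Per-neuron summary combining feature counts, Gabor geometry and
## sparseness metrics.

#' Summarize one fitted neuron
#'
#' Collects the per-neuron quantities the population analyses are built
#' from: significant feature counts, the angular spread of the excitatory
#' Gabors and the resulting uniform/nonuniform class, the pooling-mask
#' decomposition (convolutional models), and lifetime sparseness with and
#' without the suppressive features on a stimulus ensemble.
#'
#' @param params a \code{\link{qc_params}}.
#' @param cfg a \code{\link{patch_config}}.
#' @param spec a \code{\link{model_spec}}.
#' @param features an \code{\link{eigen_features}} for \code{params$J}.
#' @param gabors a \code{\link{gabor_set}} with signed weights (excitatory
#'   and suppressive fits combined), or NULL.
#' @param movie a held-out \code{\link{stimulus_movie}}, or NULL to skip
#'   the sparseness computation.
#' @param class_threshold angular-spread split point in degrees.
#' @param frame_dims stimulus frame dims (required for the pooling
#'   decomposition when \code{movie} is NULL).
#' @return a one-row data.frame (class \code{"neuron_summary"}).
#' @export
neuron_summary <- function(params, cfg, spec, features, gabors = NULL,
                           movie = NULL, class_threshold = 20,
                           frame_dims = NULL) {
  out <- data.frame(
    n_excitatory = features$n_excitatory,
    n_suppressive = features$n_suppressive,
    n_total = length(features$values),
    angular_std = NA_real_, class_label = NA_character_,
    pooling_type = NA_character_, temporal_type = NA_character_,
    sparseness_full = NA_real_, sparseness_no_suppression = NA_real_,
    sparseness_ratio = NA_real_)
  if (!is.null(gabors)) {
    exc <- gabors[gabors$w > 0, ]
    if (nrow(exc) >= 2) {
      out$angular_std <- angular_std(exc$theta * 180 / pi)
      out$class_label <- as.character(
        classify_neurons(out$angular_std, threshold = class_threshold))
    }
  }
  if (spec$convolutional) {
    if (is.null(frame_dims)) {
      if (is.null(movie)) stop("frame_dims or movie needed for the pooling decomposition")
      frame_dims <- dim(movie)[2:3]
    }
    g <- grid_dims(frame_dims, cfg)
    pd <- pooling_decomposition(params$v2, g, cfg$n_lags)
    out$pooling_type <- pd$pooling_type
    out$temporal_type <- pd$temporal_type
  }
  if (!is.null(movie)) {
    sp <- suppression_sparseness_ratio(params, features, movie, cfg, spec)
    out$sparseness_full <- sp$S_full
    out$sparseness_no_suppression <- sp$S_no_supp
    out$sparseness_ratio <- sp$ratio
  }
  class(out) <- c("neuron_summary", "data.frame")
  out
}
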