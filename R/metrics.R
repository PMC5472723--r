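## Population-level analytics: sparseness with/without suppression,
## orientation spread and classification, excitatory-suppressive
## orientation differences, pooling-mask decomposition.

#' Lifetime sparseness
#'
#' Treves-Rolls / Vinje-Gallant lifetime sparseness of a nonnegative rate
#' vector:
#' \deqn{S = \frac{1 - (\sum r/n)^2 / (\sum r^2/n)}{1 - 1/n}}
#' 0 for constant firing, approaching 1 for rare selective firing.  Scale
#' invariant: S(c r) = S(r).
#'
#' @param rates nonnegative rates, not all zero.
#' @return scalar in [0, 1].
#' @examples
#' sparseness(c(1, 0, 0, 1))  # 2/3
#' @export
sparseness <- function(rates) {
  if (any(rates < 0)) stop("rates must be nonnegative")
  if (all(rates == 0)) stop("all-zero rates: sparseness undefined")
  n <- length(rates)
  if (n < 2) stop("need at least two bins")
  (1 - mean(rates)^2 / mean(rates^2)) / (1 - 1 / n)
}

#' Sparseness with and without suppressive features
#'
#' Predicted rates are evaluated on a stimulus ensemble twice: with the full
#' quadratic kernel, and with the kernel rebuilt from the significant
#' excitatory eigen-features only (all other parameters fixed).  Returns
#' both lifetime sparseness values and the fraction of sparseness that
#' remains after suppression is removed.
#'
#' @param params a \code{\link{qc_params}}.
#' @param features an \code{\link{eigen_features}} object for
#'   \code{params$J}.
#' @param movie a \code{\link{stimulus_movie}} (held-out stimuli).
#' @param cfg a \code{\link{patch_config}}.
#' @param spec a \code{\link{model_spec}}.
#' @return list with \code{S_full}, \code{S_no_supp}, \code{ratio}
#'   (= S_no_supp / S_full) and \code{note}.
#' @export
suppression_sparseness_ratio <- function(params, features, movie, cfg,
                                         spec = model_spec()) {
  r_full <- predict_rate(movie, params, cfg, spec)
  S_full <- sparseness(r_full)
  if (features$n_suppressive == 0) {
    return(list(S_full = S_full, S_no_supp = S_full, ratio = 1,
                note = "no suppressive features; ratio is 1 by definition"))
  }
  J_exc <- reconstruct_J(features, "excitatory")
  p2 <- params
  p2$J <- J_exc
  r_ns <- predict_rate(movie, p2, cfg, spec)
  S_ns <- sparseness(r_ns)
  list(S_full = S_full, S_no_supp = S_ns, ratio = S_ns / S_full, note = NULL)
}

#' Angular standard deviation of axial orientations
#'
#' Circular spread of orientations treated axially (mod 180 degrees):
#' angles are doubled, the circular resultant length R computed, the
#' angular deviation \code{sqrt(2 (1 - R))} (radians) halved back to
#' orientation units and converted to degrees.  0 for identical
#' orientations; maximal (about 40.5 degrees) for an orthogonal set, whose
#' doubled-angle resultant length is 0.
#'
#' @param orientations angles in degrees (axial).
#' @return spread in degrees.
#' @export
angular_std <- function(orientations) {
  if (length(orientations) < 2) stop("need at least two orientations")
  a <- 2 * orientations * pi / 180
  R <- sqrt(mean(cos(a))^2 + mean(sin(a))^2)
  sqrt(2 * (1 - R)) / 2 * 180 / pi
}

#' Classify neurons by orientation spread
#'
#' Splits a population into "uniform" (below threshold) and "nonuniform"
#' (at or above threshold) classes by the angular standard deviation of
#' their excitatory Gabors.  If no threshold is supplied it is placed at the
#' midpoint of the largest gap of the empirical distribution.
#'
#' @param angular_stds per-neuron spreads in degrees.
#' @param threshold optional split point in degrees.
#' @return factor with levels \code{uniform}, \code{nonuniform}; the
#'   threshold used is attached as attribute \code{"threshold"}.
#' @export
classify_neurons <- function(angular_stds, threshold = NULL) {
  if (is.null(threshold)) {
    s <- sort(angular_stds)
    if (length(s) < 2) stop("supply a threshold to classify a single neuron")
    gaps <- diff(s)
    g <- which.max(gaps)
    threshold <- (s[g] + s[g + 1]) / 2
  }
  lab <- factor(ifelse(angular_stds < threshold, "uniform", "nonuniform"),
                levels = c("uniform", "nonuniform"))
  attr(lab, "threshold") <- threshold
  lab
}

#' Excitatory-suppressive orientation differences
#'
#' For each suppressive Gabor, the axial orientation difference to its
#' nearest excitatory Gabor (by center distance; \code{scope = "nearest"})
#' or to every excitatory Gabor (\code{scope = "all"}), histogrammed in 8
#' equal bins over [0, 90] degrees with a chi-square statistic against the
#' uniform distribution (7 degrees of freedom).
#'
#' @param gabors a \code{\link{gabor_set}} with signed weights (positive
#'   excitatory, negative suppressive).
#' @param scope \code{"nearest"} or \code{"all"}.
#' @return list with \code{differences} (degrees), \code{counts} (8 bins),
#'   \code{breaks}, \code{chisq}, \code{p_value}.
#' @export
ex_supp_orientation_differences <- function(gabors,
                                            scope = c("nearest", "all")) {
  scope <- match.arg(scope)
  exc <- which(gabors$w > 0)
  sup <- which(gabors$w < 0)
  if (length(exc) < 1 || length(sup) < 1)
    stop("need at least one excitatory and one suppressive Gabor")
  diffs <- numeric(0)
  for (s in sup) {
    d_or <- axial_diff_deg(gabors$theta[s] * 180 / pi,
                           gabors$theta[exc] * 180 / pi)
    if (scope == "nearest") {
      dist <- sqrt((gabors$x0[s] - gabors$x0[exc])^2 +
                     (gabors$y0[s] - gabors$y0[exc])^2)
      diffs <- c(diffs, d_or[which.min(dist)])
    } else diffs <- c(diffs, d_or)
  }
  breaks <- seq(0, 90, length.out = 9)
  counts <- as.vector(table(cut(pmin(diffs, 90), breaks,
                                include.lowest = TRUE)))
  expected <- length(diffs) / 8
  chisq <- sum((counts - expected)^2 / expected)
  list(differences = diffs, counts = counts, breaks = breaks,
       chisq = chisq,
       p_value = stats::pchisq(chisq, df = 7, lower.tail = FALSE))
}

#' Decompose the pooling mask into space and time
#'
#' Reshapes the pooling weights v2 (canonical lag-major order) into a
#' (grid positions) x (lags) matrix and takes its rank-1 SVD factorization,
#' with the sign convention that the temporal kernel's peak-magnitude
#' element is positive.  The spatial map is "biphasic" if its positive and
#' negative lobes each carry more than \code{lobe_frac} of the total
#' absolute mass, else "uniform"; the temporal kernel is classified
#' biphasic/unimodal the same way.
#'
#' @param v2 pooling weight vector, length Gy*Gx*n_lags.
#' @param grid c(Gy, Gx).
#' @param n_lags number of latencies.
#' @param lobe_frac opposed-lobe mass threshold (default 0.2).
#' @return list with \code{spatial} (Gy x Gx matrix), \code{temporal}
#'   (length n_lags), \code{pooling_type} ("uniform"/"biphasic"),
#'   \code{temporal_type}, \code{singular_values}.
#' @export
pooling_decomposition <- function(v2, grid, n_lags, lobe_frac = 0.2) {
  G <- prod(grid)
  if (length(v2) != G * n_lags)
    stop("v2 length does not match grid * n_lags")
  if (all(v2 == 0)) stop("zero pooling mask")
  M <- matrix(v2, nrow = G, ncol = n_lags)  # lag-major vector -> lag columns
  sv <- svd(M)
  s <- sv$u[, 1] * sqrt(sv$d[1])
  tk <- sv$v[, 1] * sqrt(sv$d[1])
  if (tk[which.max(abs(tk))] < 0) { tk <- -tk; s <- -s }
  biphasic <- function(x) {
    tot <- sum(abs(x))
    min(sum(x[x > 0]), sum(-x[x < 0])) / tot > lobe_frac
  }
  list(spatial = matrix(s, grid[1], grid[2], byrow = TRUE),
       temporal = tk,
       pooling_type = if (biphasic(s)) "biphasic" else "uniform",
       temporal_type = if (biphasic(tk)) "biphasic" else "unimodal",
       singular_values = sv$d)
}

#' Randomize suppressive Gabor orientations
#'
#' Returns a copy of the Gabor set in which every suppressive Gabor's
#' orientation is redrawn uniformly from (-pi, pi], leaving all other
#' parameters and the excitatory Gabors untouched.  Used to test how the
#' fitted (orthogonal) arrangement of suppression shapes response
#' sparseness.
#'
#' @param gabors a \code{\link{gabor_set}}.
#' @param seed integer seed.
#' @return a \code{\link{gabor_set}}.
#' @export
randomize_suppressive_orientations <- function(gabors, seed = 1L) {
  sup <- which(gabors$w < 0)
  with_seed(seed, {
    gabors$theta[sup] <- wrap_rad(stats::runif(length(sup), -pi, pi))
  })
  gabors
}
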