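## Ground-truth model neurons and stimulus ensembles for recovery and
## calibration tests.  The ground-truth response rules are evaluated by a
## deliberate straight-loop implementation, independent of the vectorized
## model code they validate.

#' Generate a synthetic stimulus movie
#'
#' \code{"white"}: i.i.d. standard Gaussian pixels.  \code{"pink"}: per
#' frame, Fourier synthesis with 1/f amplitude spectrum and random phases
#' (a naturalistic second-order statistic), normalized to zero mean and
#' unit variance over the movie.
#'
#' @param kind \code{"white"} or \code{"pink"}.
#' @param n_frames,height,width movie dimensions.
#' @param seed integer seed.
#' @param bin_ms frame duration (ms).
#' @return a \code{\link{stimulus_movie}}.
#' @export
generate_stimulus <- function(kind = c("white", "pink"), n_frames, height,
                              width, seed = 1L, bin_ms = 16) {
  kind <- match.arg(kind)
  frames <- with_seed(seed, {
    if (kind == "white") {
      array(stats::rnorm(n_frames * height * width),
            dim = c(n_frames, height, width))
    } else {
      fy <- c(0:(height %/% 2), -((height - height %/% 2 - 1):1)) / height
      fx <- c(0:(width %/% 2), -((width - width %/% 2 - 1):1)) / width
      fr <- sqrt(outer(fy^2, fx^2, `+`))
      amp <- ifelse(fr > 0, 1 / fr, 0)
      out <- array(0, dim = c(n_frames, height, width))
      for (t in seq_len(n_frames)) {
        wn <- matrix(stats::rnorm(height * width), height, width)
        f <- stats::fft(wn) * amp
        out[t, , ] <- Re(stats::fft(f, inverse = TRUE)) / (height * width)
      }
      out
    }
  })
  frames <- frames - mean(frames)
  frames <- frames / stats::sd(frames)
  stimulus_movie(frames, bin_ms = bin_ms, center = FALSE)
}

#' Third-order-interaction model neuron
#'
#' A neuron driven exclusively by the triple product of the projections of
#' the stimulus patch onto three orthonormal features:
#' \code{rate = baseline + gain * softplus(prod_i (u_i . x) / scale)}.
#' There is no pairwise-only drive: any patch orthogonal to one feature
#' yields the baseline rate.
#'
#' @param features P x 3 matrix of feature vectors (orthonormalized by QR
#'   before use).
#' @param gain,baseline output gain and baseline (spikes/bin).
#' @param scale divisor of the triple product before rectification.
#' @return object of class \code{"ground_truth_neuron"} (rule
#'   \code{"third_order"}).
#' @export
third_order_neuron <- function(features, gain = 1, baseline = 0,
                               scale = 1) {
  features <- as.matrix(features)
  if (ncol(features) != 3)
    stop("a third-order neuron needs exactly 3 features")
  if (any(colSums(features^2) == 0)) stop("zero feature vector")
  features <- qr.Q(qr(features))  # orthonormalize, documented
  structure(list(rule = "third_order", features = features, gain = gain,
                 baseline = baseline, scale = scale),
            class = "ground_truth_neuron")
}

#' Response of a third-order neuron to one patch
#'
#' @param patch numeric patch vector.
#' @param neuron a \code{\link{third_order_neuron}}.
#' @return nonnegative rate (spikes/bin).
#' @export
third_order_response <- function(patch, neuron) {
  if (neuron$rule != "third_order") stop("neuron rule is not third_order")
  u <- neuron$features
  z <- sum(u[, 1] * patch) * sum(u[, 2] * patch) * sum(u[, 3] * patch)
  neuron$baseline + neuron$gain * softplus(z / neuron$scale)
}

#' Ground-truth QC neuron with known Gabor structure
#'
#' Builds a quadratic convolutional model neuron whose kernel is a known
#' sum of Gabor outer products: an excitatory quadrature pair (phases 0 and
#' pi/2) at orientation \code{exc_theta} and, optionally, a suppressive
#' quadrature pair at \code{sup_theta} (orthogonal by default: a
#' cross-orientation-suppression cell).  The pooling mask over the
#' (grid x lags) axis is uniform or biphasic.  Returns the exact
#' \code{\link{qc_params}} for oracle comparison together with the neuron
#' record.
#'
#' @param frame_dims c(H, W) of the stimulus frames.
#' @param cfg a \code{\link{patch_config}}.
#' @param exc_theta,sup_theta orientations (radians).
#' @param exc_weight,sup_weight nonnegative kernel weights (the suppressive
#'   weight enters with a negative sign); \code{sup_weight = 0} gives an
#'   excitatory-only complex cell.
#' @param sigma,lam,gamma shared Gabor envelope, wavelength, aspect.
#' @param pooling \code{"uniform"} or \code{"biphasic"} spatial mask.
#' @param a1 subunit bias.
#' @param gain output scale d.
#' @param a2 output bias.
#' @param convolutional pool over the full grid (TRUE) or a single centered
#'   patch (FALSE).
#' @return list with \code{neuron} (class \code{"ground_truth_neuron"},
#'   rule \code{"qc"}), \code{params}, \code{cfg}, \code{spec},
#'   \code{gabors}.
#' @export
qc_ground_truth <- function(frame_dims, cfg, exc_theta = 0,
                            sup_theta = exc_theta + pi / 2,
                            exc_weight = 1, sup_weight = 1,
                            sigma = NULL, lam = NULL, gamma = 1,
                            pooling = c("uniform", "biphasic"),
                            a1 = -2, gain = 1, a2 = 0,
                            convolutional = TRUE) {
  pooling <- match.arg(pooling)
  h <- cfg$patch_h; w <- cfg$patch_w
  if (is.null(sigma)) sigma <- h / 5
  if (is.null(lam)) lam <- h / 2
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  gb <- gabor_set(x0 = rep(cx, 4), y0 = rep(cy, 4),
                  theta = c(exc_theta, exc_theta, sup_theta, sup_theta),
                  gamma = gamma, sigma = sigma, lam = lam,
                  phi = c(0, pi / 2, 0, pi / 2),
                  w = c(exc_weight, exc_weight, -sup_weight, -sup_weight))
  if (sup_weight == 0) gb <- gb[1:2, ]
  J <- gabor_sum_J(gb, c(h, w))
  spec <- model_spec(quadratic = TRUE, convolutional = convolutional)
  K <- model_pool_length(frame_dims, cfg, spec)
  if (spec$convolutional) {
    g <- grid_dims(frame_dims, cfg)
    Gn <- as.integer(g["gy"]) * as.integer(g["gx"])
    sp <- if (pooling == "uniform") rep(1, Gn) else {
      m <- matrix(1, g["gy"], g["gx"])
      m[, seq_len(g["gx"] %/% 2)] <- -0.8
      flatten_rowmajor(m)
    }
    tk <- exp(-(0:(cfg$n_lags - 1)) / 2)           # decaying temporal kernel
    v2 <- as.vector(outer(sp, tk))                 # lag-major: lag slowest
  } else {
    v2 <- exp(-(0:(cfg$n_lags - 1)) / 2)
  }
  v2 <- v2 / sum(abs(v2))
  params <- qc_params(a1 = a1, v1 = numeric(h * w), J = J, v2 = v2,
                      a2 = a2, d = gain)
  neuron <- structure(list(rule = "qc", params = params, cfg = cfg,
                           spec = spec, gabors = gb),
                      class = "ground_truth_neuron")
  list(neuron = neuron, params = params, cfg = cfg, spec = spec, gabors = gb)
}

#' Straight-loop response of a ground-truth neuron to a movie
#'
#' Independent reference evaluation of a ground-truth neuron's response
#' rule, written as explicit loops over frames, grid positions and lags
#' with no shared code with the vectorized model path.  Used to validate
#' \code{\link{predict_rate}} and as the rate generator in recovery tests.
#'
#' @param neuron a \code{"ground_truth_neuron"}.
#' @param movie a \code{\link{stimulus_movie}}.
#' @param cfg a \code{\link{patch_config}} (for third-order neurons, whose
#'   record carries no geometry).
#' @return rate vector over frames with full lag history.
#' @export
ground_truth_response <- function(neuron, movie, cfg = NULL) {
  if (neuron$rule == "third_order") {
    if (is.null(cfg)) stop("cfg required for a third-order neuron")
    d <- dim(movie$frames)
    pos <- center_position(d[2:3], cfg)
    ts <- cfg$n_lags:d[1]
    rate <- numeric(length(ts))
    for (i in seq_along(ts)) {
      fr <- movie$frames[ts[i], , ]
      patch <- numeric(cfg$patch_h * cfg$patch_w)
      idx <- 0L
      for (r in 1:cfg$patch_h) for (c in 1:cfg$patch_w) {
        idx <- idx + 1L
        patch[idx] <- fr[pos$row + r, pos$col + c]
      }
      rate[i] <- third_order_response(patch, neuron)
    }
    return(rate)
  }
  ## QC rule: explicit loops through subunits and pooling
  cfg <- neuron$cfg; p <- neuron$params; spec <- neuron$spec
  d <- dim(movie$frames)
  positions <- if (spec$convolutional) grid_offsets(d[2:3], cfg)
               else center_position(d[2:3], cfg)
  ts <- cfg$n_lags:d[1]
  rate <- numeric(length(ts))
  for (i in seq_along(ts)) {
    t <- ts[i]
    pooled <- 0
    k <- 0L
    for (lag in 0:(cfg$n_lags - 1L)) {
      fr <- movie$frames[t - lag, , ]
      for (pp in seq_len(nrow(positions))) {
        patch <- numeric(cfg$patch_h * cfg$patch_w)
        idx <- 0L
        for (r in 1:cfg$patch_h) for (c in 1:cfg$patch_w) {
          idx <- idx + 1L
          patch[idx] <- fr[positions$row[pp] + r, positions$col[pp] + c]
        }
        s <- p$a1
        for (q in seq_along(patch)) s <- s + p$v1[q] * patch[q]
        ## explicit double sum over the kernel
        s <- s + sum(p$J * outer(patch, patch))
        k <- k + 1L
        pooled <- pooled + p$v2[k] * (1 / (1 + exp(-s)))
      }
    }
    rate[i] <- if (spec$final_nonlinearity == "softplus")
      log1p(exp(p$d * pooled + p$a2)) else p$d / (1 + exp(-(pooled + p$a2)))
  }
  rate
}

#' Poisson spike counts from a rate vector
#'
#' @param rates nonnegative rates (spikes/bin).
#' @param seed integer seed.
#' @return integer counts, reproducible given the seed.
#' @export
sample_spikes <- function(rates, seed = 1L) {
  if (any(rates < 0)) stop("rates must be nonnegative")
  with_seed(seed, stats::rpois(length(rates), rates))
}

#' Subspace projection of true features onto recovered features
#'
#' Mean over the true feature vectors of the squared norm of their
#' projection onto the span of the recovered vectors (orthonormalized by
#' QR).  1 means the true span is perfectly contained in the recovered
#' span; 0 means orthogonality.
#'
#' @param recovered P x m matrix of recovered directions.
#' @param true P x k matrix of true features.
#' @return scalar in [0, 1].
#' @export
subspace_projection <- function(recovered, true) {
  recovered <- as.matrix(recovered); true <- as.matrix(true)
  if (nrow(recovered) != nrow(true))
    stop("recovered and true features live in different dimensions")
  if (any(colSums(recovered^2) == 0) || any(colSums(true^2) == 0))
    stop("zero vector among features")
  Q <- qr.Q(qr(recovered))
  tn <- sweep(true, 2, sqrt(colSums(true^2)), `/`)
  mean(colSums(crossprod(Q, tn)^2))
}

#' Gabor-like feature set for third-order model neurons
#'
#' Three unit-norm Gabor patch vectors at distinct orientations (default
#' 0, 60 and 120 degrees), centered in the patch.  Passed to
#' \code{\link{third_order_neuron}}, which orthonormalizes them.
#'
#' @param dims patch dimensions c(height, width).
#' @param thetas orientations in radians.
#' @param sigma,lam envelope size and wavelength (defaults scale with the
#'   patch).
#' @return P x length(thetas) matrix of unit-norm feature vectors.
#' @export
orthogonal_gabor_features <- function(dims, thetas = c(0, pi / 3, 2 * pi / 3),
                                      sigma = NULL, lam = NULL) {
  h <- dims[1]
  if (is.null(sigma)) sigma <- h / 4
  if (is.null(lam)) lam <- h / 2
  cx <- (dims[2] - 1) / 2; cy <- (h - 1) / 2
  vapply(thetas, function(th)
    gabor_image(list(x0 = cx, y0 = cy, theta = th, gamma = 1, sigma = sigma,
                     lam = lam, phi = pi / 2), dims),
    numeric(prod(dims)))
}
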