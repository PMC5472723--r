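## Self-adaptive rand/2/bin differential evolution, and the Gabor
## decomposition of the quadratic kernel fitted with it.
##
## Mutation: u' = u_r1 + F (u_r2 - u_r3) + F (u_r4 - u_r5) with r1..r5 five
## unique member indices excluding i; binomial crossover with one forced
## coordinate j_rand; per-member CR ~ rand[0,1) and F ~ 0.1 + 0.9 rand[0,1),
## each re-drawn before mutation with probability tau (kept only if the
## trial wins, jDE style); out-of-bounds proposals score infinite error;
## greedy replacement on the objective; the run ends when no member changes
## in an iteration (or at max_iter).

#' Differential-evolution configuration
#'
#' @param pop_factor population size = pop_factor * number of free
#'   parameters (floor of 7: rand/2/bin needs 5 distinct partners + base +
#'   self).
#' @param tau probability of re-drawing a member's CR and F before mutation.
#' @param restarts independent restarts; the best run is kept.
#' @param max_iter safety cap on iterations per restart.
#' @param seed integer seed.
#' @param bounds optional named list overriding parameter ranges:
#'   \code{sigma}, \code{gamma}, \code{lam} as length-2 positive ranges
#'   (log-uniform initialization).
#' @return an object of class \code{"de_config"}.
#' @export
de_config <- function(pop_factor = 10L, tau = 0.1, restarts = 3L,
                      max_iter = 500L, seed = 1L, bounds = list()) {
  structure(list(pop_factor = as.integer(pop_factor), tau = tau,
                 restarts = as.integer(restarts),
                 max_iter = as.integer(max_iter),
                 seed = as.integer(seed), bounds = bounds),
            class = "de_config")
}

## Generic rand/2/bin DE minimizer.  RNG state is the caller's.
de_optimize <- function(objective, lower, upper, np, tau = 0.1,
                        max_iter = 500L) {
  D <- length(lower)
  np <- max(np, 7L)
  pop <- matrix(stats::runif(np * D, rep(lower, each = np),
                             rep(upper, each = np)), np, D)
  f <- apply(pop, 1, objective)
  CR <- stats::runif(np)
  FF <- 0.1 + 0.9 * stats::runif(np)
  iter <- 0L
  evals <- np
  best_trace <- min(f)
  repeat {
    iter <- iter + 1L
    changed <- FALSE
    for (i in seq_len(np)) {
      cr_i <- if (stats::runif(1) < tau) stats::runif(1) else CR[i]
      f_i <- if (stats::runif(1) < tau) 0.1 + 0.9 * stats::runif(1) else FF[i]
      r <- sample(seq_len(np)[-i], 5L)
      u <- pop[r[1], ] + f_i * (pop[r[2], ] - pop[r[3], ]) +
        f_i * (pop[r[4], ] - pop[r[5], ])
      jrand <- sample.int(D, 1L)
      cross <- stats::runif(D) < cr_i
      cross[jrand] <- TRUE
      trial <- ifelse(cross, u, pop[i, ])
      ft <- if (any(trial < lower | trial > upper)) Inf else {
        evals <- evals + 1L
        objective(trial)
      }
      if (ft < f[i]) {
        pop[i, ] <- trial; f[i] <- ft
        CR[i] <- cr_i; FF[i] <- f_i
        changed <- TRUE
      }
    }
    best_trace <- c(best_trace, min(f))
    if (!changed || iter >= max_iter) break
  }
  b <- which.min(f)
  list(par = pop[b, ], value = f[b], iterations = iter, evals = evals,
       converged = iter < max_iter, best_trace = best_trace)
}

## ---- Gabor objective -----------------------------------------------------

## genotype layout per Gabor: x0, y0, theta, log(gamma), log(sigma),
## log(lam) [, phi].  Multiplicative parameters live in log space so DE
## steps are changes of scale.
gabor_bounds <- function(dims, quadrature, n, bounds = list()) {
  h <- dims[1]; w <- dims[2]
  sig <- bounds$sigma %||% c(0.7, max(h, w))
  gam <- bounds$gamma %||% c(0.2, 5)
  lam <- bounds$lam %||% c(2, 2 * max(h, w))
  base_lo <- c(0, 0, -pi, log(gam[1]), log(sig[1]), log(lam[1]))
  base_hi <- c(w - 1, h - 1, pi, log(gam[2]), log(sig[2]), log(lam[2]))
  if (!quadrature) {
    base_lo <- c(base_lo, -pi)
    base_hi <- c(base_hi, pi)
  }
  list(lower = rep(base_lo, n), upper = rep(base_hi, n),
       per = length(base_lo))
}

## decode a genotype into a gabor_set (without weights); quadrature pairs
## expand to two members with phases 0 and pi/2
decode_gabors <- function(par, dims, quadrature) {
  per <- if (quadrature) 6L else 7L
  n <- length(par) / per
  m <- matrix(par, nrow = per)
  if (quadrature) {
    gabor_set(x0 = rep(m[1, ], each = 2), y0 = rep(m[2, ], each = 2),
              theta = rep(m[3, ], each = 2), gamma = exp(rep(m[4, ], each = 2)),
              sigma = exp(rep(m[5, ], each = 2)), lam = exp(rep(m[6, ], each = 2)),
              phi = rep(c(0, pi / 2), n), w = 0)
  } else {
    gabor_set(x0 = m[1, ], y0 = m[2, ], theta = m[3, ],
              gamma = exp(m[4, ]), sigma = exp(m[5, ]), lam = exp(m[6, ]),
              phi = m[7, ], w = 0)
  }
}

## Best nonnegative weights and squared error for unit-norm images G
## against target Jp (P x P):  min_{w>=0} ||Jp - sum w_i g_i g_i'||_F^2.
## Uses the m x m system A_ij = (g_i.g_j)^2, b_i = g_i' Jp g_i.
gabor_weights_sse <- function(G, Jp, J_fro2) {
  A <- crossprod(G)^2
  b <- colSums(G * (Jp %*% G))
  m <- ncol(G)
  if (m == 1) {
    w <- max(b / A, 0)
  } else {
    R <- tryCatch(chol(A + diag(1e-10, m)), error = function(e) NULL)
    if (is.null(R)) return(list(w = rep(0, m), sse = J_fro2))
    d <- forwardsolve(t(R), b)
    w <- pracma::lsqnonneg(R, d)$x
  }
  sse <- J_fro2 - 2 * sum(w * b) + drop(crossprod(w, A %*% w))
  list(w = w, sse = max(sse, 0))
}

#' Fit Gabors to one part of the quadratic kernel
#'
#' Approximates a reduced kernel (reconstructed from only the significant
#' excitatory or only the suppressive eigen-features) as a weighted sum of
#' Gabor outer products, minimizing mean squared error by self-adaptive
#' rand/2/bin differential evolution.  The DE searches the 7 geometric
#' parameters per Gabor (6 per quadrature pair: phases are fixed at 0 and
#' pi/2 and all other parameters are shared); at every objective evaluation
#' the weights are solved exactly by sign-constrained least squares, so
#' excitatory fits get w >= 0 and suppressive fits w <= 0 (pair members
#' carry two independent weights).
#'
#' @param J_part symmetric reduced kernel.
#' @param dims patch dimensions c(height, width).
#' @param n_gabors number of Gabors (or of quadrature pairs); typically the
#'   number of significant features (pairs: half of it).
#' @param quadrature fit quadrature pairs instead of independent Gabors.
#' @param de a \code{\link{de_config}}.
#' @param part \code{"auto"} (sign from the kernel trace), \code{"excitatory"}
#'   or \code{"suppressive"}.
#' @return object of class \code{"gabor_fit"}: \code{gabors} (a
#'   \code{\link{gabor_set}} with fitted signed weights), \code{J_fit},
#'   \code{mse}, \code{nmse} (MSE / mean squared entry of the target),
#'   \code{correlation} between target and fit, and DE diagnostics.
#' @export
fit_gabors <- function(J_part, dims, n_gabors, quadrature = FALSE,
                       de = de_config(), part = c("auto", "excitatory",
                                                  "suppressive")) {
  part <- match.arg(part)
  if (n_gabors < 1) stop("n_gabors must be >= 1")
  if (!is.matrix(J_part) || nrow(J_part) != ncol(J_part) ||
      max(abs(J_part - t(J_part))) > 1e-8 * max(1, max(abs(J_part))))
    stop("J_part must be a symmetric matrix")
  if (prod(dims) != nrow(J_part))
    stop("dims do not match the kernel size")
  sgn <- switch(part, excitatory = 1, suppressive = -1,
                auto = if (sum(diag(J_part)) >= 0) 1 else -1)
  Jp <- sgn * J_part
  J_fro2 <- sum(Jp^2)
  if (J_fro2 == 0) stop("J_part is identically zero: nothing to fit")
  bd <- gabor_bounds(dims, quadrature, n_gabors, de$bounds)
  objective <- function(par) {
    gb <- decode_gabors(par, dims, quadrature)
    G <- vapply(seq_len(nrow(gb)), function(i) gabor_image(gb[i, ], dims),
                numeric(prod(dims)))
    gabor_weights_sse(G, Jp, J_fro2)$sse / J_fro2
  }
  np <- max(de$pop_factor * length(bd$lower), 7L)
  runs <- lapply(seq_len(de$restarts), function(r) {
    with_seed(de$seed + 1000L * (r - 1L),
              de_optimize(objective, bd$lower, bd$upper, np,
                          tau = de$tau, max_iter = de$max_iter))
  })
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "value"))]]
  gb <- decode_gabors(best$par, dims, quadrature)
  G <- vapply(seq_len(nrow(gb)), function(i) gabor_image(gb[i, ], dims),
              numeric(prod(dims)))
  ws <- gabor_weights_sse(G, Jp, J_fro2)
  gb$w <- sgn * ws$w
  J_fit <- G %*% (ws$w * t(G)) * sgn
  mse <- ws$sse / prod(dims)^2
  structure(list(gabors = gb, J_fit = J_fit, J_part = J_part,
                 dims = dims, quadrature = quadrature, part = sgn,
                 mse = mse, nmse = ws$sse / J_fro2,
                 correlation = stats::cor(as.vector(J_part), as.vector(J_fit)),
                 de = list(restart_values = vapply(runs, `[[`, numeric(1), "value"),
                           iterations = vapply(runs, `[[`, numeric(1), "iterations"),
                           converged = vapply(runs, `[[`, logical(1), "converged"),
                           config = de)),
            class = "gabor_fit")
}

#' @export
print.gabor_fit <- function(x, ...) {
  cat(sprintf("<gabor_fit> %d %s (%s part), normalized MSE %.4f, correlation %.3f\n",
              nrow(x$gabors), if (x$quadrature) "quadrature-pair members" else "Gabors",
              if (x$part > 0) "excitatory" else "suppressive",
              x$nmse, x$correlation))
  invisible(x)
}

#' @export
plot.gabor_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  graphics::image(x$J_part, axes = FALSE, main = "target kernel", ...)
  graphics::image(x$J_fit, axes = FALSE, main = "Gabor reconstruction", ...)
  invisible(x)
}

## ---- pairing and phase ---------------------------------------------------

## harmonic mean wavelength = wavelength of the mean spatial frequency
lam_bar <- function(l1, l2) 2 * l1 * l2 / (l1 + l2)

#' Pair Gabors with similar positions and orientations
#'
#' Greedy nearest-neighbour matching: a candidate pair must have center
#' distance below \code{max_dist} mean wavelengths and axial orientation
#' difference below \code{max_angle} degrees; candidates are accepted in
#' order of increasing combined dissimilarity (distance in units of the
#' mean wavelength plus orientation difference as a fraction of
#' \code{max_angle}), ties broken by larger combined |w|.  Each Gabor joins
#' at most one pair.
#'
#' @param gabors a \code{\link{gabor_set}}.
#' @param max_dist center-distance threshold in units of the pair's mean
#'   wavelength.
#' @param max_angle axial orientation threshold in degrees.
#' @return data.frame with one row per pair: indices \code{i}, \code{j},
#'   \code{delta_phase} (degrees, corrected for displacement), \code{dx},
#'   \code{dy}, \code{lam_bar}.
#' @export
pair_gabors <- function(gabors, max_dist = 1, max_angle = 30) {
  n <- nrow(gabors)
  if (n < 2) stop("need at least two Gabors to pair")
  cand <- NULL
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    lb <- lam_bar(gabors$lam[i], gabors$lam[j])
    dist <- sqrt((gabors$x0[i] - gabors$x0[j])^2 +
                   (gabors$y0[i] - gabors$y0[j])^2) / lb
    ang <- axial_diff_deg(gabors$theta[i] * 180 / pi,
                          gabors$theta[j] * 180 / pi)
    if (dist < max_dist && ang < max_angle) {
      cand <- rbind(cand, data.frame(
        i = i, j = j, score = dist + ang / max_angle,
        wsum = abs(gabors$w[i]) + abs(gabors$w[j]), lam_bar = lb))
    }
  }
  if (is.null(cand)) return(empty_pairs())
  cand <- cand[order(cand$score, -cand$wsum), ]
  used <- logical(n)
  out <- empty_pairs()
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]; j <- cand$j[r]
    if (used[i] || used[j]) next
    used[i] <- used[j] <- TRUE
    pr <- data.frame(i = i, j = j,
                     dx = gabors$x0[i] - gabors$x0[j],
                     dy = gabors$y0[i] - gabors$y0[j],
                     lam_bar = cand$lam_bar[r], delta_phase = NA_real_)
    pr$delta_phase <- phase_difference(pr, gabors)
    out <- rbind(out, pr)
  }
  out
}

empty_pairs <- function() {
  data.frame(i = integer(0), j = integer(0), dx = numeric(0),
             dy = numeric(0), lam_bar = numeric(0), delta_phase = numeric(0))
}

#' Displacement-corrected phase difference of a Gabor pair
#'
#' Raw phase difference corrected for the phase advance implied by the
#' center displacement along the carrier direction:
#' \code{wrap(phi_i - phi_j - (2 pi / lam_bar) (dx . n))} with \code{n} the
#' unit carrier direction at the pair's mean (axial) orientation and
#' \code{lam_bar} the harmonic mean wavelength (the wavelength of the mean
#' spatial frequency).
#'
#' @param pair one row as returned by \code{\link{pair_gabors}} (fields
#'   \code{i}, \code{j}, \code{dx}, \code{dy}, \code{lam_bar}).
#' @param gabors the \code{\link{gabor_set}} the indices refer to.
#' @return phase difference in degrees in [0, 180).
#' @export
phase_difference <- function(pair, gabors) {
  i <- pair$i; j <- pair$j
  th <- c(gabors$theta[i], gabors$theta[j])
  ph <- c(gabors$phi[i], gabors$phi[j])
  mth <- atan2(mean(sin(2 * th)), mean(cos(2 * th))) / 2  # axial mean
  ## express both carriers in the same half-plane: a Gabor with
  ## (theta + pi, phi) is the Gabor with (theta, -phi)
  for (k in 1:2) if (cos(th[k] - mth) < 0) ph[k] <- -ph[k]
  nhat <- c(cos(mth), sin(mth))
  shift <- 2 * pi / pair$lam_bar * (pair$dx * nhat[1] + pair$dy * nhat[2])
  d <- (ph[1] - ph[2] - shift) * 180 / pi
  d <- abs(wrap_deg(d))
  if (d >= 180) d <- 0
  d
}
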