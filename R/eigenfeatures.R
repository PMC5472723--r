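## Significant excitatory/suppressive features of the quadratic kernel J.
##
## Eigenvectors of the mean-subtracted J with positive eigenvalues are
## excitatory features, negative eigenvalues suppressive.  Significance is
## assessed against null distributions of the extreme eigenvalues of
## matrices whose diagonal and off-diagonal entries are shuffled separately
## (preserving symmetry), testing eigenvalues in order of decreasing
## magnitude and stopping at the first non-significant one.

#' Subtract the scalar mean of a symmetric matrix
#'
#' Removes the grand mean of all entries of J before the eigen-analysis, to
#' avoid the spurious extreme eigenvalue a nonzero mean induces.
#'
#' @param J symmetric matrix (asymmetric input is symmetrized with a warning).
#' @return zero-mean symmetric matrix.
#' @export
center_J <- function(J) {
  if (!is.matrix(J) || nrow(J) != ncol(J)) stop("J must be square")
  if (max(abs(J - t(J))) > 1e-8 * max(1, max(abs(J)))) {
    warning("asymmetric J symmetrized before centering")
    J <- (J + t(J)) / 2
  } else J <- (J + t(J)) / 2
  J - mean(J)
}

#' Null distribution of extreme eigenvalues by shuffling
#'
#' Each shuffle permutes the diagonal entries among diagonal slots and the
#' upper-triangle off-diagonal entries among off-diagonal slots (mirrored to
#' keep the matrix symmetric), and records the largest and smallest
#' eigenvalue.  The diagonal and off-diagonal multisets -- and hence the
#' trace -- are preserved by every shuffle.
#'
#' @param J_centered zero-mean symmetric matrix (see \code{\link{center_J}}).
#' @param n_shuffles number of shuffles (>= 100).
#' @param seed integer seed.
#' @param keep_matrices also return the shuffled matrices (small inputs
#'   only; used to verify the permutation invariants).
#' @return list with numeric vectors \code{max} and \code{min} of length
#'   \code{n_shuffles} (and \code{matrices} if requested).
#' @export
shuffle_null <- function(J_centered, n_shuffles = 1000L, seed = 1L,
                         keep_matrices = FALSE) {
  if (n_shuffles < 100L) stop("n_shuffles must be >= 100")
  P <- nrow(J_centered)
  dg <- diag(J_centered)
  ut <- upper.tri(J_centered)
  off <- J_centered[ut]
  with_seed(seed, {
    mx <- mn <- numeric(n_shuffles)
    mats <- if (keep_matrices) vector("list", n_shuffles)
    M <- matrix(0, P, P)
    for (i in seq_len(n_shuffles)) {
      M[ut] <- sample(off)
      M2 <- M + t(M)
      diag(M2) <- sample(dg)
      ev <- eigen(M2, symmetric = TRUE, only.values = TRUE)$values
      mx[i] <- ev[1]
      mn[i] <- ev[P]
      if (keep_matrices) mats[[i]] <- M2
    }
    out <- list(max = mx, min = mn)
    if (keep_matrices) out$matrices <- mats
    out
  })
}

#' Significant eigen-features of J
#'
#' After mean-subtraction, eigenvalues are tested in order of decreasing
#' magnitude: positive eigenvalues against the null distribution of shuffled
#' maxima, negative against the shuffled minima.  Testing stops at the first
#' eigenvalue whose tail probability is >= \code{alpha} (sequential rule; no
#' deflation of previously found components).  An empty result is valid.
#'
#' @param J symmetric quadratic kernel.
#' @param alpha significance level (default 0.05).
#' @param n_shuffles shuffles for the null (default 1000).
#' @param seed integer seed.
#' @return object of class \code{"eigen_features"}: \code{vectors} (P x m,
#'   unit-norm columns), \code{values}, \code{p_values}, \code{labels}
#'   ("excitatory"/"suppressive"), sorted by decreasing |eigenvalue|, plus
#'   \code{n_excitatory}, \code{n_suppressive} and the null distributions.
#' @export
significant_features <- function(J, alpha = 0.05, n_shuffles = 1000L,
                                 seed = 1L) {
  Jc <- center_J(J)
  P <- nrow(Jc)
  eg <- eigen(Jc, symmetric = TRUE)
  ord <- order(abs(eg$values), decreasing = TRUE)
  null <- shuffle_null(Jc, n_shuffles, seed)
  keep <- integer(0)
  pvals <- numeric(0)
  for (j in ord) {
    lam <- eg$values[j]
    p <- if (lam >= 0) (1 + sum(null$max >= lam)) / (n_shuffles + 1)
         else         (1 + sum(null$min <= lam)) / (n_shuffles + 1)
    if (p >= alpha) break
    keep <- c(keep, j)
    pvals <- c(pvals, p)
  }
  vals <- eg$values[keep]
  vecs <- eg$vectors[, keep, drop = FALSE]
  labels <- ifelse(vals >= 0, "excitatory", "suppressive")
  structure(list(vectors = vecs, values = vals, p_values = pvals,
                 labels = labels,
                 n_excitatory = sum(vals > 0),
                 n_suppressive = sum(vals < 0),
                 alpha = alpha, n_shuffles = as.integer(n_shuffles),
                 seed = seed, null = null, P = P),
            class = "eigen_features")
}

#' @export
print.eigen_features <- function(x, ...) {
  cat(sprintf("<eigen_features> %d significant (%d excitatory, %d suppressive) at alpha = %g\n",
              length(x$values), x$n_excitatory, x$n_suppressive, x$alpha))
  invisible(x)
}

#' Rebuild a kernel from selected eigen-features
#'
#' Sum of \eqn{\lambda_i v_i v_i'} over the selected features, e.g. the
#' excitatory-only kernel used to predict responses "without suppression".
#'
#' @param features an \code{\link{eigen_features}} object.
#' @param which \code{"all"}, \code{"excitatory"} or \code{"suppressive"}.
#' @return P x P symmetric matrix (zero matrix if no feature selected).
#' @export
reconstruct_J <- function(features, which = c("all", "excitatory", "suppressive")) {
  which <- match.arg(which)
  sel <- switch(which,
                all = seq_along(features$values),
                excitatory = which(features$labels == "excitatory"),
                suppressive = which(features$labels == "suppressive"))
  J <- matrix(0, features$P, features$P)
  for (i in sel) {
    v <- features$vectors[, i]
    J <- J + features$values[i] * tcrossprod(v)
  }
  J
}
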