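## Hartigan's dip statistic and a Monte-Carlo p-value against the uniform
## null.
##
## The dip of a sample is the smallest sup-norm distance between its
## empirical CDF and any unimodal CDF.  A unimodal CDF that stays within d
## of the empirical CDF must pass, at each order statistic x_(k), through
## the "box" [k/n - d, (k-1)/n + d] (clipped to [0, 1]); as a piecewise
## linear function with knots at the data it must be convex up to some peak
## segment and concave after.  Feasibility of a convex function through a
## sequence of boxes is a hull condition: the lower convex hull of the box
## tops must clear every box bottom.  The dip is located by bisection on d,
## checking at each d the longest convex-feasible prefix and the longest
## concave-feasible suffix.  An exact linear-programming formulation of the
## same minimization serves as the independent oracle in the test suite.

## longest prefix of boxes [lo_i, hi_i] at positions x (strictly increasing)
## admitting a convex function lo <= g <= hi; returns the prefix length
convex_feasible_prefix <- function(x, lo, hi) {
  n <- length(x)
  if (any(lo > hi)) n_ok_limit <- which(lo > hi)[1] - 1L else n_ok_limit <- n
  if (n_ok_limit < 1L) return(0L)
  hull <- c(1L)                 # indices of lower convex hull of (x, hi)
  best <- 1L
  for (k in 2:n_ok_limit) {
    ## maintain lower hull (increasing slopes)
    while (length(hull) >= 2L) {
      a <- hull[length(hull) - 1L]; b <- hull[length(hull)]
      if ((hi[k] - hi[b]) * (x[b] - x[a]) <= (hi[b] - hi[a]) * (x[k] - x[b]))
        hull <- hull[-length(hull)]
      else break
    }
    a <- hull[length(hull)]
    hull <- c(hull, k)
    ## hull changed on (x[a], x[k]): check box bottoms under the new edge
    ok <- TRUE
    if (k - a > 1L) {
      ii <- (a + 1L):(k - 1L)
      hv <- hi[a] + (hi[k] - hi[a]) * (x[ii] - x[a]) / (x[k] - x[a])
      if (any(hv < lo[ii] - 1e-12)) ok <- FALSE
    }
    if (!ok) return(best)
    best <- k
  }
  best
}

## dip of a sorted, deduplicated box system; bisection on d
dip_from_boxes <- function(x, lb, ub) {
  n <- length(x)
  if (n == 1L) return(0)
  feasible <- function(d) {
    lo <- pmax(lb - d, 0)
    hi <- pmin(ub + d, 1)
    if (any(lo > hi)) return(FALSE)
    kstar <- convex_feasible_prefix(x, lo, hi)
    if (kstar < 2L) return(FALSE)
    ## concave on k..n == convex on the mirrored axis
    m <- convex_feasible_prefix(-rev(x), rev(-hi), rev(-lo))
    kmin <- n - m + 1L
    kmin <= kstar - 1L
  }
  lo_d <- 0; hi_d <- 0.5
  for (it in 1:50) {
    mid <- (lo_d + hi_d) / 2
    if (feasible(mid)) hi_d <- mid else lo_d <- mid
  }
  hi_d
}

#' Hartigan's dip statistic with Monte-Carlo p-value
#'
#' The dip is the maximum distance between the empirical CDF and the
#' closest unimodal CDF.  The p-value is the Monte-Carlo tail probability
#' of the dip under samples of the same size from the uniform distribution
#' (null tables are cached per sample size within the session).
#'
#' @param values numeric sample (n >= 4).
#' @param n_null number of uniform null samples for the p-value.
#' @param seed integer seed for the null table.
#' @return list with \code{dip}, \code{p_value}, \code{n}, \code{n_null}.
#' @export
dip_statistic <- function(values, n_null = 500L, seed = 1L) {
  if (length(values) < 4) stop("need at least 4 values for the dip test")
  d <- dip_stat(values)
  n <- length(values)
  key <- sprintf("dipnull_%d_%d_%d", n, n_null, seed)
  null <- get0(key, envir = .qconv_cache)
  if (is.null(null)) {
    null <- with_seed(seed,
                      vapply(seq_len(n_null),
                             function(i) dip_stat(stats::runif(n)),
                             numeric(1)))
    assign(key, null, envir = .qconv_cache)
  }
  list(dip = d, p_value = (1 + sum(null >= d)) / (n_null + 1),
       n = n, n_null = as.integer(n_null))
}

## dip statistic of a raw sample.  Tied observations are separated by an
## infinitesimal jitter: a unimodal CDF may carry an atom at its mode, and
## the dip with atoms allowed is the zero-jitter limit of the
## distinct-point dip.
dip_stat <- function(values) {
  x <- sort(values)
  n <- length(x)
  if (anyDuplicated(x)) {
    gaps <- diff(x)
    eps <- if (any(gaps > 0)) min(gaps[gaps > 0]) * 1e-9 else 1
    x <- x + (seq_len(n) - 1) * (eps / n)
  }
  lb <- seq_len(n) / n          # g(x_k) >= k/n - d
  ub <- (seq_len(n) - 1) / n    # g(x_k) <= (k-1)/n + d
  dip_from_boxes(x, lb, ub)
}
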