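## Stimulus movies, patch geometry and lagged patch extraction.
##
## Conventions (fixed throughout the package):
##  * pixels are indexed 0-based, row-major; a patch is labelled by the
##    0-based (row, col) offset of its top-left corner;
##  * lag l means the patch taken from frame t - l, l = 0..n_lags-1, so the
##    response at t depends on present and past frames only;
##  * the canonical ordering of the (position, lag) pooling axis is lag-major:
##    index k = l * Gy*Gx + (row-major grid position), and this is the order
##    of the pooling weights v2;
##  * patch vectors are the patch pixels read row-major.

#' Stimulus movie
#'
#' Container for a grayscale stimulus movie of T frames of H x W pixels.
#' Intensities are mean-centered per movie on construction (no variance
#' normalization): the model biases absorb offsets and the quadratic kernel
#' stays interpretable.
#'
#' @param frames numeric array with dim c(T, H, W); all values finite.
#' @param bin_ms positive duration of one frame bin in milliseconds.
#' @param center mean-center the movie (default TRUE).
#' @return an object of class \code{"stimulus_movie"} with elements
#'   \code{frames} and \code{bin_ms}.
#' @export
stimulus_movie <- function(frames, bin_ms = 16, center = TRUE) {
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("`frames` must be a T x H x W array")
  if (!all(is.finite(frames)))
    stop("stimulus contains non-finite values")
  if (!is.numeric(bin_ms) || length(bin_ms) != 1L || bin_ms <= 0)
    stop("`bin_ms` must be a positive scalar")
  if (center) frames <- frames - mean(frames)
  structure(list(frames = frames, bin_ms = as.numeric(bin_ms)),
            class = "stimulus_movie")
}

#' @export
dim.stimulus_movie <- function(x) dim(x$frames)

#' @export
print.stimulus_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<stimulus_movie> %d frames of %d x %d px, %g ms bins\n",
              d[1], d[2], d[3], x$bin_ms))
  invisible(x)
}

#' Patch configuration
#'
#' Geometry of the convolutional patch grid: single-frame patches of
#' \code{patch_h} x \code{patch_w} pixels anchored every \code{stride}
#' pixels, replicated over \code{n_lags} latencies.
#'
#' @param patch_h,patch_w patch size in pixels.
#' @param stride grid stride in pixels.
#' @param n_lags number of latencies (>= 1).
#' @return an object of class \code{"patch_config"}.
#' @export
patch_config <- function(patch_h, patch_w = patch_h, stride = 1L, n_lags = 1L) {
  patch_h <- as.integer(patch_h); patch_w <- as.integer(patch_w)
  stride <- as.integer(stride); n_lags <- as.integer(n_lags)
  if (patch_h < 1L || patch_w < 1L) stop("patch size must be positive")
  if (stride < 1L) stop("stride must be positive")
  if (n_lags < 1L) stop("n_lags must be >= 1")
  structure(list(patch_h = patch_h, patch_w = patch_w,
                 stride = stride, n_lags = n_lags),
            class = "patch_config")
}

#' @export
print.patch_config <- function(x, ...) {
  cat(sprintf("<patch_config> %d x %d px patches, stride %d, %d lags\n",
              x$patch_h, x$patch_w, x$stride, x$n_lags))
  invisible(x)
}

## grid extent per axis: floor((H - patch)/stride) + 1
grid_dims <- function(frame_dims, cfg) {
  H <- frame_dims[1]; W <- frame_dims[2]
  if (cfg$patch_h > H || cfg$patch_w > W)
    stop(sprintf("patch (%d x %d) larger than frame (%d x %d)",
                 cfg$patch_h, cfg$patch_w, H, W))
  c(gy = (H - cfg$patch_h) %/% cfg$stride + 1L,
    gx = (W - cfg$patch_w) %/% cfg$stride + 1L)
}

#' Patch vector length
#'
#' Length of the flattened patch vector, i.e. the dimension of the linear
#' filter v1 and the side of the quadratic kernel J.
#'
#' @param cfg a \code{\link{patch_config}}.
#' @return integer \code{patch_h * patch_w}.
#' @examples
#' patch_vector_length(patch_config(16))  # 256
#' @export
patch_vector_length <- function(cfg) {
  stopifnot(inherits(cfg, "patch_config"))
  cfg$patch_h * cfg$patch_w
}

#' Pooling vector length
#'
#' Length of the pooling weight vector v2: grid positions per frame times
#' the number of latencies.  With 20 x 20 frames, 16 x 16 patches, stride 1
#' and 10 lags this is 5 x 5 x 10 = 250.
#'
#' @param frame_dims either a \code{\link{stimulus_movie}} or an H, W pair.
#' @param cfg a \code{\link{patch_config}}.
#' @return integer Gy * Gx * n_lags.
#' @export
pooling_vector_length <- function(frame_dims, cfg) {
  if (inherits(frame_dims, "stimulus_movie")) frame_dims <- dim(frame_dims)[2:3]
  g <- grid_dims(frame_dims, cfg)
  as.integer(g["gy"]) * as.integer(g["gx"]) * cfg$n_lags
}

## 0-based top-left offsets of the grid, row-major over (row, col)
grid_offsets <- function(frame_dims, cfg) {
  g <- grid_dims(frame_dims, cfg)
  rows <- (seq_len(g["gy"]) - 1L) * cfg$stride
  cols <- (seq_len(g["gx"]) - 1L) * cfg$stride
  ## row-major: row varies slowest? canonical row-major reading order:
  ## position index p = r * gx + c  (r slow, c fast)
  data.frame(row = rep(rows, each = length(cols)),
             col = rep(cols, times = length(rows)))
}

## flatten an H x W patch matrix row-major into a vector
flatten_rowmajor <- function(m) as.vector(t(m))

#' Extract lagged patches for one frame
#'
#' Returns every patch feeding the model's response at frame \code{t}: one
#' flattened patch vector per (grid position, lag), in the canonical
#' lag-major order (lag varies slowest; within a lag, grid positions in
#' row-major order).  This order is the order of the pooling weights v2.
#'
#' @param movie a \code{\link{stimulus_movie}}.
#' @param cfg a \code{\link{patch_config}}.
#' @param t 1-based frame index; must satisfy \code{t >= n_lags} so that the
#'   full lag history exists.
#' @param positions optional data.frame of 0-based top-left offsets
#'   (columns \code{row}, \code{col}) overriding the full grid.
#' @return a numeric matrix with \code{Gy*Gx*n_lags} rows (canonical order)
#'   and \code{patch_h*patch_w} columns; attributes \code{positions} and
#'   \code{lags} record the layout.
#' @export
extract_patches <- function(movie, cfg, t, positions = NULL) {
  stopifnot(inherits(movie, "stimulus_movie"), inherits(cfg, "patch_config"))
  d <- dim(movie$frames)
  if (t < cfg$n_lags || t > d[1])
    stop(sprintf("frame index t=%d out of range [%d, %d]", t, cfg$n_lags, d[1]))
  if (is.null(positions)) positions <- grid_offsets(d[2:3], cfg)
  P <- cfg$patch_h * cfg$patch_w
  K <- nrow(positions) * cfg$n_lags
  out <- matrix(0, K, P)
  k <- 0L
  for (lag in 0:(cfg$n_lags - 1L)) {
    fr <- movie$frames[t - lag, , ]
    for (p in seq_len(nrow(positions))) {
      r0 <- positions$row[p]; c0 <- positions$col[p]
      k <- k + 1L
      out[k, ] <- flatten_rowmajor(
        fr[(r0 + 1L):(r0 + cfg$patch_h), (c0 + 1L):(c0 + cfg$patch_w)])
    }
  }
  attr(out, "positions") <- positions
  attr(out, "lags") <- 0:(cfg$n_lags - 1L)
  out
}

## Precomputed design for all usable frames: a list of K matrices, each
## N x P, where N = T - (n_lags - 1) and row t corresponds to stimulus frame
## t + n_lags - 1.  Component k follows the canonical (lag-major) order.
## Frames without full lag history are dropped (no zero padding).
patch_design <- function(movie, cfg, positions = NULL) {
  d <- dim(movie$frames)
  if (is.null(positions)) positions <- grid_offsets(d[2:3], cfg)
  L <- cfg$n_lags
  if (d[1] < L) stop("movie shorter than n_lags")
  N <- d[1] - (L - 1L)
  P <- cfg$patch_h * cfg$patch_w
  tidx <- L:d[1]
  X <- vector("list", nrow(positions) * L)
  k <- 0L
  for (lag in 0:(L - 1L)) {
    for (p in seq_len(nrow(positions))) {
      r0 <- positions$row[p]; c0 <- positions$col[p]
      sl <- movie$frames[tidx - lag,
                         (r0 + 1L):(r0 + cfg$patch_h),
                         (c0 + 1L):(c0 + cfg$patch_w), drop = FALSE]
      ## row-major pixel order: (row, col) with col fastest
      k <- k + 1L
      X[[k]] <- matrix(aperm(sl, c(1, 3, 2)), N, P)
    }
  }
  list(X = X, N = N, P = P, K = length(X),
       positions = positions, n_lags = L, t_first = L)
}

## single centered position used when the model is non-convolutional
center_position <- function(frame_dims, cfg) {
  data.frame(row = (frame_dims[1] - cfg$patch_h) %/% 2L,
             col = (frame_dims[2] - cfg$patch_w) %/% 2L)
}
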