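#' Spatio-temporal spike-triggered average
#'
#' `STA[d, l] = sum_t Y_t raw[t - l, d] / sum_t Y_t`, with zero padding for
#' lags reaching before the first frame. Lag 1 of the result is the frame in
#' the spike bin itself (lag 0), lag 2 the preceding frame, and so on.
#'
#' @param raw T x D matrix of raw stimulus frames.
#' @param Y spike counts aligned to `raw`.
#' @param L number of lag bins (default 15, i.e. 125 ms at 120 Hz).
#' @param lag_bin lag bin width in seconds.
#' @return An object of class `sta` with fields `values` (D x L), `lag_bin`.
#' @export
compute_sta <- function(raw, Y, L = 15, lag_bin = 1 / 120) {
  raw <- as_frames(raw)
  Yc <- as_counts(Y)
  check_aligned(raw, Yc)
  tot <- sum(Yc)
  if (tot <= 0) stop("cannot compute an STA with zero total spikes")
  Tn <- nrow(raw); D <- ncol(raw)
  vals <- matrix(0, D, L)
  spk <- which(Yc > 0)
  for (l in seq_len(L)) {
    idx <- spk - (l - 1)
    ok <- idx >= 1
    if (any(ok))
      vals[, l] <- colSums(raw[idx[ok], , drop = FALSE] * Yc[spk[ok]]) / tot
  }
  structure(list(values = vals, lag_bin = lag_bin), class = "sta")
}

#' @export
print.sta <- function(x, ...) {
  cat(sprintf("<sta> %d pixels x %d lags (%.0f ms span)\n", nrow(x$values),
              ncol(x$values), 1000 * ncol(x$values) * x$lag_bin))
  invisible(x)
}

# label 4- (or 8-) connected components of a logical image; 0 = background
connected_components <- function(mask_img, connectivity = 4) {
  nr <- nrow(mask_img); nc <- ncol(mask_img)
  labels <- matrix(0L, nr, nc)
  nbr <- if (connectivity == 4) {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  } else {
    cbind(rep(-1:1, 3), rep(-1:1, each = 3))[-5, ]
  }
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask_img[i, j] || labels[i, j] > 0L) next
    cur <- cur + 1L
    stack <- list(c(i, j))
    labels[i, j] <- cur
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(nbr))) {
        ii <- p[1] + nbr[k, 1]; jj <- p[2] + nbr[k, 2]
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
            mask_img[ii, jj] && labels[ii, jj] == 0L) {
          labels[ii, jj] <- cur
          stack[[length(stack) + 1L]] <- c(ii, jj)
        }
      }
    }
  }
  labels
}

#' Receptive-field mask from a spatial STA map
#'
#' Estimates the background noise level robustly (median absolute deviation,
#' scaled to the Gaussian standard deviation) and keeps the largest
#' connected component of pixels whose magnitude exceeds `k` times that
#' level. The crop window is the component's bounding rectangle padded by a
#' one-pixel border (clipped at the stimulus edge).
#'
#' @param sta_spatial numeric vector of length `prod(grid_shape)`, or matrix.
#' @param grid_shape integer `c(rows, cols)`; inferred when a matrix is given.
#' @param k threshold in robust-sigma units (default 2.5).
#' @param connectivity 4 (default) or 8.
#' @return A list with `mask` (logical, full grid), `crop` (list with
#'   `rows`, `cols` index ranges), `sigma` (robust noise sd).
#' @export
receptive_field_mask <- function(sta_spatial, grid_shape = NULL, k = 2.5,
                                 connectivity = 4) {
  if (k <= 0) stop("k must be > 0")
  if (is.matrix(sta_spatial)) {
    img <- sta_spatial
  } else {
    if (is.null(grid_shape)) stop("grid_shape required for a vector input")
    img <- matrix(sta_spatial, grid_shape[1], grid_shape[2])
  }
  sigma <- stats::mad(as.vector(img), center = 0)
  thr <- abs(img) > k * sigma
  if (!any(thr)) stop("no receptive field: no pixel exceeds the threshold")
  labels <- connected_components(thr, connectivity)
  sizes <- tabulate(labels[labels > 0L])
  best <- which.max(sizes)
  mask <- labels == best
  ridx <- range(which(rowSums(mask) > 0))
  cidx <- range(which(colSums(mask) > 0))
  crop <- list(rows = max(1, ridx[1] - 1):min(nrow(img), ridx[2] + 1),
               cols = max(1, cidx[1] - 1):min(ncol(img), cidx[2] + 1))
  list(mask = mask, crop = crop, sigma = sigma)
}

#' Common temporal filter from an STA
#'
#' Averages the temporal traces of masked (significant) pixels after
#' aligning each trace's sign by the sign of its own largest-magnitude
#' sample, and normalizes the result to unit L2 norm. Sign alignment makes
#' pixels of opposite polarity contribute coherently.
#'
#' @param sta an object from [compute_sta()].
#' @param mask logical vector (length D) or matrix selecting pixels.
#' @return Numeric length-L filter with unit norm, lag 0 first.
#' @export
time_course <- function(sta, mask) {
  sel <- which(as.vector(mask))
  if (length(sel) == 0) stop("mask selects no pixels")
  traces <- sta$values[sel, , drop = FALSE]
  signs <- apply(traces, 1, function(v) sign(v[which.max(abs(v))]))
  signs[signs == 0] <- 1
  tc <- colMeans(traces * signs)
  nrm <- sqrt(sum(tc^2))
  if (nrm == 0) stop("degenerate time course (all-zero traces)")
  tc / nrm
}

#' Temporally prefilter and standardize a raw stimulus
#'
#' Convolves each pixel's intensity sequence with the shared time course
#' (`X_t[d] = sum_l tc[l] raw[t-l, d]`, zero-padded at the start) and then
#' centers and scales each column to unit variance, producing the
#' approximately standard-normal stimulus the estimator assumes.
#'
#' @param raw T x D raw frames.
#' @param tc temporal filter (lag 0 first).
#' @param bin_width seconds per bin.
#' @param grid_shape optional `c(rows, cols)` carried into the result.
#' @return A [stimulus_matrix()].
#' @export
prefilter_and_standardize <- function(raw, tc, bin_width = 1 / 120,
                                      grid_shape = NULL) {
  raw <- as_frames(raw)
  L <- length(tc)
  if (L > nrow(raw)) stop("filter longer than the stimulus")
  Tn <- nrow(raw)
  X <- matrix(0, Tn, ncol(raw))
  for (l in seq_len(L)) {
    if (tc[l] == 0) next
    src <- seq_len(Tn - l + 1)
    X[src + l - 1, ] <- X[src + l - 1, ] + tc[l] * raw[src, ]
  }
  sdv <- apply(X, 2, stats::sd)
  if (any(sdv == 0)) stop("zero-variance stimulus column after prefiltering")
  X <- scale(X, center = TRUE, scale = sdv)
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  stimulus_matrix(X, bin_width = bin_width, grid_shape = grid_shape,
                  check_standardized = FALSE)
}

#' Space-time separable approximation of an STA
#'
#' Best rank-1 factorization (leading singular vectors) of the D x L STA in
#' the least-squares sense. The sign convention puts the polarity into the
#' spatial factor: the temporal factor is flipped so that the dominant
#' pixel's spatial weight carries the map's sign (positive peak for ON-type
#' maps, negative for OFF-type).
#'
#' @param sta an `sta` object or bare D x L matrix.
#' @return List with `spatial` (length D), `temporal` (length L, unit norm),
#'   and `sv` (all singular values). `spatial %o% temporal` is the rank-1
#'   approximation.
#' @export
separable_approx <- function(sta) {
  M <- if (inherits(sta, "sta")) sta$values else as.matrix(sta)
  sv <- svd(M)
  spatial <- sv$u[, 1] * sv$d[1]
  temporal <- sv$v[, 1]
  dom <- which.max(abs(spatial))
  map_sign <- sign(M[dom, which.max(abs(M[dom, ]))])
  if (map_sign != 0 && sign(spatial[dom]) != map_sign) {
    spatial <- -spatial
    temporal <- -temporal
  }
  list(spatial = spatial, temporal = temporal, sv = sv$d)
}
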