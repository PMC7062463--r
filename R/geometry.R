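#' Two-dimensional Gaussian fit to a subunit image
#'
#' Least-squares fit of `amp * exp(-(p - mu)' Sigma^{-1} (p - mu) / 2)` to
#' the subunit filter after normalizing by its maximum absolute weight
#' (sign-flipped so the peak is positive). The covariance is parameterized
#' by log standard deviations and an atanh correlation, keeping it
#' symmetric positive definite. Returns the mean-squared error of the fit,
#' the locality statistic used to compare estimated and permuted subunits.
#'
#' @param img subunit image: matrix, or vector with `grid_shape`.
#' @param grid_shape `c(rows, cols)` when `img` is a vector.
#' @return An object of class `gaussian2d_fit`: `center` (x = column,
#'   y = row, in pixel units), `cov` (2 x 2 SPD), `amplitude`, `mse`,
#'   `flagged` (TRUE for degenerate images or optimizer failure).
#' @export
gaussian2d_fit <- function(img, grid_shape = NULL) {
  if (!is.matrix(img)) {
    if (is.null(grid_shape)) stop("grid_shape required for a vector input")
    img <- matrix(img, grid_shape[1], grid_shape[2])
  }
  peak <- max(abs(img))
  if (peak == 0)
    return(structure(list(center = c(NA, NA), cov = diag(2), amplitude = NA,
                          mse = NA_real_, flagged = TRUE),
                     class = "gaussian2d_fit"))
  z <- img / peak * sign(img[which.max(abs(img))])
  nr <- nrow(img); nc <- ncol(img)
  px <- rep(seq_len(nc), each = nr)    # x = column index
  py <- rep(seq_len(nr), nc)           # y = row index
  zv <- as.vector(z)
  # moment initialization from the positive part
  zp <- pmax(zv, 0)
  if (sum(zp) == 0) zp <- abs(zv)
  mx <- sum(px * zp) / sum(zp); my <- sum(py * zp) / sum(zp)
  vx <- max(sum((px - mx)^2 * zp) / sum(zp), 0.25)
  vy <- max(sum((py - my)^2 * zp) / sum(zp), 0.25)
  th0 <- c(mx, my, log(sqrt(vx)), log(sqrt(vy)), 0, 0)  # last: log amp
  obj <- function(th) {
    sx <- exp(th[3]); sy <- exp(th[4]); rho <- tanh(th[5]); amp <- exp(th[6])
    dx <- (px - th[1]) / sx; dy <- (py - th[2]) / sy
    q <- (dx^2 - 2 * rho * dx * dy + dy^2) / (1 - rho^2)
    mean((amp * exp(-q / 2) - zv)^2)
  }
  opt <- tryCatch(stats::optim(th0, obj, method = "BFGS",
                               control = list(maxit = 500, reltol = 1e-12)),
                  error = function(e) NULL)
  flagged <- is.null(opt)
  if (flagged) opt <- list(par = th0, value = obj(th0))
  th <- opt$par
  sx <- exp(th[3]); sy <- exp(th[4]); rho <- tanh(th[5])
  cov <- matrix(c(sx^2, rho * sx * sy, rho * sx * sy, sy^2), 2, 2)
  structure(list(center = c(x = th[1], y = th[2]), cov = cov,
                 amplitude = exp(th[6]), mse = opt$value, flagged = flagged),
            class = "gaussian2d_fit")
}

#' @export
print.gaussian2d_fit <- function(x, ...) {
  cat(sprintf("<gaussian2d_fit> center (%.2f, %.2f), sds (%.2f, %.2f), MSE %.3g%s\n",
              x$center[1], x$center[2], sqrt(x$cov[1, 1]), sqrt(x$cov[2, 2]),
              x$mse, if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

#' Permutation control for subunit spatial locality
#'
#' Shuffles, pixel by pixel, the filter values across the subunits of one
#' cell (each pixel keeps its location but the subunit identities are
#' permuted), refits 2-D Gaussians to every permuted subunit, and compares
#' the real subunits' Gaussian-fit MSEs against this null distribution.
#' Under the null, the quantiles of the real MSEs are uniform on (0, 1);
#' spatially compact estimated subunits concentrate near zero.
#'
#' @param K N x D subunit filters of one cell (or a [subunit_bank()]).
#' @param grid_shape pixel grid.
#' @param n_perm number of pixelwise permutations (> 0).
#' @param seed optional integer seed.
#' @return List with `null_mse` (n_perm x N matrix), `real_mse` (length N),
#'   `quantiles` (fraction of null MSEs below each real MSE), `degenerate`
#'   (TRUE when all subunits are identical, making the control
#'   uninformative).
#' @export
permutation_control <- function(K, grid_shape, n_perm = 100, seed = NULL) {
  if (n_perm <= 0) stop("n_perm must be positive")
  if (inherits(K, "subunit_bank")) K <- K$K
  N <- nrow(K)
  if (N < 2) stop("permutation control needs at least two subunits")
  D <- ncol(K)
  real <- vapply(seq_len(N), function(n)
    gaussian2d_fit(K[n, ], grid_shape)$mse, numeric(1))
  degenerate <- all(apply(K, 2, function(col) max(col) - min(col) == 0))
  null_mse <- with_seed(seed, {
    out <- matrix(NA_real_, n_perm, N)
    for (p in seq_len(n_perm)) {
      Kp <- apply(K, 2, sample)      # N x D with per-pixel shuffled identity
      out[p, ] <- vapply(seq_len(N), function(n)
        gaussian2d_fit(Kp[n, ], grid_shape)$mse, numeric(1))
    }
    out
  })
  q <- vapply(seq_len(N), function(n) mean(null_mse[, n] < real[n]), numeric(1))
  list(null_mse = null_mse, real_mse = real, quantiles = q,
       degenerate = degenerate)
}

#' Normalized nearest-neighbor subunit distances (tiling statistic)
#'
#' For each subunit, the distance to its nearest neighbor divided by the
#' geometric mean of the two Gaussian fits' standard deviations along the
#' center-joining direction (`sd along u = sqrt(u' Sigma u)`). Values
#' around 1.5 indicate tiling with minimal gaps and modest overlap.
#'
#' @param fits list of [gaussian2d_fit()] results for one cell (>= 2).
#' @return Numeric vector of normalized distances, one per subunit.
#' @export
tiling_statistic <- function(fits) {
  M <- length(fits)
  if (M < 2) stop("need at least two Gaussian fits")
  out <- numeric(M)
  for (i in seq_len(M)) {
    best <- Inf
    for (j in seq_len(M)) {
      if (j == i) next
      d <- fits[[j]]$center - fits[[i]]$center
      L <- sqrt(sum(d^2))
      u <- if (L > 0) d / L else c(1, 0)
      s1 <- sqrt(drop(t(u) %*% fits[[i]]$cov %*% u))
      s2 <- sqrt(drop(t(u) %*% fits[[j]]$cov %*% u))
      best <- min(best, L / sqrt(s1 * s2))
    }
    out[i] <- best
  }
  out
}
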