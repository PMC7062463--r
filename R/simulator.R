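#' Jittered hexagonal cone mosaic
#'
#' Cone positions on a hexagonal lattice (alternate rows offset by half the
#' spacing, row pitch `spacing * sqrt(3)/2`), rotated relative to the
#' stimulus grid, with independent radially symmetric Gaussian positional
#' jitter, and centered on the origin. Units are grid units (g.u.), 1 g.u.
#' corresponding to 1 micron in the biologically scaled simulation.
#'
#' @param n number of cones (must be `rows^2` of the square hex patch;
#'   default 64 = 8 x 8).
#' @param spacing nearest-neighbor distance in g.u. (default 5).
#' @param angle lattice rotation relative to the stimulus grid, degrees
#'   (default 60).
#' @param jitter_sd jitter standard deviation in g.u. (default 0.35).
#' @param seed optional integer seed.
#' @return An object of class `cone_mosaic`: list with `positions` (n x 2),
#'   `spacing`, `jitter_sd`, `angle`.
#' @export
make_mosaic <- function(n = 64, spacing = 5, angle = 60, jitter_sd = 0.35,
                        seed = NULL) {
  side <- round(sqrt(n))
  if (side^2 != n) stop("n must be a square number (hexagonal patch of side sqrt(n))")
  ix <- rep(seq_len(side), side)
  iy <- rep(seq_len(side), each = side)
  x <- (ix - 1) * spacing + ifelse(iy %% 2 == 0, spacing / 2, 0)
  y <- (iy - 1) * spacing * sqrt(3) / 2
  P <- cbind(x - mean(x), y - mean(y))
  th <- angle * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  P <- P %*% t(R)
  P <- P + with_seed(seed, matrix(stats::rnorm(2 * n, 0, jitter_sd), n, 2))
  structure(list(positions = P, spacing = spacing, jitter_sd = jitter_sd,
                 angle = angle),
            class = "cone_mosaic")
}

#' @export
print.cone_mosaic <- function(x, ...) {
  cat(sprintf("<cone_mosaic> %d cones, spacing %.3g g.u., jitter sd %.3g g.u.\n",
              nrow(x$positions), x$spacing, x$jitter_sd))
  invisible(x)
}

#' Partition cones into bipolar-cell pools
#'
#' k-means clustering of cone positions (multiple restarts, best inertia
#' kept); each cluster is the cone pool of one model bipolar cell.
#'
#' @param mosaic a [cone_mosaic()].
#' @param k number of bipolar cells (default 12).
#' @param nstart k-means restarts.
#' @param seed optional integer seed.
#' @return Integer vector assigning each cone to a bipolar (1..k).
#' @export
assign_bipolars <- function(mosaic, k = 12, nstart = 20, seed = NULL) {
  if (k > nrow(mosaic$positions)) stop("k must not exceed the number of cones")
  if (k == nrow(mosaic$positions)) return(seq_len(k))   # singleton clusters
  km <- with_seed(seed, stats::kmeans(mosaic$positions, centers = k,
                                      nstart = nstart, iter.max = 100))
  if (any(tabulate(km$cluster, k) == 0)) stop("empty bipolar cluster after restarts")
  km$cluster
}

# biphasic temporal kernel (difference of gamma densities), unit norm,
# lag 0 first; peak near 50 ms, trough near 80 ms at 120 Hz
cone_time_course <- function(L = 15, bin_width = 1 / 120,
                             t_peak = 0.05, t_trough = 0.08, trough_frac = 0.45) {
  tt <- (seq_len(L) - 1) * bin_width
  g <- function(t, tp, p = 5) (t / tp)^p * exp(-p * (t / tp - 1))
  tc <- g(tt, t_peak) - trough_frac * g(tt, t_trough, p = 7)
  tc / sqrt(sum(tc^2))
}

# square stimulus pixel grid covering the mosaic extent plus a margin
make_pixel_grid <- function(mosaic, pixel_gu = 6, margin = 3) {
  ext <- max(abs(mosaic$positions)) + margin * pixel_gu
  half <- ceiling(ext / pixel_gu)
  centers <- (seq_len(2 * half) - half - 0.5) * pixel_gu
  list(x = centers, y = centers, pixel_gu = pixel_gu,
       grid_shape = c(length(centers), length(centers)))
}

# D x n_cones matrix: Gaussian pooling weight of each cone over each pixel,
# computed as the exact separable integral of the cone's Gaussian profile
# over the pixel area (each cone's weights sum to ~1 across the grid)
cone_pooling_matrix <- function(mosaic, grid, pool_sd = 1) {
  h <- grid$pixel_gu / 2
  px <- rep(grid$x, times = length(grid$y))   # column-major: rows = x index
  py <- rep(grid$y, each = length(grid$x))
  P <- mosaic$positions
  M <- matrix(0, length(px), nrow(P))
  for (i in seq_len(nrow(P))) {
    wx <- stats::pnorm(px + h, P[i, 1], pool_sd) -
      stats::pnorm(px - h, P[i, 1], pool_sd)
    wy <- stats::pnorm(py + h, P[i, 2], pool_sd) -
      stats::pnorm(py - h, P[i, 2], pool_sd)
    M[, i] <- wx * wy
  }
  M
}

#' Ground-truth simulated retinal ganglion cell
#'
#' Builds the two-layer cascade: cones on a jittered hexagonal mosaic pool
#' the stimulus with a Gaussian spatial profile (sd 1 g.u.) and a shared
#' biphasic temporal filter; cones are partitioned into bipolar pools by
#' k-means; each bipolar exponentiates its summed (gain-scaled) cone drive;
#' the cell's rate is the positively weighted sum of bipolar outputs times
#' a global gain calibrated to the target mean firing rate. The true
#' subunit filters on the stimulus pixel grid (one per bipolar) are
#' exported for recovery tests.
#'
#' @param n_cones,spacing,jitter_sd,angle mosaic parameters
#'   (see [make_mosaic()]).
#' @param n_bipolar number of bipolar cells (default 12).
#' @param pixel_gu stimulus pixel size in g.u. (default 6; the receptive
#'   field then spans roughly 6 x 6 pixels).
#' @param pool_sd cone Gaussian pooling sd in g.u.
#' @param input_gain scale on the summed cone drive inside each bipolar
#'   exponential; the default gives bipolar log-drive fluctuations of order
#'   one under default-contrast binary noise.
#' @param weight_cv bipolar weight coefficient of variation (weights drawn
#'   from a truncated-positive normal with mean 1, sd `weight_cv`).
#' @param L,bin_width temporal filter length (bins) and bin width (s).
#' @param seed integer seed for the mosaic, partition and weights.
#' @return An object of class `rgc_cell` with fields `mosaic`, `bipolar`
#'   (cone assignment), `weights`, `grid`, `pooling` (D x cones),
#'   `true_subunits` (n_bipolar x D filters), `time_course`, `input_gain`,
#'   `bin_width`. The global `gain` is `NA` until calibrated by
#'   [simulate_cell()].
#' @export
rgc_cell <- function(n_cones = 64, spacing = 5, jitter_sd = 0.35, angle = 60,
                     n_bipolar = 12, pixel_gu = 6, pool_sd = 1,
                     input_gain = 1.5, weight_cv = 0.1, L = 15,
                     bin_width = 1 / 120, seed = NULL) {
  mosaic <- make_mosaic(n_cones, spacing, angle, jitter_sd,
                        seed = child_seed(seed, 1))
  bip <- assign_bipolars(mosaic, n_bipolar, seed = child_seed(seed, 2))
  w <- with_seed(child_seed(seed, 3), {
    repeat {
      w0 <- stats::rnorm(n_bipolar, 1, weight_cv)
      if (all(w0 > 0)) break
    }
    w0
  })
  grid <- make_pixel_grid(mosaic, pixel_gu)
  pool <- cone_pooling_matrix(mosaic, grid, pool_sd)
  Ktrue <- t(vapply(seq_len(n_bipolar), function(b)
    input_gain * rowSums(pool[, bip == b, drop = FALSE]),
    numeric(nrow(pool))))
  structure(list(mosaic = mosaic, bipolar = bip, weights = w, grid = grid,
                 pooling = pool, true_subunits = Ktrue,
                 time_course = cone_time_course(L, bin_width),
                 input_gain = input_gain, bin_width = bin_width,
                 gain = NA_real_, seed = seed),
            class = "rgc_cell")
}

#' @export
print.rgc_cell <- function(x, ...) {
  cat(sprintf("<rgc_cell> %d cones -> %d bipolars, %dx%d pixel grid (%.3g g.u. pixels)\n",
              nrow(x$mosaic$positions), length(x$weights),
              x$grid$grid_shape[1], x$grid$grid_shape[2], x$grid$pixel_gu))
  invisible(x)
}

# pre-Poisson rate of the cascade on raw frames, for a given global gain
rgc_rate <- function(cell, raw, gain) {
  filt <- prefilter_raw(raw, cell$time_course)        # T x D temporally filtered
  drive <- filt %*% t(cell$true_subunits)             # T x n_bipolar
  gain * drop(exp(drive) %*% cell$weights)
}

# temporal convolution without standardization (shared by rate computation)
prefilter_raw <- function(raw, tc) {
  raw <- as_frames(raw)
  Tn <- nrow(raw)
  X <- matrix(0, Tn, ncol(raw))
  for (l in seq_along(tc)) {
    if (tc[l] == 0) next
    src <- seq_len(Tn - l + 1)
    X[src + l - 1, ] <- X[src + l - 1, ] + tc[l] * raw[src, ]
  }
  X
}

#' Simulate spiking responses of a ground-truth RGC
#'
#' Runs the cascade on raw stimulus frames and draws Poisson spikes. If the
#' cell's global gain is uncalibrated (`NA`), it is set so the mean rate on
#' a calibration white-noise run equals `target_rate` (19 spikes/s by
#' default); the calibrated cell is returned alongside the response.
#'
#' @param cell an [rgc_cell()].
#' @param raw T x D raw stimulus frames on the cell's pixel grid.
#' @param target_rate mean firing rate (spikes/s) used for calibration.
#' @param calibration_frames length of the internal calibration run.
#' @param contrast calibration stimulus contrast.
#' @param seed integer seed (spike generation and calibration stimulus).
#' @return List with `rates` (expected counts per bin), `spikes`
#'   (a [spike_counts()]), and `cell` (with calibrated `gain`).
#' @export
simulate_cell <- function(cell, raw, target_rate = 19,
                          calibration_frames = 30000, contrast = 0.48,
                          seed = NULL) {
  raw <- as_frames(raw)
  if (ncol(raw) != nrow(cell$pooling))
    stop("stimulus does not match the cell's pixel grid")
  if (is.na(cell$gain)) {
    calib <- white_noise(calibration_frames, cell$grid$grid_shape,
                         contrast = contrast, seed = child_seed(seed, 11))
    base <- rgc_rate(cell, calib, gain = 1)
    cell$gain <- target_rate * cell$bin_width / mean(base)
  }
  rates <- rgc_rate(cell, raw, cell$gain)
  spikes <- sample_spikes(rates, bin_width = cell$bin_width,
                          seed = child_seed(seed, 12))
  list(rates = rates, spikes = spikes, cell = cell)
}

#' Low-dimensional ground-truth LNLN toy cell
#'
#' Explicit small cascade cells used for recovery and consistency tests:
#' `n_subunits = 3` gives three unit-norm filters at distinct angles in a
#' low-dimensional Gaussian stimulus space; `n_subunits = 5` gives five
#' compact Gaussian blob filters on a pixel grid. Responses are
#' `g(sum_n w_n exp(K_n . X))` with Poisson spiking.
#'
#' @param n_subunits 3 or 5 (other values allowed: filters at equispaced
#'   angles when `dims == 2`, random compact blobs otherwise).
#' @param dims stimulus dimensionality: 2 (default for `n_subunits = 3`) or
#'   `c(rows, cols)` of a pixel grid (default 8 x 8 for `n_subunits = 5`).
#' @param filter_norm L2 norm of each true filter (drives response
#'   nonlinearity strength).
#' @param mean_rate target mean spike count per bin used to set the weights.
#' @param nonlinearity optional [output_nonlinearity()] (default identity).
#' @param seed integer seed (blob placement only; angular filters are
#'   deterministic).
#' @return A [subunit_model()] with attribute `true_bank` (the generating
#'   bank) — usable directly with [firing_rate()]/[sample_spikes()].
#' @export
toy_cell <- function(n_subunits = 3, dims = NULL, filter_norm = 1.5,
                     mean_rate = 0.08, nonlinearity = output_nonlinearity(),
                     seed = NULL) {
  if (is.null(dims)) dims <- if (n_subunits == 3) 2 else c(8, 8)
  if (length(dims) == 1 && dims == 2) {
    ang <- pi / 2 + (seq_len(n_subunits) - 1) * 2 * pi / n_subunits
    K <- filter_norm * cbind(cos(ang), sin(ang))
    grid_shape <- NULL
  } else {
    nr <- dims[1]; nc <- dims[2]
    D <- nr * nc
    # compact Gaussian blobs on a ring covering the grid
    cx <- (nc + 1) / 2; cy <- (nr + 1) / 2
    rad <- min(nr, nc) / 3.2
    ang <- with_seed(child_seed(seed, 21), stats::runif(1, 0, 2 * pi)) +
      (seq_len(n_subunits) - 1) * 2 * pi / n_subunits
    px <- rep(seq_len(nr), nc); py <- rep(seq_len(nc), each = nr)
    K <- t(vapply(seq_len(n_subunits), function(i) {
      mx <- cy + rad * sin(ang[i]); my <- cx + rad * cos(ang[i])
      k <- exp(-((px - mx)^2 + (py - my)^2) / (2 * (min(nr, nc) / 6)^2))
      filter_norm * k / sqrt(sum(k^2))
    }, numeric(D)))
    grid_shape <- c(nr, nc)
  }
  # equal weights; scaled so mean generator under N(0, I) hits mean_rate
  w <- rep(mean_rate / sum(exp(rowSums(K^2) / 2)), n_subunits)
  bank <- subunit_bank(K, w)
  model <- subunit_model(bank, nonlinearity, grid_shape = grid_shape)
  attr(model, "true_bank") <- bank
  model
}

#' Binary (or Gaussian) white-noise stimulus
#'
#' Frames of independent pixels at `+/- contrast/2` (binary, default) or
#' zero-mean Gaussians of the matching variance.
#'
#' @param T_frames number of frames.
#' @param grid integer `c(rows, cols)` or total pixel count.
#' @param contrast Michelson-style pixel contrast in (0, 1]; binary values
#'   are `+/- contrast/2` (0.24 at the default 48%).
#' @param binary draw binary frames (default) or Gaussian.
#' @param seed optional integer seed.
#' @return T x D matrix with attribute `grid_shape`.
#' @export
white_noise <- function(T_frames, grid, contrast = 0.48, binary = TRUE,
                        seed = NULL) {
  if (contrast <= 0 || contrast > 1) stop("contrast must be in (0, 1]")
  D <- if (length(grid) > 1) prod(grid) else grid
  half <- contrast / 2
  S <- with_seed(seed, {
    if (binary) matrix(sample(c(-half, half), T_frames * D, replace = TRUE),
                       T_frames, D)
    else matrix(stats::rnorm(T_frames * D, 0, half), T_frames, D)
  })
  attr(S, "grid_shape") <- if (length(grid) > 1) as.integer(grid) else NULL
  S
}
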