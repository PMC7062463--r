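#' Train / validation / test partition of time bins
#'
#' The test set is the contiguous tail of the recording (`test_frac` of all
#' bins); the remaining bins are split at random into training and
#' validation sets.
#'
#' @param T_total number of time bins.
#' @param test_frac fraction held out as the contiguous test tail.
#' @param val_frac fraction of the non-test bins used for validation.
#' @param seed optional integer seed for the random train/validation split.
#' @return An object of class `partition`: list of integer index vectors
#'   `train`, `validation`, `test` (disjoint, covering all bins).
#' @export
make_partition <- function(T_total, test_frac = 0.1, val_frac = 0.1,
                           seed = NULL) {
  n_test <- ceiling(test_frac * T_total)
  if (n_test >= T_total) stop("T_total too small for the requested test fraction")
  test <- (T_total - n_test + 1):T_total
  rest <- seq_len(T_total - n_test)
  n_val <- round(val_frac * length(rest))
  if (length(rest) - n_val < 1) stop("T_total too small")
  val <- sort(with_seed(seed, sample(rest, n_val)))
  structure(list(train = setdiff(rest, val), validation = val, test = test),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("<partition> train %d / validation %d / test %d bins (test contiguous at end)\n",
              length(x$train), length(x$validation), length(x$test)))
  invisible(x)
}

# per-bin log-likelihood of a fitted model on an index subset
heldout_ll <- function(model, X, Y, idx) {
  Xf <- as_frames(X); Yc <- as_counts(Y)
  -nll(model, Xf[idx, , drop = FALSE], Yc[idx])
}

#' Cross-validated selection of subunit count and regularization
#'
#' For every `(N, lambda)` on the grids, fits the model on random
#' training/validation splits (`repeats` of them, each with a fresh
#' initialization), evaluates the validation log-likelihood of the
#' stage-two model, averages over repeats, and returns the maximizing pair
#' together with a full results table and a final fit on train+validation
#' data at the selected setting.
#'
#' @inheritParams fit_subunits
#' @param N_grid candidate subunit counts (default 1..6).
#' @param lam_grid candidate regularization strengths (default 0: no
#'   regularization search).
#' @param repeats fits averaged per grid point.
#' @param test_frac held-out contiguous test tail excluded from all fitting.
#' @return An object of class `model_selection`: `N_star`, `lam_star`,
#'   `table` (data.frame: N, lam, repeat, val_ll), `fit` (final
#'   `subunit_fit`), `model` (final stage-two [subunit_model()]),
#'   `test_ll` (held-out log-likelihood per bin of the final model).
#' @export
select_model <- function(X, Y, N_grid = 1:6, lam_grid = 0,
                         reg_kind = c("none", "l1", "lnl1"), eps = 0.01,
                         grid_shape = NULL, connectivity = 4, repeats = 3,
                         test_frac = 0.1, val_frac = 0.1, max_iter = 100,
                         tol = 1e-6, seed = NULL) {
  reg_kind <- match.arg(reg_kind)
  Xf <- as_frames(X); Yc <- as_counts(Y)
  check_aligned(Xf, Yc)
  if (is.null(grid_shape) && inherits(X, "stimulus_matrix"))
    grid_shape <- X$grid_shape
  Tn <- length(Yc)
  rows <- list()
  for (r in seq_len(repeats)) {
    part <- make_partition(Tn, test_frac, val_frac, seed = child_seed(seed, r))
    Xtr <- Xf[part$train, , drop = FALSE]; Ytr <- Yc[part$train]
    for (N in N_grid) for (lam in lam_grid) {
      fit <- fit_subunits(Xtr, Ytr, N, lam = lam,
                          reg_kind = if (lam > 0) reg_kind else "none",
                          eps = eps, grid_shape = grid_shape,
                          connectivity = connectivity, max_iter = max_iter,
                          tol = tol, seed = child_seed(seed, 100 * r + N))
      mod <- fit_output_nonlinearity(Xtr, Ytr, fit$bank,
                                     grid_shape = grid_shape)
      vll <- heldout_ll(mod, Xf, Yc, part$validation)
      rows[[length(rows) + 1]] <- data.frame(N = N, lam = lam, rep = r,
                                             val_ll = vll)
    }
  }
  tab <- do.call(rbind, rows)
  agg <- stats::aggregate(val_ll ~ N + lam, tab, mean)
  agg$se <- stats::aggregate(val_ll ~ N + lam, tab,
                             function(v) stats::sd(v) / sqrt(length(v)))$val_ll
  agg$se[is.na(agg$se)] <- 0
  # one-standard-error rule: among settings within one SE of the best mean
  # validation likelihood, keep the most parsimonious (smallest N, then
  # largest lambda) — breaks the near-ties that nested subunit models
  # produce on clean data
  imax <- which.max(agg$val_ll)
  cand <- agg[agg$val_ll >= agg$val_ll[imax] - agg$se[imax], ]
  cand <- cand[order(cand$N, -cand$lam), ]
  best <- cand[1, ]
  part <- make_partition(Tn, test_frac, val_frac, seed = child_seed(seed, 1))
  fitidx <- sort(c(part$train, part$validation))
  fit <- fit_subunits(Xf[fitidx, , drop = FALSE], Yc[fitidx], best$N,
                      lam = best$lam,
                      reg_kind = if (best$lam > 0) reg_kind else "none",
                      eps = eps, grid_shape = grid_shape,
                      connectivity = connectivity, max_iter = max_iter,
                      tol = tol, seed = child_seed(seed, 7))
  mod <- fit_output_nonlinearity(Xf[fitidx, , drop = FALSE], Yc[fitidx],
                                 fit$bank, grid_shape = grid_shape)
  structure(list(N_star = best$N, lam_star = best$lam, table = tab,
                 summary = agg, fit = fit, model = mod,
                 test_ll = heldout_ll(mod, Xf, Yc, part$test)),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat(sprintf("<model_selection> N*=%d, lambda*=%.3g; held-out test LL %.5g /bin\n",
              x$N_star, x$lam_star, x$test_ll))
  invisible(x)
}

#' Peri-stimulus time histogram
#'
#' Trial-averaged spike counts smoothed with a Gaussian kernel (truncated
#' at four standard deviations, renormalized at the edges so kernel mass is
#' conserved), returned as a rate in spikes/s.
#'
#' @param rasters R x T matrix of per-trial binned counts (a single trial
#'   may be passed as a vector).
#' @param sigma smoothing standard deviation in seconds (default 16.67 ms).
#' @param bin_width bin width in seconds.
#' @return Numeric length-T smoothed rate (spikes/s).
#' @export
psth <- function(rasters, sigma = 1 / 60, bin_width = 1 / 120) {
  rasters <- rbind(rasters)
  m <- colMeans(rasters) / bin_width
  sig_bins <- sigma / bin_width
  if (sig_bins < 1e-9) return(m)
  half <- max(1L, ceiling(4 * sig_bins))
  kern <- stats::dnorm(-half:half, sd = sig_bins)
  kern <- kern / sum(kern)
  Tn <- length(m)
  padded <- c(rep(0, half), m, rep(0, half))
  sm <- stats::filter(padded, kern, sides = 2)[(half + 1):(half + Tn)]
  # edge renormalization: divide by the kernel mass actually inside range
  mass <- stats::filter(c(rep(0, half), rep(1, Tn), rep(0, half)), kern,
                        sides = 2)[(half + 1):(half + Tn)]
  as.numeric(sm / mass)
}

#' PSTH correlation between data and model
#'
#' Simulates as many model trials as were recorded (Poisson draws from the
#' model rate on the same stimulus), computes both PSTHs with the same
#' smoothing, and returns their Pearson correlation.
#'
#' @param model a [subunit_model()] (or a rate vector).
#' @param X stimulus frames presented on each trial.
#' @param rasters R x T recorded counts.
#' @param sigma,bin_width PSTH smoothing parameters.
#' @param seed integer seed for the simulated trials.
#' @return Pearson correlation in `[-1, 1]`; `NA` with a warning when
#'   either PSTH has zero variance.
#' @export
psth_correlation <- function(model, X, rasters, sigma = 1 / 60,
                             bin_width = 1 / 120, seed = NULL) {
  rasters <- rbind(rasters)
  R <- nrow(rasters)
  lam <- if (is.numeric(model)) model else firing_rate(model, X)
  sim <- with_seed(seed, matrix(stats::rpois(R * length(lam), rep(lam, each = R)),
                                R, length(lam)))
  p_data <- psth(rasters, sigma, bin_width)
  p_model <- psth(sim, sigma, bin_width)
  if (stats::sd(p_data) < 1e-10 * (1 + mean(p_data)) ||
      stats::sd(p_model) < 1e-10 * (1 + mean(p_model))) {
    warning("zero-variance PSTH; correlation undefined")
    return(NA_real_)
  }
  stats::cor(p_data, p_model)
}

#' Response structure of a raster
#'
#' Temporal variance of the PSTH — the amount of stimulus-locked rate
#' modulation. Given a second raster (e.g. the white-noise condition), the
#' ratio of the two structures is also returned.
#'
#' @param rasters R x T counts.
#' @param sigma,bin_width PSTH smoothing parameters.
#' @param reference optional raster to normalize by.
#' @return List with `structure` (variance of the PSTH over time, in
#'   (spikes/s)^2) and `ratio` (structure / reference structure, or `NA`).
#' @export
response_structure <- function(rasters, sigma = 1 / 60, bin_width = 1 / 120,
                               reference = NULL) {
  s <- stats::var(psth(rasters, sigma, bin_width))
  ratio <- if (is.null(reference)) NA_real_
           else s / stats::var(psth(reference, sigma, bin_width))
  list(structure = s, ratio = ratio)
}

#' Angle between stimulus frames and a receptive field
#'
#' `acos` of the normalized inner product, in degrees within `[0, 180]`.
#' Zero-norm frames are returned as `NA`.
#'
#' @param X T x D frames.
#' @param rf nonzero receptive-field vector.
#' @return Numeric vector of angles (degrees), one per frame.
#' @export
rf_stimulus_angle <- function(X, rf) {
  Xf <- as_frames(X)
  nr <- sqrt(sum(rf^2))
  if (nr == 0) stop("receptive field must be nonzero")
  nx <- sqrt(rowSums(Xf^2))
  cosang <- drop(Xf %*% rf) / (nx * nr)
  out <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  out[nx == 0] <- NA_real_
  out
}

#' Post-saccade analysis window mask
#'
#' Marks the bins falling within `window` seconds after each saccade (or
#' image-transition) time, for splitting responses into saccadic and
#' inter-saccadic epochs.
#'
#' @param saccade_times event times in seconds.
#' @param T_total number of bins.
#' @param bin_width seconds per bin.
#' @param window epoch length after each event (default 0.25 s).
#' @return Logical vector of length `T_total`; `TRUE` inside a window.
#' @export
saccade_window_mask <- function(saccade_times, T_total, bin_width = 1 / 120,
                                window = 0.25) {
  mask <- logical(T_total)
  for (s in saccade_times) {
    lo <- max(1L, floor(s / bin_width) + 1L)
    hi <- min(T_total, ceiling((s + window) / bin_width))
    if (lo <= hi) mask[lo:hi] <- TRUE
  }
  mask
}
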