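#' Joint subunit estimation for a cell population
#'
#' Fits one shared bank of subunit filters to several simultaneously
#' recorded cells with per-cell nonnegative weights, by clustering the
#' pooled spike-triggered stimuli: each iteration computes per-cell soft
#' assignments, updates each shared filter as the responsibility-weighted
#' mean of spike-triggered frames pooled over cells (followed by the
#' proximal step), and updates the per-cell weights. A per-cell output
#' nonlinearity is then fit in stage two. With a single cell the procedure
#' reduces exactly to [fit_subunits()].
#'
#' @inheritParams fit_subunits
#' @param Y_list list of spike-count vectors, one per cell, aligned to `X`.
#' @param reg_kind regularizer for the shared filters (default `"lnl1"`,
#'   which suits the larger union stimulus window).
#' @param stage2 fit per-cell output nonlinearities (default `TRUE`).
#' @param weak_frac subunits contributing less than this fraction of a
#'   cell's total strength are flagged (not removed) as poorly estimated
#'   for that cell.
#' @return An object of class `population_fit`: shared `K`, per-cell
#'   weight matrix `W` (N x C), per-cell `models` (when `stage2`), `trace`,
#'   `converged`, `weak` flag matrix.
#' @export
fit_population <- function(X, Y_list, N, lam = 0,
                           reg_kind = c("lnl1", "l1", "none"), eps = 0.01,
                           grid_shape = NULL, connectivity = 4,
                           max_iter = 100, tol = 1e-6, seed = NULL,
                           init = c("sta-noise", "random"), stage2 = TRUE,
                           weak_frac = 0.01) {
  reg_kind <- match.arg(reg_kind)
  init <- match.arg(init)
  if (!is.list(Y_list)) Y_list <- list(Y_list)
  if (is.null(grid_shape) && inherits(X, "stimulus_matrix"))
    grid_shape <- X$grid_shape
  reg <- make_regularizer(reg_kind, lam, eps, grid_shape, connectivity)
  res <- with_seed(seed,
                   fit_engine(X, Y_list, N, reg, max_iter, tol, init = init))
  C <- length(Y_list)
  strength <- sweep(res$W, 1, exp(rowSums(res$K^2) / 2), `*`)   # N x C
  weak <- sweep(strength, 2, colSums(strength), `/`) < weak_frac
  models <- NULL
  if (isTRUE(stage2)) {
    models <- lapply(seq_len(C), function(c)
      fit_output_nonlinearity(X, Y_list[[c]],
                              subunit_bank(res$K, res$W[, c]),
                              grid_shape = grid_shape))
  }
  structure(list(K = res$K, W = res$W, models = models, trace = res$trace,
                 converged = res$converged, iterations = res$iterations,
                 rescues = res$rescues, weak = weak, seed = seed,
                 reg = list(kind = reg$kind, lam = reg$lam, eps = eps),
                 grid_shape = grid_shape),
            class = "population_fit")
}

#' @export
print.population_fit <- function(x, ...) {
  cat(sprintf("<population_fit> N=%d shared subunits, %d cells, %s reg (lam=%.3g), %d iterations%s\n",
              nrow(x$K), ncol(x$W), x$reg$kind, x$reg$lam, x$iterations,
              if (x$converged) " (converged)" else ""))
  invisible(x)
}

#' Best allocation of a subunit budget across separate fits
#'
#' Given per-cell validation log-likelihoods for a range of subunit counts,
#' finds the allocation of a total subunit budget across cells that
#' maximizes the summed validation log-likelihood (dynamic programming over
#' cells; every cell gets at least one subunit).
#'
#' @param ll_tables list (one per cell) of numeric vectors: entry `[n]` is
#'   the validation log-likelihood of that cell's n-subunit fit.
#' @param budget total number of subunits to allocate.
#' @return List with `allocation` (integer per cell) and `total_ll`.
#' @export
best_separate_combination <- function(ll_tables, budget) {
  C <- length(ll_tables)
  if (budget < C) stop("budget must allow at least one subunit per cell")
  maxN <- vapply(ll_tables, length, integer(1))
  # dp[c, b]: best total LL using cells 1..c with b subunits
  dp <- matrix(-Inf, C, budget)
  choice <- matrix(0L, C, budget)
  for (b in seq_len(min(maxN[1], budget))) {
    dp[1, b] <- ll_tables[[1]][b]; choice[1, b] <- b
  }
  if (C > 1) for (c in 2:C) for (b in c:budget) {
    for (n in seq_len(min(maxN[c], b - (c - 1)))) {
      v <- dp[c - 1, b - n] + ll_tables[[c]][n]
      if (is.finite(v) && v > dp[c, b]) { dp[c, b] <- v; choice[c, b] <- n }
    }
  }
  best_b <- which.max(dp[C, ])       # allow using less than the full budget
  alloc <- integer(C)
  b <- best_b
  for (c in C:1) { alloc[c] <- choice[c, b]; b <- b - alloc[c] }
  list(allocation = alloc, total_ll = dp[C, best_b])
}

#' Fraction of closely spaced subunits across cells
#'
#' For each subunit, finds its nearest neighbor among the subunits of
#' *other* cells and normalizes the center separation by the geometric mean
#' of the two Gaussian fits' standard deviations along the center-joining
#' direction. Returns the fraction of subunits closer than `threshold_sd`,
#' together with the analogous within-cell fraction (the prediction from
#' single-cell subunit spacing).
#'
#' @param fits_by_cell list (per cell) of lists of [gaussian2d_fit()]
#'   results (each with `center` and `cov`).
#' @param threshold_sd separation threshold in joint-SD units (default 1).
#' @return List with `fraction` (across cells), `predicted` (within cells),
#'   `n_cross`, `n_within`.
#' @export
sharing_fraction <- function(fits_by_cell, threshold_sd = 1) {
  if (length(fits_by_cell) < 2) stop("need subunits from at least two cells")
  centers <- list(); covs <- list(); cell <- integer(0)
  for (c in seq_along(fits_by_cell)) for (f in fits_by_cell[[c]]) {
    centers[[length(centers) + 1]] <- f$center
    covs[[length(covs) + 1]] <- f$cov
    cell <- c(cell, c)
  }
  M <- length(centers)
  ndist <- function(i, j) {
    d <- centers[[j]] - centers[[i]]
    L <- sqrt(sum(d^2))
    if (L == 0) return(0)
    u <- d / L
    s1 <- sqrt(drop(t(u) %*% covs[[i]] %*% u))
    s2 <- sqrt(drop(t(u) %*% covs[[j]] %*% u))
    L / sqrt(s1 * s2)
  }
  nn_over <- function(same_cell) {
    vals <- numeric(0)
    for (i in seq_len(M)) {
      cand <- which(if (same_cell) cell == cell[i] else cell != cell[i])
      cand <- setdiff(cand, i)
      if (length(cand) == 0) next
      vals <- c(vals, min(vapply(cand, function(j) ndist(i, j), numeric(1))))
    }
    vals
  }
  cross <- nn_over(FALSE)
  within <- nn_over(TRUE)
  list(fraction = mean(cross < threshold_sd),
       predicted = if (length(within)) mean(within < threshold_sd) else NA_real_,
       n_cross = length(cross), n_within = length(within))
}
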