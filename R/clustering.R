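#' Soft cluster assignments of spike-triggered stimuli
#'
#' For each spike-triggered frame, the responsibility of subunit n is the
#' softmax `alpha_n = w_n exp(K_n.X) / sum_m w_m exp(K_m.X)`, computed with
#' max-subtraction in the log domain for overflow safety. Subunits with zero
#' weight receive zero responsibility.
#'
#' @param X_spike S x D matrix of spike-triggered frames.
#' @param bank a [subunit_bank()].
#' @return S x N matrix whose rows are nonnegative and sum to one.
#' @export
update_activations <- function(X_spike, bank) {
  Xs <- as_frames(X_spike)
  if (all(bank$w == 0)) stop("all subunit weights are zero")
  logw <- ifelse(bank$w > 0, log(bank$w), -Inf)
  Z <- sweep(Xs %*% t(bank$K), 2, logw, `+`)   # S x N log-scores
  m <- apply(Z, 1, max)
  E <- exp(Z - m)
  E / rowSums(E)
}

#' Filter (cluster-center) update
#'
#' Each filter becomes the responsibility-weighted mean of the
#' spike-triggered frames, `K_n = sum_t Y_t alpha_{t,n} X_t / sum_t Y_t
#' alpha_{t,n}`, optionally followed by a proximal (regularization) step.
#'
#' @param X_spike S x D spike-triggered frames.
#' @param Y_spike length-S spike counts (multiplicities).
#' @param alpha S x N soft assignments.
#' @param prox optional function applied to each updated filter vector.
#' @return N x D filter matrix.
#' @export
update_filters <- function(X_spike, Y_spike, alpha, prox = NULL) {
  Xs <- as_frames(X_spike)
  Ys <- as_counts(Y_spike)
  W <- alpha * Ys                     # S x N
  mass <- colSums(W)
  if (any(mass <= 0))
    stop("empty cluster: a subunit received zero responsibility mass")
  K <- t(Xs) %*% W                    # D x N
  K <- t(sweep(K, 2, mass, `/`))      # N x D
  if (!is.null(prox)) K <- t(apply(K, 1, prox))
  K
}

#' Weight update
#'
#' `w_n = (sum_t Y_t alpha_{t,n} / T) exp(-K_n.K_n / 2)`: the per-bin
#' responsibility mass of a subunit, discounted by its expected drive so
#' that `w_n exp(K_n.K_n/2)` (the subunit strength) equals that mass.
#'
#' @inheritParams update_filters
#' @param bank bank holding the freshly updated filters.
#' @param T_total total number of stimulus bins.
#' @return Length-N nonnegative weight vector.
#' @export
update_weights <- function(Y_spike, alpha, bank, T_total) {
  if (T_total <= 0) stop("T_total must be positive")
  Ys <- as_counts(Y_spike)
  mass <- colSums(alpha * Ys)
  (mass / T_total) * exp(-rowSums(bank$K^2) / 2)
}

# spike-triggered view of (X, Y): frames with Y_t > 0 and their counts
spike_view <- function(X, Y) {
  Xf <- as_frames(X)
  Yc <- as_counts(Y)
  check_aligned(Xf, Yc)
  idx <- which(Yc > 0)
  list(X = Xf[idx, , drop = FALSE], Y = Yc[idx], T_total = length(Yc))
}

# shared single-cell / population clustering engine.
# X: stimulus; Y_list: list of count vectors (one per cell).
# Returns bank (filters), per-cell weight matrix (N x C), trace, ...
fit_engine <- function(X, Y_list, N, reg, max_iter = 100, tol = 1e-6,
                       init = c("sta-noise", "random"), init_noise = 0.1,
                       init_K = NULL, init_W = NULL) {
  init <- match.arg(init)
  Xf <- as_frames(X)
  D <- ncol(Xf)
  C <- length(Y_list)
  views <- lapply(Y_list, function(Y) spike_view(Xf, Y))
  T_total <- views[[1]]$T_total
  tot_spikes <- sum(vapply(views, function(v) sum(v$Y), numeric(1)))
  if (tot_spikes <= 0) stop("no spikes: cannot fit subunits")

  # pooled spike-triggered average direction for initialization
  sta_vec <- Reduce(`+`, lapply(views, function(v) colSums(v$X * v$Y))) / tot_spikes
  sd_noise <- init_noise * sqrt(sum(sta_vec^2)) / sqrt(D)
  if (!is.null(init_K)) {
    K <- rbind(init_K)
    if (nrow(K) != N || ncol(K) != D) stop("init_K has the wrong shape")
  } else if (init == "sta-noise") {
    K <- matrix(rep(sta_vec, each = N), N, D) +
      matrix(stats::rnorm(N * D, 0, sd_noise), N, D)
    if (N == 1) K[1, ] <- sta_vec
  } else {
    K <- matrix(stats::rnorm(N * D, 0, max(sd_noise, 1e-3)), N, D)
  }
  W <- if (!is.null(init_W)) {
    matrix(init_W, N, C)
  } else {
    matrix(vapply(views, function(v) sum(v$Y), numeric(1)) / T_total / N,
           N, C, byrow = TRUE)       # N x C weights
  }

  objective <- function(K, W) {
    bankK2 <- rowSums(K^2)
    val <- 0
    for (c in seq_len(C)) {
      v <- views[[c]]
      G <- drop(exp(v$X %*% t(K)) %*% W[, c])
      val <- val + sum(W[, c] * exp(bankK2 / 2)) - sum(v$Y * log(G)) / T_total
    }
    val + sum(apply(K, 1, reg$penalty))
  }

  trace <- numeric(0)
  rescues <- 0L
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # (1) per-cell soft assignments; (2) shared filter update
    num <- matrix(0, D, N)
    mass <- matrix(0, N, C)
    alphas <- vector("list", C)
    for (c in seq_len(C)) {
      v <- views[[c]]
      A <- update_activations(v$X, subunit_bank(K, W[, c]))
      alphas[[c]] <- A
      WY <- A * v$Y
      num <- num + t(v$X) %*% WY
      mass[, c] <- colSums(WY)
    }
    tot_mass <- rowSums(mass)
    dead <- tot_mass <= 1e-12 * tot_spikes
    for (n in which(!dead)) K[n, ] <- num[, n] / tot_mass[n]
    if (any(dead)) {
      # rescue: reseed the subunit from a random spike-triggered frame
      for (n in which(dead)) {
        c0 <- sample.int(C, 1)
        r <- sample.int(nrow(views[[c0]]$X), 1)
        K[n, ] <- views[[c0]]$X[r, ]
        tot_mass[n] <- tot_spikes / (10 * N)
        mass[n, ] <- tot_mass[n] / C
        rescues <- rescues + 1L
      }
    }
    if (!is.null(reg$prox)) K <- t(apply(K, 1, reg$prox))
    # (3) per-cell weights
    W <- sweep(mass, 1, exp(-rowSums(K^2) / 2), `*`) / T_total
    obj <- objective(K, W)
    trace <- c(trace, obj)
    # converged when the surrogate change is small AND shrinking: near the
    # symmetric initialization the change can be tiny while still growing
    # (slow escape from the saddle), which must not count as convergence
    if (it > 2) {
      d1 <- abs(trace[it - 1] - obj)
      d0 <- abs(trace[it - 2] - trace[it - 1])
      if (d1 < tol * abs(obj) && d1 <= d0) {
        converged <- TRUE
        break
      }
    }
  }

  # stable reporting: sort subunits by total strength across cells
  strength <- rowSums(sweep(W, 1, exp(rowSums(K^2) / 2), `*`))
  ord <- order(strength, decreasing = TRUE)
  list(K = K[ord, , drop = FALSE], W = W[ord, , drop = FALSE],
       trace = trace, converged = converged, iterations = length(trace),
       rescues = rescues, sta = sta_vec)
}

#' Fit subunit filters by spike-triggered soft clustering
#'
#' The core estimator: alternates soft assignment of spike-triggered frames
#' to subunits, responsibility-weighted centroid updates of the filters
#' (with an optional proximal regularization step), and weight updates,
#' monotonically decreasing a convex surrogate of the approximate Poisson
#' negative log-likelihood until the relative change drops below `tol` or
#' `max_iter` iterations.
#'
#' @param X a [stimulus_matrix()] (prefiltered and standardized) or matrix.
#' @param Y spike counts aligned to `X`.
#' @param N number of subunits.
#' @param lam regularization strength (0 disables).
#' @param reg_kind one of `"none"`, `"l1"`, `"lnl1"`.
#' @param eps LNL1 stabilizer.
#' @param grid_shape pixel grid for the LNL1 neighborhood; taken from `X`
#'   when available.
#' @param connectivity neighborhood connectivity (4 or 8).
#' @param max_iter maximum clustering iterations (default 100).
#' @param tol relative convergence tolerance on the surrogate objective.
#' @param seed integer seed controlling initialization (and any
#'   empty-cluster rescues); `NULL` uses the current RNG stream.
#' @param init `"sta-noise"` (STA direction plus small Gaussian noise, the
#'   default) or `"random"`.
#' @return An object of class `subunit_fit`: list with `bank` (a
#'   [subunit_bank()], sorted by descending [subunit_strength()]), `trace`
#'   (per-iteration surrogate values), `converged`, `iterations`,
#'   `rescues`, `seed`, `reg` and the initialization STA (`sta`).
#' @export
fit_subunits <- function(X, Y, N, lam = 0, reg_kind = c("none", "l1", "lnl1"),
                         eps = 0.01, grid_shape = NULL, connectivity = 4,
                         max_iter = 100, tol = 1e-6, seed = NULL,
                         init = c("sta-noise", "random")) {
  reg_kind <- match.arg(reg_kind)
  init <- match.arg(init)
  if (N < 1) stop("N must be >= 1")
  if (is.null(grid_shape) && inherits(X, "stimulus_matrix"))
    grid_shape <- X$grid_shape
  reg <- make_regularizer(reg_kind, lam, eps, grid_shape, connectivity)
  res <- with_seed(seed,
                   fit_engine(X, list(Y), N, reg, max_iter, tol, init = init))
  structure(list(bank = subunit_bank(res$K, drop(res$W)),
                 trace = res$trace, converged = res$converged,
                 iterations = res$iterations, rescues = res$rescues,
                 seed = seed, reg = list(kind = reg$kind, lam = reg$lam, eps = eps),
                 sta = res$sta, grid_shape = grid_shape),
            class = "subunit_fit")
}

#' @export
print.subunit_fit <- function(x, ...) {
  cat(sprintf("<subunit_fit> N=%d, %s reg (lam=%.3g), %d iterations%s, surrogate %.6g\n",
              n_subunits(x$bank), x$reg$kind, x$reg$lam, x$iterations,
              if (x$converged) " (converged)" else "",
              utils::tail(x$trace, 1)))
  invisible(x)
}

#' Fit the output nonlinearity (estimation stage two)
#'
#' Holds the subunit filter directions fixed and fits the saturating output
#' nonlinearity `g(x) = x^a / (1 + b x)` together with per-subunit weight
#' scales by minimizing the exact Poisson negative log-likelihood.
#' Positivity (`a > 0`, scales > 0) is enforced by log reparameterization
#' and `b >= 0` by a softplus; three deterministic starts are tried and the
#' best kept. If the optimizer fails to improve, the best iterate seen is
#' returned with `warning_flag = TRUE`.
#'
#' @param X stimulus frames.
#' @param Y spike counts.
#' @param bank fitted [subunit_bank()] (from [fit_subunits()]).
#' @param per_subunit_scale if `TRUE` (default) each subunit weight gets its
#'   own positive scale; if `FALSE` a single shared scale is fit.
#' @param grid_shape,bin_width,time_course metadata carried into the model.
#' @return A [subunit_model()] with attributes `nll` (training value) and
#'   `warning_flag`.
#' @export
fit_output_nonlinearity <- function(X, Y, bank, per_subunit_scale = TRUE,
                                    grid_shape = NULL, bin_width = 1 / 120,
                                    time_course = NULL) {
  Xf <- as_frames(X)
  Yc <- as_counts(Y)
  check_aligned(Xf, Yc)
  E <- exp(Xf %*% t(bank$K))          # T x N subunit outputs
  N <- ncol(E)
  n_s <- if (per_subunit_scale) N else 1
  Tn <- length(Yc)
  spk <- Yc > 0

  unpack <- function(theta) {
    s <- exp(theta[seq_len(n_s)])
    list(s = s, a = exp(theta[n_s + 1]), b = log1p(exp(theta[n_s + 2])),
         ws = bank$w * if (per_subunit_scale) s else rep(s, N))
  }
  neg_ll <- function(theta) {
    p <- unpack(theta)
    G <- drop(E %*% p$ws)
    lam <- G^p$a / (1 + p$b * G)
    if (any(!is.finite(lam)) || any(lam[spk] <= 0)) return(1e10)
    mean(lam) - sum(Yc[spk] * log(lam[spk])) / Tn
  }
  neg_ll_grad <- function(theta) {
    p <- unpack(theta)
    G <- drop(E %*% p$ws)
    lam <- G^p$a / (1 + p$b * G)
    if (any(!is.finite(lam)) || any(lam[spk] <= 0))
      return(rep(0, length(theta)))
    dl <- (1 - Yc / lam) / Tn                      # d obj / d lam_t
    dG <- dl * lam * (p$a / G - p$b / (1 + p$b * G))
    g_ws <- drop(crossprod(E, dG))                 # d obj / d ws_n
    g_s <- if (per_subunit_scale) g_ws * p$ws else sum(g_ws * p$ws)
    g_a <- sum(dl * lam * log(G)) * p$a
    g_b <- -sum(dl * lam * G / (1 + p$b * G)) *
      stats::plogis(theta[n_s + 2])                # softplus'
    c(g_s, g_a, g_b)
  }

  starts <- list(c(rep(0, n_s), 0, -12),        # identity g
                 c(rep(0, n_s), 0, 0),          # moderate saturation b ~ 0.69
                 c(rep(0, n_s), log(0.8), -3))  # compressive exponent
  best <- NULL
  warn <- FALSE
  values <- numeric(0)
  for (th0 in starts) {
    opt <- tryCatch(stats::optim(th0, neg_ll, neg_ll_grad, method = "BFGS",
                                 control = list(maxit = 100, reltol = 1e-8)),
                    error = function(e) NULL)
    if (is.null(opt)) { warn <- TRUE; next }
    v0 <- neg_ll(th0)
    if (opt$value > v0) {             # keep best iterate contract
      opt$par <- th0; opt$value <- v0; warn <- TRUE
    }
    if (is.null(best) || opt$value < best$value) best <- opt
    values <- c(values, opt$value)
    # two starts already agree to high precision: a third is redundant
    if (length(values) >= 2 &&
        diff(range(values[1:2])) < 1e-8 * max(1, abs(values[1]))) break
  }
  if (is.null(best)) stop("output-nonlinearity optimization failed at all starts")
  s <- exp(best$par[seq_len(n_s)])
  a <- exp(best$par[n_s + 1])
  b <- log1p(exp(best$par[n_s + 2]))
  ws <- bank$w * if (per_subunit_scale) s else rep(s, N)
  model <- subunit_model(subunit_bank(bank$K, ws),
                         output_nonlinearity(a, b),
                         time_course = time_course, grid_shape = grid_shape,
                         bin_width = bin_width)
  attr(model, "nll") <- best$value
  attr(model, "warning_flag") <- warn
  model
}

#' STA-decomposition residual
#'
#' At an unregularized fixed point of the clustering, the strength-weighted
#' sum of subunit filters is proportional to the spike-triggered average.
#' This returns `1 - cos(sum_n strength_n K_n, sum_t Y_t X_t)`, near zero
#' at convergence without regularization (exactly zero for N = 1);
#' proximal steps break the identity, so regularized fits report larger
#' values.
#'
#' @param bank fitted [subunit_bank()].
#' @param X_spike spike-triggered frames (or full stimulus).
#' @param Y_spike matching spike counts.
#' @return Scalar in `[0, 2]`.
#' @export
sta_decomposition_residual <- function(bank, X_spike, Y_spike) {
  Xs <- as_frames(X_spike)
  Ys <- as_counts(Y_spike)
  recon <- drop(subunit_strength(bank$K, bank$w) %*% bank$K)
  sta <- colSums(Xs * Ys)
  1 - cosine(recon, sta)
}
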