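#' Initialize a subunit split
#'
#' Replaces parent subunit `m` by two children: each child filter is the
#' parent filter plus independent Gaussian noise, and each child weight is
#' half the parent weight (so the children's log-weight biases sum to the
#' parent's activation mass at the split point). Other subunits are left
#' untouched; child one takes the parent's slot, child two is appended.
#'
#' @param bank a [subunit_bank()].
#' @param m parent index.
#' @param noise_sd per-element noise sd; default `0.05 * ||K_m|| / sqrt(D)`.
#' @param seed optional integer seed.
#' @return A list with `bank` (N+1 subunits) and `children` (indices of the
#'   two children in the new bank).
#' @export
split_init <- function(bank, m, noise_sd = NULL, seed = NULL) {
  N <- n_subunits(bank)
  if (m < 1 || m > N) stop("invalid parent index")
  D <- ncol(bank$K)
  km <- bank$K[m, ]
  if (is.null(noise_sd)) noise_sd <- 0.05 * sqrt(sum(km^2)) / sqrt(D)
  eps <- with_seed(seed, matrix(stats::rnorm(2 * D, 0, noise_sd), 2, D))
  K <- rbind(bank$K, km + eps[2, ])
  K[m, ] <- km + eps[1, ]
  w <- c(bank$w, bank$w[m] / 2)
  w[m] <- bank$w[m] / 2
  list(bank = subunit_bank(K, w), children = c(m, N + 1L))
}

#' Factorized child assignments
#'
#' Splits the parent's responsibility between two children with a
#' conditional softmax: `alpha_child1 = alpha_parent * sigma`,
#' `alpha_child2 = alpha_parent * (1 - sigma)` where
#' `sigma = e^{K1.X + b1} / (e^{K1.X + b1} + e^{K2.X + b2})` and the biases
#' are the log child weights. The children's responsibilities sum exactly
#' to the parent's for every frame.
#'
#' @param X_spike S x D spike-triggered frames.
#' @param alpha_parent length-S parent responsibilities.
#' @param children a [subunit_bank()] holding the two child filters/weights.
#' @return S x 2 matrix of child responsibilities.
#' @export
child_assignments <- function(X_spike, alpha_parent, children) {
  if (n_subunits(children) != 2) stop("children must hold exactly two subunits")
  Xs <- as_frames(X_spike)
  b <- ifelse(children$w > 0, log(children$w), -Inf)
  Z <- sweep(Xs %*% t(children$K), 2, b, `+`)
  m <- pmax(Z[, 1], Z[, 2])
  e1 <- exp(Z[, 1] - m); e2 <- exp(Z[, 2] - m)
  sig <- e1 / (e1 + e2)
  cbind(alpha_parent * sig, alpha_parent * (1 - sig))
}

# fit the two children of a split with all other subunits frozen.
# bank: bank after split_init; ch: child indices; alpha_full: S x (N+1)
# responsibilities are recomputed only within the split pair.
refine_children <- function(bank, ch, X_spike, Y_spike, alpha_parent,
                            T_total, reg, max_iter = 50, tol = 1e-6) {
  Xs <- as_frames(X_spike)
  Ys <- as_counts(Y_spike)
  K <- bank$K; w <- bank$w
  prev <- Inf
  for (it in seq_len(max_iter)) {
    A <- child_assignments(Xs, alpha_parent, subunit_bank(K[ch, ], w[ch]))
    mass <- colSums(A * Ys)
    if (any(mass <= 0)) break
    Kc <- t(Xs) %*% (A * Ys)
    Kc <- t(sweep(Kc, 2, mass, `/`))
    if (!is.null(reg$prox)) Kc <- t(apply(Kc, 1, reg$prox))
    K[ch, ] <- Kc
    w[ch] <- (mass / T_total) * exp(-rowSums(Kc^2) / 2)
    obj <- sum(w[ch] * exp(rowSums(K[ch, ]^2) / 2)) -
      sum(Ys * (alpha_parent * log(pmax(
        exp(Xs %*% t(K[ch, , drop = FALSE])) %*% w[ch], 1e-300)))) / T_total
    if (is.finite(prev) && abs(prev - obj) < tol * abs(obj)) break
    prev <- obj
  }
  subunit_bank(K, w)
}

#' Hierarchical (split-based) subunit estimation
#'
#' Grows the model one subunit at a time: starting from the flat N = 1 fit,
#' each level tries splitting every current subunit (children refined with
#' factorized assignments while other subunits stay frozen), keeps the
#' split giving the largest decrease in the approximate negative
#' log-likelihood, and optionally refines all subunits jointly afterwards.
#'
#' @inheritParams fit_subunits
#' @param N_max deepest level (number of subunits) to grow to.
#' @param noise_sd split noise sd passed to [split_init()].
#' @param refine `"joint"` (default): after the greedy choice, all subunits
#'   are refined together from the split initialization; `"frozen"`: keep
#'   the children-only refinement.
#' @return An object of class `hierarchy_path`: list with `levels` (one
#'   `subunit_fit`-like entry per N), `parents` (index split at each step),
#'   `gains` (surrogate decrease per step).
#' @export
fit_path <- function(X, Y, N_max, lam = 0, reg_kind = c("none", "l1", "lnl1"),
                     eps = 0.01, grid_shape = NULL, connectivity = 4,
                     noise_sd = NULL, refine = c("joint", "frozen"),
                     max_iter = 100, tol = 1e-6, seed = NULL) {
  reg_kind <- match.arg(reg_kind)
  refine <- match.arg(refine)
  if (N_max < 1) stop("N_max must be >= 1")
  if (is.null(grid_shape) && inherits(X, "stimulus_matrix"))
    grid_shape <- X$grid_shape
  reg <- make_regularizer(reg_kind, lam, eps, grid_shape, connectivity)
  sv <- spike_view(X, Y)

  base <- fit_subunits(X, Y, 1, lam = lam, reg_kind = reg_kind, eps = eps,
                       grid_shape = grid_shape, connectivity = connectivity,
                       max_iter = max_iter, tol = tol, seed = seed)
  surrogate <- function(bank)
    expected_nll(bank, sv$X, sv$Y, sv$T_total) + sum(apply(bank$K, 1, reg$penalty))

  levels <- list(base)
  parents <- integer(0)
  gains <- numeric(0)
  bank <- base$bank
  lvl <- 1L
  while (lvl < N_max) {
    cur_obj <- surrogate(bank)
    alpha <- update_activations(sv$X, bank)
    best <- NULL
    for (m in seq_len(n_subunits(bank))) {
      sp <- split_init(bank, m, noise_sd = noise_sd,
                       seed = child_seed(seed, 1000 * lvl + m))
      cand <- refine_children(sp$bank, sp$children, sv$X, sv$Y,
                              alpha[, m], sv$T_total, reg,
                              max_iter = max_iter, tol = tol)
      obj <- surrogate(cand)
      if (is.null(best) || obj < best$obj)
        best <- list(bank = cand, obj = obj, parent = m)
    }
    if (refine == "joint") {
      res <- with_seed(child_seed(seed, 999 + lvl),
                       fit_engine(X, list(Y), n_subunits(best$bank), reg,
                                  max_iter, tol,
                                  init_K = best$bank$K, init_W = cbind(best$bank$w)))
      jb <- subunit_bank(res$K, drop(res$W))
      jo <- surrogate(jb)
      if (jo <= best$obj) { best$bank <- jb; best$obj <- jo }
    }
    lvl <- lvl + 1L
    parents <- c(parents, best$parent)
    gains <- c(gains, cur_obj - best$obj)
    # report sorted by strength, like the flat fit
    s <- subunit_strength(best$bank$K, best$bank$w)
    ord <- order(s, decreasing = TRUE)
    bank <- subunit_bank(best$bank$K[ord, , drop = FALSE], best$bank$w[ord])
    levels[[lvl]] <- list(bank = bank, surrogate = best$obj)
  }
  structure(list(levels = levels, parents = parents, gains = gains,
                 seed = seed),
            class = "hierarchy_path")
}

#' @export
print.hierarchy_path <- function(x, ...) {
  cat(sprintf("<hierarchy_path> levels 1..%d; split gains: %s\n",
              length(x$levels), paste(signif(x$gains, 3), collapse = ", ")))
  invisible(x)
}

#' Greedy subunit matching between two banks
#'
#' Pairs subunits across two fits by repeatedly taking the pair with the
#' largest cosine similarity between normalized filters (greedy, not
#' globally optimal). Unmatched subunits of the larger bank are reported
#' (when the banks differ by one, these are the split products).
#'
#' @param bankA,bankB [subunit_bank()] objects (or bare filter matrices).
#' @return A list with `pairs` (data.frame `a`, `b`, `cos`) and
#'   `unmatched_b` (indices of B-subunits without a partner).
#' @export
match_subunits <- function(bankA, bankB) {
  KA <- if (inherits(bankA, "subunit_bank")) bankA$K else rbind(bankA)
  KB <- if (inherits(bankB, "subunit_bank")) bankB$K else rbind(bankB)
  normr <- function(M) M / sqrt(rowSums(M^2))
  C <- normr(KA) %*% t(normr(KB))
  pairs <- data.frame(a = integer(0), b = integer(0), cos = numeric(0))
  A_left <- seq_len(nrow(KA)); B_left <- seq_len(nrow(KB))
  while (length(A_left) > 0 && length(B_left) > 0) {
    sub <- C[A_left, B_left, drop = FALSE]
    k <- arrayInd(which.max(sub), dim(sub))
    pairs <- rbind(pairs, data.frame(a = A_left[k[1]], b = B_left[k[2]],
                                     cos = sub[k[1], k[2]]))
    A_left <- A_left[-k[1]]; B_left <- B_left[-k[2]]
  }
  list(pairs = pairs[order(pairs$a), ], unmatched_b = B_left)
}
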