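#' Project frames onto the null space of linear receptive fields
#'
#' Closed-form spatial nulling: every frame of `S_w` is replaced by
#' `(I - A (A'A)^{-1} A') S_w`, the closest frame (in L2) with zero
#' projection on every column of `A`. A linear(-nonlinear) model whose
#' spatial filter lies in the span of `A` gives a constant response to the
#' result.
#'
#' @param S_w T x D matrix of stimulus frames (rows are frames).
#' @param A D x C matrix whose columns are the vectorized receptive fields
#'   to null; must have full column rank.
#' @return T x D projected stimulus.
#' @export
spatial_null <- function(S_w, A) {
  S_w <- as_frames(S_w)
  A <- cbind(A)
  if (qr(A)$rank < ncol(A)) stop("receptive-field matrix is rank deficient")
  G <- solve(crossprod(A))
  S_w - (S_w %*% A) %*% (G %*% t(A))
}

#' Spatio-temporal (spectral) nulling
#'
#' Nulls the circular convolution of the stimulus with full spatio-temporal
#' filters: per pixel the stimulus is Fourier transformed over time, and at
#' each temporal frequency the complex spatial vector is projected onto the
#' orthogonal complement of the filters' spatial content at that frequency.
#' Conjugate symmetry is preserved, so the inverse transform is real. For
#' space-time separable filters this reproduces [spatial_null()] applied
#' with the spatial factors.
#'
#' @param S_w T x D stimulus frames.
#' @param a_list list of D x L spatio-temporal filters (one per cell), or a
#'   single matrix.
#' @param zero_tol frequencies where a filter's temporal content is below
#'   `zero_tol` times its maximum impose no constraint for that cell.
#' @return T x D real matrix whose circular convolution with each filter is
#'   (numerically) zero at all times.
#' @export
spectral_null <- function(S_w, a_list, zero_tol = 1e-12) {
  S_w <- as_frames(S_w)
  if (is.matrix(a_list)) a_list <- list(a_list)
  Tn <- nrow(S_w); D <- ncol(S_w)
  L <- ncol(a_list[[1]])
  if (Tn < L) stop("stimulus shorter than the filter")
  # temporal DFT of each filter, zero-padded to T: D x T complex per cell
  At <- lapply(a_list, function(a) {
    if (nrow(a) != D) stop("filter spatial dimension mismatch")
    pad <- cbind(a, matrix(0, D, Tn - ncol(a)))
    t(stats::mvfft(t(pad)))          # D x T
  })
  St <- stats::mvfft(S_w)            # T x D, DFT over time per pixel
  mags <- lapply(At, function(M) apply(Mod(M), 2, max))
  for (f in seq_len(Tn)) {
    cols <- list()
    for (c in seq_along(At)) {
      if (mags[[c]][f] > zero_tol * max(mags[[c]]))
        cols[[length(cols) + 1]] <- Conj(At[[c]][, f])
    }
    if (length(cols) == 0) next
    V <- do.call(cbind, cols)        # D x C complex
    G <- solve(Conj(t(V)) %*% V)
    s <- St[f, ]
    St[f, ] <- s - V %*% (G %*% (Conj(t(V)) %*% s))
  }
  Re(stats::mvfft(St, inverse = TRUE)) / Tn
}

# per-pixel variance-sphere projection: rescale each mean-removed pixel
# time series to the target variance (variance with denominator T)
project_variance <- function(S, var_target) {
  Tn <- nrow(S)
  mu <- colMeans(S)
  Z <- sweep(S, 2, mu)
  nrm <- sqrt(colSums(Z^2))
  target <- sqrt(Tn * var_target)
  sc <- ifelse(nrm > 0, target / nrm, 0)
  sweep(Z, 2, sc, `*`) + matrix(mu, Tn, length(mu), byrow = TRUE)
}

#' Enforce display and contrast constraints on a null stimulus
#'
#' Dykstra-style cyclic projections onto three constraint sets: the null
#' space of the receptive fields (affine), the display box `[lo, hi]`
#' (convex), and the per-pixel temporal variance sphere (rescaling each
#' mean-removed pixel trace to the target variance; non-convex, so
#' convergence is monitored empirically rather than guaranteed). The box
#' projection is applied last in each cycle so the returned frames always
#' respect the display range.
#'
#' @param S T x D stimulus (typically the output of [spatial_null()]).
#' @param A D x C receptive-field matrix to stay orthogonal to.
#' @param lo,hi display range (defaults -0.5, 0.5).
#' @param var_target per-pixel temporal variance to preserve (scalar or
#'   length-D); default: the input's mean per-pixel variance.
#' @param max_iter maximum Dykstra cycles.
#' @param tol convergence tolerance on the worst constraint residual,
#'   relative to `sqrt(mean(S^2))`.
#' @return The constrained stimulus with attribute `residuals`: a list with
#'   `orthogonality` (max |A'S| over frames), `box` (max excess), `variance`
#'   (max relative deviation), `iterations` and `converged`.
#' @export
enforce_constraints <- function(S, A, lo = -0.5, hi = 0.5, var_target = NULL,
                                max_iter = 200, tol = 1e-8) {
  S <- as_frames(S)
  A <- cbind(A)
  Tn <- nrow(S)
  if (is.null(var_target)) {
    v <- colSums(sweep(S, 2, colMeans(S))^2) / Tn
    var_target <- rep(mean(v), ncol(S))
  } else if (length(var_target) == 1) {
    var_target <- rep(var_target, ncol(S))
  }
  G <- solve(crossprod(A))
  proj_null <- function(M) M - (M %*% A) %*% (G %*% t(A))
  scaleS <- sqrt(mean(S^2))

  P1 <- matrix(0, Tn, ncol(S)); P2 <- P1; P3 <- P1  # Dykstra increments
  X <- S
  resid <- c(Inf, Inf, Inf)
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    Y <- proj_null(X + P1);                 P1 <- X + P1 - Y
    Z <- project_variance(Y + P2, var_target); P2 <- Y + P2 - Z
    Xn <- pmin(pmax(Z + P3, lo), hi);       P3 <- Z + P3 - Xn
    X <- Xn
    orth <- max(abs(X %*% A))
    box <- max(0, max(X - hi), max(lo - X))
    vv <- colSums(sweep(X, 2, colMeans(X))^2) / Tn
    varres <- max(abs(vv - var_target) / var_target)
    resid <- c(orth / scaleS, box, varres)
    if (max(resid) < tol) break
  }
  attr(X, "residuals") <- list(orthogonality = max(abs(X %*% A)),
                               box = resid[2], variance = resid[3],
                               iterations = it,
                               converged = max(resid) < tol)
  X
}

#' Quantize a stimulus to 8-bit display levels
#'
#' Affine map of `[lo, hi]` onto 0..255 followed by round-half-even, so the
#' per-entry quantization error is at most `(hi - lo) / 510`.
#'
#' @param S numeric frames within `[lo, hi]`.
#' @param lo,hi display range.
#' @return Integer matrix of levels 0..255, with attributes `lo`, `hi` for
#'   inverting the map.
#' @export
quantize_8bit <- function(S, lo = -0.5, hi = 0.5) {
  S <- as_frames(S)
  if (any(S < lo - 1e-12) || any(S > hi + 1e-12))
    stop("stimulus exceeds the display range")
  q <- round((pmin(pmax(S, lo), hi) - lo) / (hi - lo) * 255)  # round-half-even
  storage.mode(q) <- "integer"
  attr(q, "lo") <- lo; attr(q, "hi") <- hi
  q
}

#' Map 8-bit levels back to contrast units
#'
#' @param q integer frames from [quantize_8bit()].
#' @param lo,hi display range (defaults read from attributes).
#' @return Numeric frames in `[lo, hi]`.
#' @export
dequantize_8bit <- function(q, lo = attr(q, "lo"), hi = attr(q, "hi")) {
  lo + (hi - lo) * (unclass(q) / 255)
}
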