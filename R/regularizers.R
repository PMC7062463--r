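#' Pixel neighborhood graph of a stimulus grid
#'
#' Adjacency lists over grid pixels (column-major pixel indexing, matching
#' `matrix()`), used by the locally normalized L1 regularizer. 4-connected
#' by default; 8-connected optional. Neighborhoods exclude the pixel itself
#' and are truncated at grid borders.
#'
#' @param grid_shape integer `c(rows, cols)`.
#' @param connectivity 4 or 8.
#' @return An object of class `neighborhood_graph`: a list of integer
#'   vectors, one per pixel.
#' @export
neighborhood_graph <- function(grid_shape, connectivity = 4) {
  nr <- as.integer(grid_shape[1]); nc <- as.integer(grid_shape[2])
  off <- if (connectivity == 4) {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  } else if (connectivity == 8) {
    cbind(rep(-1:1, 3), rep(-1:1, each = 3))[-5, ]
  } else stop("connectivity must be 4 or 8")
  nbr <- vector("list", nr * nc)
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    ii <- i + off[, 1]; jj <- j + off[, 2]
    ok <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
    nbr[[(j - 1L) * nr + i]] <- (jj[ok] - 1L) * nr + ii[ok]
  }
  structure(nbr, class = "neighborhood_graph", grid_shape = c(nr, nc))
}

#' Soft-thresholding (L1 proximal) operator
#'
#' Elementwise `max(v - lam, 0) - max(-v - lam, 0)`, the proximal operator
#' of `lam * sum_i |v_i|`.
#'
#' @param v numeric vector.
#' @param lam threshold, >= 0. May be a vector for per-element thresholds.
#' @return Shrunk vector of the same length.
#' @export
prox_l1 <- function(v, lam) {
  if (any(lam < 0)) stop("lam must be >= 0")
  pmax(v - lam, 0) - pmax(-v - lam, 0)
}

#' Local-normalization weights for the LNL1 regularizer
#'
#' Per-pixel weights `a_i = 1 / (eps + sum_{j in nbr(i)} |k_j|)`: pixels
#' surrounded by strong neighbors get small weights (little shrinkage),
#' isolated pixels get weights up to `1/eps` (strong suppression).
#'
#' @param k filter vector over the grid.
#' @param eps positive stabilizer (default 0.01, small relative to typical
#'   nonzero filter values, which are of order one).
#' @param nbr a [neighborhood_graph()].
#' @return Positive weight vector.
#' @export
lnl1_weights <- function(k, eps = 0.01, nbr) {
  if (eps <= 0) stop("eps must be > 0")
  ak <- abs(k)
  nbr_sum <- vapply(nbr, function(j) sum(ak[j]), numeric(1))
  1 / (eps + nbr_sum)
}

#' Proximal step for the locally normalized L1 penalty
#'
#' One majorize-minimize step: the LNL1 penalty is linearized around the
#' input filter, giving a weighted L1 norm whose proximal operator is
#' per-pixel soft thresholding with threshold `a_i * lam`, where the `a_i`
#' are computed from the *input* `k` (one Taylor step per clustering
#' iteration).
#'
#' @inheritParams lnl1_weights
#' @param lam regularization strength, >= 0.
#' @return Shrunk filter vector.
#' @export
prox_lnl1 <- function(k, lam, eps = 0.01, nbr) {
  if (lam < 0) stop("lam must be >= 0")
  if (lam == 0) return(k)
  prox_l1(k, lnl1_weights(k, eps, nbr) * lam)
}

#' Locally normalized L1 penalty value
#'
#' `sum_i |k_i| / (eps + sum_{j in nbr(i)} |k_j|)`. Unlike the plain L1
#' norm, this penalty depends on the spatial arrangement of the filter: a
#' contiguous blob is cheaper than the same values scattered over the grid.
#'
#' @inheritParams lnl1_weights
#' @return Scalar penalty.
#' @export
lnl1_penalty <- function(k, eps = 0.01, nbr) {
  sum(abs(k) * lnl1_weights(k, eps, nbr))
}

# resolve a proximal operator and matching penalty from a reg setting
# reg_kind in c("none", "l1", "lnl1")
make_regularizer <- function(reg_kind, lam, eps = 0.01, grid_shape = NULL,
                             connectivity = 4) {
  reg_kind <- match.arg(reg_kind, c("none", "l1", "lnl1"))
  if (reg_kind == "none" || lam == 0)
    return(list(prox = NULL, penalty = function(k) 0, kind = "none", lam = 0))
  if (reg_kind == "l1")
    return(list(prox = function(k) prox_l1(k, lam),
                penalty = function(k) lam * sum(abs(k)),
                kind = "l1", lam = lam))
  if (is.null(grid_shape))
    stop("lnl1 regularization requires grid_shape")
  nbr <- neighborhood_graph(grid_shape, connectivity)
  list(prox = function(k) prox_lnl1(k, lam, eps, nbr),
       penalty = function(k) lam * lnl1_penalty(k, eps, nbr),
       kind = "lnl1", lam = lam)
}
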