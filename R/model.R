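#' Generator signal of a subunit bank
#'
#' Computes the summed exponentiated subunit drive
#' `G_t = sum_n w_n exp(K_n . X_t)` for every stimulus frame. This is the
#' model's firing rate before the output nonlinearity.
#'
#' @param bank a [subunit_bank()].
#' @param X a [stimulus_matrix()] or bare T x D matrix.
#' @return Numeric vector of length T, strictly positive whenever some
#'   weight is positive.
#' @export
generator_signal <- function(bank, X) {
  Xf <- as_frames(X)
  if (ncol(Xf) != ncol(bank$K))
    stop(sprintf("stimulus dimension %d does not match filter dimension %d",
                 ncol(Xf), ncol(bank$K)))
  E <- exp(Xf %*% t(bank$K))      # T x N
  drop(E %*% bank$w)
}

#' Model firing rate
#'
#' Expected spike count per bin: `lambda_t = g(G_t)` with `G_t` the
#' generator signal. Bin width is absorbed into the subunit weights, so
#' rates are per-bin expected counts.
#'
#' @param model a [subunit_model()].
#' @param X stimulus frames.
#' @return Nonnegative numeric vector of length T.
#' @export
firing_rate <- function(model, X) {
  G <- generator_signal(model$bank, X)
  apply_nonlinearity(model$nonlinearity, G)
}

#' Sample Poisson spikes from a rate vector
#'
#' @param rates nonnegative expected counts per bin.
#' @param bin_width bin width in seconds (metadata only).
#' @param seed optional integer seed for reproducible draws.
#' @return A [spike_counts()] object.
#' @export
sample_spikes <- function(rates, bin_width = 1 / 120, seed = NULL) {
  if (any(!is.finite(rates)) || any(rates < 0)) stop("rates must be finite and nonnegative")
  counts <- with_seed(seed, stats::rpois(length(rates), rates))
  spike_counts(counts, bin_width = bin_width)
}

#' Poisson negative log-likelihood per bin
#'
#' `(1/T) sum_t lambda_t - (1/T) sum_t Y_t log(lambda_t)`. The data-only
#' `log(Y_t!)` terms are omitted, so values are comparable across models fit
#' to the same data but not across datasets.
#'
#' @param model a [subunit_model()], or a precomputed rate vector.
#' @param X stimulus frames (ignored when `model` is a rate vector).
#' @param Y spike counts.
#' @return Scalar negative log-likelihood per bin.
#' @export
nll <- function(model, X, Y) {
  Yc <- as_counts(Y)
  lam <- if (is.numeric(model)) model else {
    check_aligned(X, Y)
    firing_rate(model, X)
  }
  if (length(lam) != length(Yc)) stop("rate and count lengths differ")
  spk <- Yc > 0
  if (any(lam[spk] <= 0))
    stop("degenerate model: zero firing rate in a bin with observed spikes")
  mean(lam) - sum(Yc[spk] * log(lam[spk])) / length(Yc)
}

#' Expected (approximate) negative log-likelihood
#'
#' The analytic objective the clustering optimizes: the mean-rate term is
#' replaced by its expectation under a standard Gaussian stimulus using the
#' Gaussian moment generating function,
#' `sum_n w_n exp(K_n.K_n / 2) - (1/T) sum_{t: Y_t>0} Y_t log G_t`.
#' Only spike-triggered frames enter the data term, which is what makes the
#' clustering updates cheap.
#'
#' @param bank a [subunit_bank()].
#' @param X_spike S x D matrix of spike-triggered frames (rows with
#'   `Y_t > 0`), or a full stimulus together with full `Y_spike`.
#' @param Y_spike spike counts for those frames.
#' @param T_total total number of stimulus bins in the recording.
#' @return Scalar approximate negative log-likelihood per bin.
#' @export
expected_nll <- function(bank, X_spike, Y_spike, T_total) {
  Xs <- as_frames(X_spike)
  Ys <- as_counts(Y_spike)
  if (nrow(Xs) != length(Ys)) stop("X_spike and Y_spike lengths differ")
  keep <- Ys > 0
  Xs <- Xs[keep, , drop = FALSE]
  Ys <- Ys[keep]
  rate_term <- sum(bank$w * exp(rowSums(bank$K^2) / 2))
  if (length(Ys) == 0) return(rate_term)
  G <- generator_signal(bank, Xs)
  rate_term - sum(Ys * log(G)) / T_total
}

#' Average response contribution of one subunit
#'
#' `w * exp(k.k / 2)`: the expected contribution of a subunit to the firing
#' rate over a standard Gaussian stimulus ensemble, ignoring the output
#' nonlinearity. Used to rank and display subunits.
#'
#' @param k filter vector, or an N x D matrix (one filter per row).
#' @param w weight (vector when `k` is a matrix).
#' @return Scalar or vector of strengths.
#' @export
subunit_strength <- function(k, w) {
  if (is.matrix(k)) w * exp(rowSums(k^2) / 2) else w * exp(sum(k^2) / 2)
}
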