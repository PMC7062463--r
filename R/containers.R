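#' Stimulus matrix container
#'
#' Bundles prefiltered, standardized stimulus frames with their timing and
#' spatial layout. Rows are time bins, columns are pixels (or generic
#' stimulus dimensions, e.g. space x time bins for one-dimensional stimuli).
#' The estimator assumes columns are approximately standard normal, which is
#' what temporal prefiltering of binary white noise followed by per-pixel
#' standardization produces; construction checks per-column mean and
#' standard deviation when `check_standardized = TRUE`.
#'
#' @param frames numeric matrix, T x D.
#' @param bin_width bin width in seconds (default 1/120).
#' @param grid_shape integer `c(rows, cols)` used to reshape filters into
#'   images, or `NULL` for non-spatial stimuli.
#' @param check_standardized logical; verify the mean/sd invariants.
#' @return An object of class `stimulus_matrix` (a list with elements
#'   `frames`, `bin_width`, `grid_shape`).
#' @export
stimulus_matrix <- function(frames, bin_width = 1 / 120, grid_shape = NULL,
                            check_standardized = TRUE) {
  frames <- as.matrix(frames)
  stopifnot_finite(frames, "frames")
  if (!is.null(grid_shape)) {
    grid_shape <- as.integer(grid_shape)
    if (length(grid_shape) != 2 || prod(grid_shape) != ncol(frames))
      stop("grid_shape must have two entries whose product equals ncol(frames)")
  }
  if (isTRUE(check_standardized) && nrow(frames) > 1) {
    mu <- colMeans(frames)
    sdv <- apply(frames, 2, stats::sd)
    if (any(abs(mu) > 0.05) || any(abs(sdv - 1) > 0.05))
      stop("frames are not standardized: per-column mean must be within 0.05 of 0 and sd within 0.05 of 1 (use prefilter_and_standardize(), or check_standardized = FALSE)")
  }
  structure(list(frames = frames, bin_width = bin_width, grid_shape = grid_shape),
            class = "stimulus_matrix")
}

#' @export
print.stimulus_matrix <- function(x, ...) {
  cat(sprintf("<stimulus_matrix> %d frames x %d dims, bin %.4g s", nrow(x$frames),
              ncol(x$frames), x$bin_width))
  if (!is.null(x$grid_shape))
    cat(sprintf(", grid %dx%d", x$grid_shape[1], x$grid_shape[2]))
  cat("\n")
  invisible(x)
}

#' Spike-count container
#'
#' Binned spike counts aligned to stimulus frames.
#'
#' @param counts nonnegative integer vector, one entry per stimulus bin.
#' @param bin_width bin width in seconds.
#' @return An object of class `spike_counts`.
#' @export
spike_counts <- function(counts, bin_width = 1 / 120) {
  counts <- as.numeric(counts)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be finite nonnegative integers")
  structure(list(counts = counts, bin_width = bin_width), class = "spike_counts")
}

#' @export
print.spike_counts <- function(x, ...) {
  cat(sprintf("<spike_counts> %d bins, %d spikes, mean rate %.2f /s\n",
              length(x$counts), sum(x$counts),
              mean(x$counts) / x$bin_width))
  invisible(x)
}

# coerce helpers: accept bare matrices/vectors in computational code
as_frames <- function(X) if (inherits(X, "stimulus_matrix")) X$frames else as.matrix(X)
as_counts <- function(Y) if (inherits(Y, "spike_counts")) Y$counts else as.numeric(Y)

check_aligned <- function(X, Y) {
  Xf <- as_frames(X); Yc <- as_counts(Y)
  if (nrow(Xf) != length(Yc))
    stop(sprintf("stimulus has %d frames but spike counts have %d bins",
                 nrow(Xf), length(Yc)))
  invisible(TRUE)
}

#' Subunit filter bank
#'
#' A set of N linear subunit filters with nonnegative output weights. The
#' log-weights play the role of the additive biases used by the hierarchical
#' (splitting) variant of the estimator.
#'
#' @param K numeric matrix, N x D (one filter per row).
#' @param w nonnegative numeric vector of length N.
#' @return An object of class `subunit_bank`.
#' @export
subunit_bank <- function(K, w) {
  K <- rbind(K)
  w <- as.numeric(w)
  stopifnot_finite(K, "K")
  if (length(w) != nrow(K)) stop("length(w) must equal nrow(K)")
  if (any(!is.finite(w)) || any(w < 0)) stop("w must be finite and nonnegative")
  structure(list(K = K, w = w), class = "subunit_bank")
}

#' @export
print.subunit_bank <- function(x, ...) {
  s <- subunit_strength(x$K, x$w)
  cat(sprintf("<subunit_bank> N=%d subunits, D=%d; strengths: %s\n",
              nrow(x$K), ncol(x$K),
              paste(signif(s, 3), collapse = ", ")))
  invisible(x)
}

n_subunits <- function(bank) nrow(bank$K)

#' Saturating output nonlinearity
#'
#' The final pointwise nonlinearity `g(x) = x^a / (1 + b x)` applied to the
#' summed, weighted subunit drive (`x >= 0`). With `a = 1, b = 0` the model
#' output is the raw generator signal; `b > 0` saturates towards `x^(a-1)/b`
#' for large drive. `g` is nondecreasing on the operating range provided
#' `a >= b*x/(1+b*x)` there, which holds for the fitted regimes (a near 1).
#'
#' @param a exponent, > 0.
#' @param b saturation coefficient, >= 0.
#' @return An object of class `output_nonlinearity`.
#' @export
output_nonlinearity <- function(a = 1, b = 0) {
  if (!is.finite(a) || a <= 0) stop("a must be > 0")
  if (!is.finite(b) || b < 0) stop("b must be >= 0")
  structure(list(a = a, b = b), class = "output_nonlinearity")
}

apply_nonlinearity <- function(nl, x) x^nl$a / (1 + nl$b * x)

#' @export
print.output_nonlinearity <- function(x, ...) {
  cat(sprintf("<output_nonlinearity> g(x) = x^%.4g / (1 + %.4g x)\n", x$a, x$b))
  invisible(x)
}

#' Full subunit response model
#'
#' A subunit bank plus output nonlinearity and the metadata needed to map
#' filters back to stimulus pixels. The optional shared temporal filter is
#' the time course used to prefilter the stimulus (space-time separability
#' assumption).
#'
#' @param bank a [subunit_bank()].
#' @param nonlinearity an [output_nonlinearity()].
#' @param time_course optional numeric vector (temporal filter, most recent
#'   lag first).
#' @param grid_shape optional integer `c(rows, cols)`.
#' @param bin_width bin width in seconds.
#' @return An object of class `subunit_model`.
#' @export
subunit_model <- function(bank, nonlinearity = output_nonlinearity(),
                          time_course = NULL, grid_shape = NULL,
                          bin_width = 1 / 120) {
  if (!inherits(bank, "subunit_bank")) stop("bank must be a subunit_bank")
  if (!inherits(nonlinearity, "output_nonlinearity"))
    stop("nonlinearity must be an output_nonlinearity")
  if (!is.null(grid_shape) && prod(grid_shape) != ncol(bank$K))
    stop("grid_shape inconsistent with filter dimension")
  structure(list(bank = bank, nonlinearity = nonlinearity,
                 time_course = time_course,
                 grid_shape = if (is.null(grid_shape)) NULL else as.integer(grid_shape),
                 bin_width = bin_width),
            class = "subunit_model")
}

#' @export
print.subunit_model <- function(x, ...) {
  cat(sprintf("<subunit_model> N=%d subunits, D=%d, g(x)=x^%.3g/(1+%.3gx)\n",
              nrow(x$bank$K), ncol(x$bank$K), x$nonlinearity$a, x$nonlinearity$b))
  invisible(x)
}
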