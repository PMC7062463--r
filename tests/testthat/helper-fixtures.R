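# shared in-code fixtures for the test suite

# standard-normal stimulus frames
gauss_stim <- function(T_frames, D, seed = 1) {
  withr_seed <- function(s, e) stclust:::with_seed(s, e)
  withr_seed(seed, matrix(rnorm(T_frames * D), T_frames, D))
}

# a small toy recording: 3-subunit cell in 2-D Gaussian stimulus space
toy_recording <- function(T_frames = 4e4, seed = 1, n_subunits = 3,
                          mean_rate = 0.08) {
  toy <- toy_cell(n_subunits, mean_rate = mean_rate, seed = seed)
  X <- gauss_stim(T_frames, ncol(attr(toy, "true_bank")$K), seed = seed + 1)
  rates <- firing_rate(toy, X)
  Y <- sample_spikes(rates, seed = seed + 2)
  list(model = toy, truth = attr(toy, "true_bank"), X = X, Y = Y,
       rates = rates)
}

# a small calibrated RGC-simulator recording with preprocessed stimulus
rgc_recording <- function(minutes = 2, pixel_gu = 6, contrast = 0.48,
                          seed = 1) {
  cell <- rgc_cell(pixel_gu = pixel_gu, seed = seed)
  Tn <- round(minutes * 60 * 120)
  raw <- white_noise(Tn, cell$grid$grid_shape, contrast = contrast,
                     seed = seed + 100)
  sim <- simulate_cell(cell, raw, contrast = contrast, seed = seed + 200)
  list(cell = sim$cell, raw = raw, rates = sim$rates, Y = sim$spikes)
}

# crop indices for the simulator cell's true RF support (+1 pixel border)
true_rf_window <- function(cell, frac = 0.05) {
  D0 <- cell$grid$grid_shape[1]
  rfimg <- matrix(colSums(cell$true_subunits), D0, D0)
  supp <- rfimg > frac * max(rfimg)
  rr <- range(which(rowSums(supp) > 0)); cc <- range(which(colSums(supp) > 0))
  rows <- max(1, rr[1] - 1):min(D0, rr[2] + 1)
  cols <- max(1, cc[1] - 1):min(D0, cc[2] + 1)
  list(keep = as.vector(matrix(seq_len(D0^2), D0, D0)[rows, cols]),
       grid_shape = c(length(rows), length(cols)))
}

# surrogate trace monotone (within tolerance)?
trace_monotone <- function(tr, tol = 1e-8) {
  all(diff(tr) <= tol * pmax(1, abs(tr[-1])))
}

# best assignment between two filter banks by exhaustive enumeration of
# permutations (oracle for greedy matching tests); returns min matched cosine
best_match_min_cos <- function(KA, KB) {
  normr <- function(M) M / sqrt(rowSums(M^2))
  C <- normr(KA) %*% t(normr(KB))
  n <- nrow(KA)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- -Inf; best_min <- NA
  for (p in perms(seq_len(n))) {
    tot <- sum(C[cbind(seq_len(n), p)])
    if (tot > best) { best <- tot; best_min <- min(C[cbind(seq_len(n), p)]) }
  }
  best_min
}

# two-cell pixel-grid ground truth with one shared subunit: cell A drives
# subunits {1, 2, shared}, cell B drives {3, 4, shared} on a 10 x 6 grid
shared_truth <- function(filter_norm = 1.5, mean_rate = 0.1, seed = 1) {
  nr <- 6; nc <- 10
  px <- rep(seq_len(nr), nc); py <- rep(seq_len(nc), each = nr)
  blob <- function(cx, cy, sd = 1.1) {
    k <- exp(-((px - cx)^2 + (py - cy)^2) / (2 * sd^2))
    filter_norm * k / sqrt(sum(k^2))
  }
  K <- rbind(blob(2, 2), blob(5, 2),            # cell A only
             blob(2, 9), blob(5, 9),            # cell B only
             blob(3.5, 5.5))                    # shared
  w1 <- mean_rate / sum(exp(rowSums(K[c(1, 2, 5), ]^2) / 2))
  banks <- list(A = subunit_bank(K[c(1, 2, 5), ], rep(w1, 3)),
                B = subunit_bank(K[c(3, 4, 5), ], rep(w1, 3)))
  list(K = K, banks = banks, grid_shape = c(nr, nc))
}

shared_recording <- function(T_frames = 1e5, seed = 1) {
  tr <- shared_truth(seed = seed)
  X <- gauss_stim(T_frames, 60, seed = seed + 1)
  Y <- lapply(tr$banks, function(b)
    sample_spikes(generator_signal(b, X), seed = seed + 2)$counts)
  c(tr, list(X = X, Y = Y))
}

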