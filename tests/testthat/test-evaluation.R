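test_that("partitions are disjoint, covering, with a contiguous test tail", {
  p <- make_partition(100, seed = 1)
  expect_equal(p$test, 91:100)
  expect_equal(sort(c(p$train, p$validation, p$test)), 1:100)
  expect_length(intersect(p$train, p$validation), 0)
  expect_identical(make_partition(100, seed = 2), make_partition(100, seed = 2))
  expect_error(make_partition(5, test_frac = 0.9, val_frac = 0.9), "small")
})

test_that("validation likelihood selects the true subunit count", {
  # single-subunit (LN) truth: N* = 1
  rec1 <- toy_recording(T_frames = 4e4, seed = 2, n_subunits = 1,
                        mean_rate = 0.1)
  sel1 <- select_model(rec1$X, rec1$Y, N_grid = 1:3, repeats = 3, seed = 3)
  expect_equal(sel1$N_star, 1)
  # grid sanity: the selected setting is within one SE of the best mean
  agg <- sel1$summary
  sel_row <- agg[agg$N == sel1$N_star & agg$lam == sel1$lam_star, ]
  imax <- which.max(agg$val_ll)
  expect_gte(sel_row$val_ll, agg$val_ll[imax] - agg$se[imax])
  # three-subunit truth: N* = 3 (single run; the multi-seed success-rate
  # version of this check lives in the acceptance suite)
  rec3 <- toy_recording(T_frames = 6e4, seed = 4)
  sel3 <- select_model(rec3$X, rec3$Y, N_grid = 1:4, repeats = 3, seed = 5)
  expect_equal(sel3$N_star, 3)
})

test_that("psth smooths the trial mean and conserves counts", {
  set.seed(6)
  rast <- matrix(rpois(20 * 400, 0.3), 20, 400)
  # sigma -> 0 recovers the raw trial mean
  expect_equal(psth(rast, sigma = 0), colMeans(rast) / (1 / 120))
  p <- psth(rast)
  # kernel-mass check: total rate conserved within 0.1% (interior bins)
  expect_lt(abs(sum(p[30:370]) - sum(colMeans(rast)[30:370] / (1 / 120))) /
              sum(p[30:370]), 0.001)
  # identical trials: smoothed single trial
  one <- rpois(300, 0.5)
  same <- matrix(rep(one, each = 10), 10, 300)
  expect_equal(psth(same), psth(rbind(one)))
})

test_that("psth_correlation is high for the generating model, NA otherwise", {
  toy <- toy_cell(3, mean_rate = 0.15, seed = 7)
  X <- gauss_stim(1500, 2, seed = 8)
  lam <- firing_rate(toy, X)
  rast <- t(sapply(1:30, function(r)
    sample_spikes(lam, seed = 100 + r)$counts))
  r <- psth_correlation(toy, X, rast, seed = 9)
  expect_gt(r, 0.9)
  expect_warning(rc <- psth_correlation(rep(0.5, 1500), X,
                                        matrix(1, 5, 1500), seed = 10),
                 "zero-variance")
  expect_true(is.na(rc))
})

test_that("response structure measures PSTH variance with known values", {
  expect_equal(response_structure(matrix(1, 10, 200))$structure, 0)
  # sinusoidal rate of amplitude a: variance a^2/2 times the squared
  # Gaussian-smoothing attenuation exp(-(2 pi f sigma)^2 / 2)^2
  bw <- 1 / 120; f <- 2; Tn <- 2400
  tt <- (seq_len(Tn) - 1) * bw
  a <- 20
  lam <- (30 + a * sin(2 * pi * f * tt)) * bw
  rast <- t(sapply(1:400, function(r) sample_spikes(lam, seed = r)$counts))
  sigma <- 1 / 60
  atten <- exp(-(2 * pi * f * sigma)^2 / 2)
  rs <- response_structure(rast, sigma = sigma)
  expect_lt(abs(rs$structure - a^2 * atten^2 / 2) / (a^2 * atten^2 / 2), 0.15)
  # structure converges with increasing trial count
  s_few <- response_structure(rast[1:5, , drop = FALSE], sigma = sigma)$structure
  s_many <- rs$structure
  expect_gt(s_few, s_many)   # fewer trials inflate the variance
  # ratio statistic against a reference raster
  expect_equal(response_structure(rast, sigma = sigma,
                                  reference = rast)$ratio, 1)
})

test_that("stimulus-RF angles behave geometrically", {
  rf <- c(1, 0, 0, 0)
  expect_equal(rf_stimulus_angle(rbind(3 * rf), rf), 0)
  expect_equal(rf_stimulus_angle(rbind(c(0, 1, 0, 0)), rf), 90)
  expect_equal(rf_stimulus_angle(rbind(-rf), rf), 180)
  expect_true(is.na(rf_stimulus_angle(rbind(rep(0, 4)), rf)))
  # concentration near 90 degrees in high dimension
  X <- gauss_stim(2000, 400, seed = 11)
  ang <- rf_stimulus_angle(X, rnorm(400))
  expect_lt(abs(mean(ang) - 90), 1)
  expect_lt(sd(ang), 5)
})

test_that("2-D Gaussian fits recover parameters and flag degeneracy", {
  nr <- 11; nc <- 13
  px <- rep(seq_len(nc), each = nr); py <- rep(seq_len(nr), nc)
  img <- matrix(0.8 * exp(-((px - 7)^2 / (2 * 2.5^2) +
                              (py - 5)^2 / (2 * 1.5^2))), nr, nc)
  g <- gaussian2d_fit(img)
  expect_lt(g$mse, 1e-8)
  expect_equal(unname(g$center), c(7, 5), tolerance = 1e-3)
  expect_equal(sqrt(diag(g$cov)), c(2.5, 1.5), tolerance = 1e-2)
  # pixel-shuffled image fits strictly worse
  set.seed(12)
  img_sh <- matrix(sample(as.vector(img)), nr, nc)
  expect_gt(gaussian2d_fit(img_sh)$mse, g$mse * 100)
  expect_true(gaussian2d_fit(matrix(0, 5, 5))$flagged)
})

test_that("permutation control concentrates real subunits near quantile 0", {
  toy5 <- toy_cell(5, seed = 13)
  K <- attr(toy5, "true_bank")$K
  pc <- permutation_control(K, c(8, 8), n_perm = 40, seed = 14)
  expect_lt(max(pc$quantiles), 0.1)
  expect_false(pc$degenerate)
  expect_error(permutation_control(K, c(8, 8), n_perm = 0), "positive")
  # identical subunits: degenerate control flagged
  Ksame <- K[rep(1, 3), ]
  pc2 <- permutation_control(Ksame, c(8, 8), n_perm = 5, seed = 15)
  expect_true(pc2$degenerate)
})

test_that("the tiling statistic normalizes distances by joint SDs", {
  gfit <- function(cx, cy, cov) structure(
    list(center = c(x = cx, y = cy), cov = cov, amplitude = 1, mse = 0,
         flagged = FALSE), class = "gaussian2d_fit")
  two <- list(gfit(0, 0, diag(2)), gfit(3, 0, diag(2)))
  expect_equal(tiling_statistic(two), c(3, 3))
  # anisotropic oracle: sd along u = sqrt(u' Sigma u)
  S1 <- matrix(c(4, 1, 1, 1), 2); S2 <- matrix(c(1, 0, 0, 9), 2)
  pair <- list(gfit(0, 0, S1), gfit(5, 5, S2))
  u <- c(1, 1) / sqrt(2)
  d <- sqrt(50)
  expected <- d / sqrt(sqrt(drop(t(u) %*% S1 %*% u)) *
                         sqrt(drop(t(u) %*% S2 %*% u)))
  expect_equal(tiling_statistic(pair), rep(expected, 2), tolerance = 1e-12)
  expect_error(tiling_statistic(list(gfit(0, 0, diag(2)))), "at least two")
})

test_that("post-saccade masks cover exactly the windows after each event", {
  m <- saccade_window_mask(c(0, 1), T_total = 240, bin_width = 1 / 120,
                           window = 0.25)
  expect_true(all(m[1:30]))          # 250 ms = 30 bins at 120 Hz
  expect_false(any(m[32:120]))
  expect_true(all(m[121:150]))
  expect_false(any(m[152:240]))
  expect_equal(saccade_window_mask(numeric(0), 10), rep(FALSE, 10))
})
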