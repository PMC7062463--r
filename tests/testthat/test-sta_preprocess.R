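test_that("compute_sta equals the double-loop oracle and handles edges", {
  set.seed(1)
  raw <- matrix(rnorm(60), 20, 3)
  Y <- rpois(20, 0.5); Y[3] <- 2
  sta <- compute_sta(raw, Y, L = 4)
  oracle <- matrix(0, 3, 4)
  for (d in 1:3) for (l in 1:4) {
    s <- 0
    for (t in 1:20) if (t - (l - 1) >= 1) s <- s + Y[t] * raw[t - (l - 1), d]
    oracle[d, l] <- s / sum(Y)
  }
  expect_equal(sta$values, oracle, tolerance = 1e-12)
  # single spike: STA is the preceding stimulus
  Y1 <- rep(0, 20); Y1[10] <- 1
  s1 <- compute_sta(raw, Y1, L = 3)
  expect_equal(s1$values, t(raw[10:8, ]))
  # constant spiking on zero-mean noise: entries shrink to ~0
  big <- matrix(rnorm(2e4), 1e4, 2)
  s0 <- compute_sta(big, rep(2, 1e4), L = 2)
  expect_lt(max(abs(s0$values)), 0.05)
  expect_error(compute_sta(raw, rep(0, 20)), "zero total spikes")
})

test_that("receptive_field_mask keeps the largest component with a border", {
  expect_error(receptive_field_mask(matrix(0, 5, 5)), "no receptive field")
  # one hot pixel over unit-scale noise: singleton mask, 3x3 crop
  set.seed(2)
  img <- matrix(rnorm(81), 9, 9)
  img[5, 5] <- 30
  rf <- receptive_field_mask(img)
  expect_equal(sum(rf$mask), 1)
  expect_equal(rf$crop$rows, 4:6)
  expect_equal(rf$crop$cols, 4:6)
  # two disjoint blobs: only the larger is retained
  img2 <- matrix(rnorm(144), 12, 12)
  img2[2:4, 2:4] <- 40          # 9 pixels
  img2[9:10, 9] <- 40           # 2 pixels
  rf2 <- receptive_field_mask(img2)
  expect_equal(sum(rf2$mask), 9)
  expect_false(any(rf2$mask[9:10, 9]))
})

test_that("time_course sign-aligns pixels and recovers rank-1 structure", {
  tc_true <- stclust:::cone_time_course(10)
  # single masked pixel returns its own normalized trace
  sta1 <- structure(list(values = rbind(3 * tc_true), lag_bin = 1 / 120),
                    class = "sta")
  expect_equal(time_course(sta1, TRUE), tc_true, tolerance = 1e-12)
  # traces v and -v both contribute +v after sign alignment
  sta2 <- structure(list(values = rbind(tc_true, -tc_true), lag_bin = 1 / 120),
                    class = "sta")
  expect_equal(time_course(sta2, c(TRUE, TRUE)), tc_true, tolerance = 1e-12)
  # rank-1 synthetic STA recovers the temporal factor
  set.seed(3)
  spatial <- rnorm(25) * (runif(25) < 0.4)
  vals <- outer(spatial, tc_true) + matrix(rnorm(250, sd = 1e-4), 25, 10)
  sta3 <- structure(list(values = vals, lag_bin = 1 / 120), class = "sta")
  tc_est <- time_course(sta3, spatial != 0)
  expect_gt(abs(sum(tc_est * tc_true)), 0.999)
})

test_that("prefilter_and_standardize yields standardized columns", {
  set.seed(4)
  raw <- white_noise(3000, c(3, 3), seed = 5)
  # delta filter: standardized copy of the raw stimulus
  X0 <- prefilter_and_standardize(raw, c(1, 0, 0))
  expect_equal(cor(X0$frames[, 1], raw[, 1]), 1, tolerance = 1e-12)
  # generic filter satisfies the StimulusMatrix invariants
  tc <- stclust:::cone_time_course(12)
  X <- prefilter_and_standardize(raw, tc, grid_shape = c(3, 3))
  expect_lt(max(abs(colMeans(X$frames))), 0.05)
  expect_lt(max(abs(apply(X$frames, 2, sd) - 1)), 0.05)
  expect_s3_class(X, "stimulus_matrix")
  # degenerate constant column
  raw2 <- raw; raw2[, 2] <- 0.24
  expect_error(prefilter_and_standardize(raw2, c(1, 0, 0)), "zero-variance")
})

test_that("separable_approx is the best rank-1 factorization", {
  set.seed(6)
  u <- rnorm(20); v <- rnorm(8); v <- v / sqrt(sum(v^2))
  sa <- separable_approx(u %o% v)
  expect_lt(max(abs(sa$spatial %o% sa$temporal - u %o% v)), 1e-10)
  # rank-2: Frobenius residual^2 equals the second singular value squared
  u2 <- rnorm(20); v2 <- rnorm(8)
  M <- u %o% v + 0.3 * (u2 %o% v2)
  sa2 <- separable_approx(M)
  resid2 <- sum((M - sa2$spatial %o% sa2$temporal)^2)
  expect_equal(resid2, svd(M)$d[2]^2, tolerance = 1e-8)
  # projection property
  expect_lte(sqrt(sum((sa2$spatial %o% sa2$temporal)^2)), sqrt(sum(M^2)))
  # dominant-pixel sign convention: OFF map gives negative spatial peak
  sa3 <- separable_approx(-abs(u) %o% v)
  expect_lt(sa3$spatial[which.max(abs(sa3$spatial))], 0)
})

test_that("an L = 1 STA on prefiltered stimulus is the clustering's target", {
  rec <- toy_recording(T_frames = 5000, seed = 2)
  sta <- compute_sta(rec$X, rec$Y, L = 1)
  direct <- colSums(rec$X * rec$Y$counts) / sum(rec$Y$counts)
  expect_equal(drop(sta$values), direct, tolerance = 1e-12)
})

test_that("simulator round trip: STA mask recovers the true RF support", {
  rec <- rgc_recording(minutes = 8, contrast = 0.96, seed = 3)
  sta <- compute_sta(rec$raw, rec$Y, L = 15)
  sp <- separable_approx(sta)
  rf <- receptive_field_mask(sp$spatial,
                             grid_shape = rec$cell$grid$grid_shape)
  D0 <- rec$cell$grid$grid_shape[1]
  rfimg <- matrix(colSums(rec$cell$true_subunits), D0, D0)
  truth <- rfimg > 0.25 * max(rfimg)
  # every strongly driven true pixel is inside the estimated crop window
  expect_true(all(which(rowSums(truth) > 0) %in% rf$crop$rows))
  expect_true(all(which(colSums(truth) > 0) %in% rf$crop$cols))
  # and the mask overlaps the truth substantially
  expect_gt(sum(rf$mask & truth) / sum(truth), 0.5)
})
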