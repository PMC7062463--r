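test_that("update_activations is a stable softmax over subunits", {
  X <- gauss_stim(40, 3, seed = 1)
  b1 <- subunit_bank(matrix(rnorm(3), 1, 3), 0.7)
  expect_equal(drop(update_activations(X, b1)), rep(1, 40))
  K <- matrix(rnorm(3), 1, 3)
  b3 <- subunit_bank(rbind(K, K, K), rep(0.2, 3))
  expect_equal(update_activations(X, b3), matrix(1 / 3, 40, 3))
  # naive exp/softmax oracle
  set.seed(2)
  bank <- subunit_bank(matrix(rnorm(12), 4, 3), runif(4))
  A <- update_activations(X, bank)
  naive <- t(apply(X, 1, function(x) {
    e <- bank$w * exp(drop(bank$K %*% x)); e / sum(e)
  }))
  expect_equal(A, naive, tolerance = 1e-12)
  expect_equal(rowSums(A), rep(1, 40), tolerance = 1e-9)
  # overflow safety with huge filters
  bigK <- matrix(c(400, 0, 0, -400, 0, 0), 2, 3, byrow = TRUE)
  Abig <- update_activations(X, subunit_bank(bigK, c(0.5, 0.5)))
  expect_true(all(is.finite(Abig)))
  expect_equal(rowSums(Abig), rep(1, 40))
  expect_error(update_activations(X, subunit_bank(K, 0)), "zero")
})

test_that("update_filters is the responsibility-weighted centroid", {
  set.seed(3)
  Xs <- gauss_stim(30, 4, seed = 3)
  Ys <- rpois(30, 1) + 1
  sta <- colSums(Xs * Ys) / sum(Ys)
  # all mass on one subunit: that filter is the STA
  alpha <- cbind(rep(1, 30), 0)
  expect_error(update_filters(Xs, Ys, alpha), "empty cluster")
  alpha_u <- matrix(0.5, 30, 2)
  Ku <- update_filters(Xs, Ys, alpha_u)
  expect_equal(Ku[1, ], sta, tolerance = 1e-12)
  expect_equal(Ku[2, ], sta, tolerance = 1e-12)
  # random responsibilities vs double-loop oracle
  A <- matrix(runif(60), 30, 2); A <- A / rowSums(A)
  K <- update_filters(Xs, Ys, A)
  for (n in 1:2) {
    num <- rep(0, 4); den <- 0
    for (t in 1:30) { num <- num + Ys[t] * A[t, n] * Xs[t, ]; den <- den + Ys[t] * A[t, n] }
    expect_equal(K[n, ], num / den, tolerance = 1e-12)
  }
  # prox is applied after the centroid step
  Kp <- update_filters(Xs, Ys, A, prox = function(k) prox_l1(k, 10))
  expect_true(all(Kp == 0))
})

test_that("update_weights matches the discounted responsibility mass", {
  set.seed(4)
  Ys <- rpois(25, 2) + 1
  alpha <- matrix(1, 25, 1)
  b <- subunit_bank(matrix(0, 1, 3), 1)
  expect_equal(update_weights(Ys, alpha, b, T_total = 100), sum(Ys) / 100)
  expect_equal(update_weights(2 * Ys, alpha, b, 100),
               2 * update_weights(Ys, alpha, b, 100))
})

test_that("at a converged fit, strengths decompose the mean rate and STA", {
  rec <- toy_recording(T_frames = 3e4, seed = 5)
  fit <- fit_subunits(rec$X, rec$Y, 3, seed = 6)
  # stationarity: total strength equals the mean spike rate per bin
  expect_equal(sum(subunit_strength(fit$bank$K, fit$bank$w)),
               mean(rec$Y$counts), tolerance = 1e-3)
  spk <- rec$Y$counts > 0
  expect_lt(sta_decomposition_residual(fit$bank, rec$X[spk, ],
                                       rec$Y$counts[spk]), 1e-3)
  # N = 1 is exactly the spike-triggered average
  f1 <- fit_subunits(rec$X, rec$Y, 1, seed = 6)
  expect_lt(sta_decomposition_residual(f1$bank, rec$X[spk, ],
                                       rec$Y$counts[spk]), 1e-6)
  sta_dir <- colSums(rec$X * rec$Y$counts)
  expect_gt(abs(sum(f1$bank$K[1, ] * sta_dir)) /
              sqrt(sum(f1$bank$K[1, ]^2) * sum(sta_dir^2)), 0.999)
})

test_that("the surrogate objective is non-increasing for every seed", {
  rec <- toy_recording(T_frames = 2e4, seed = 7)
  for (s in 1:4) {
    fit <- fit_subunits(rec$X, rec$Y, 3, seed = s, init = "random")
    expect_true(trace_monotone(fit$trace))
  }
  # regularized runs keep the penalized surrogate finite and the fit sane
  rec5 <- toy_recording(T_frames = 2e4, seed = 8, n_subunits = 5)
  fit5 <- fit_subunits(rec5$X, rec5$Y, 5, lam = 0.05, reg_kind = "l1",
                       seed = 9)
  expect_true(all(is.finite(fit5$trace)))
  expect_true(all(fit5$bank$w >= 0))
})

test_that("subunit recovery on the three-subunit toy is accurate", {
  rec <- toy_recording(T_frames = 2e5, seed = 10)
  fit <- fit_subunits(rec$X, rec$Y, 3, seed = 11)
  m <- match_subunits(rec$truth$K, fit$bank$K)
  expect_gt(min(m$pairs$cos), 0.95)
  # strengths are reported in decreasing order
  s <- subunit_strength(fit$bank$K, fit$bank$w)
  expect_true(all(diff(s) <= 1e-12))
})

test_that("fits are invariant to permuting the initialization indices", {
  rec <- toy_recording(T_frames = 2e4, seed = 12)
  reg <- stclust:::make_regularizer("none", 0)
  K0 <- rbind(c(0.4, 0.8), c(0.9, -0.2), c(-0.5, 0.6))
  W0 <- cbind(rep(mean(rec$Y$counts) / 3, 3))
  r1 <- stclust:::fit_engine(rec$X, list(rec$Y$counts), 3, reg,
                             init_K = K0, init_W = W0)
  perm <- c(3, 1, 2)
  r2 <- stclust:::fit_engine(rec$X, list(rec$Y$counts), 3, reg,
                             init_K = K0[perm, ], init_W = W0[perm, , drop = FALSE])
  # strength-sorted output is identical up to numerical noise
  expect_equal(r1$K, r2$K, tolerance = 1e-10)
  expect_equal(r1$W, r2$W, tolerance = 1e-10)
  expect_equal(r1$trace, r2$trace, tolerance = 1e-10)
})

test_that("stage two recovers the output nonlinearity", {
  # identity-nonlinearity data: a ~ 1, b ~ 0
  rec <- toy_recording(T_frames = 1e5, seed = 13)
  fit <- fit_subunits(rec$X, rec$Y, 3, seed = 14)
  mod <- fit_output_nonlinearity(rec$X, rec$Y, fit$bank)
  expect_gt(mod$nonlinearity$a, 0.9)
  expect_lt(mod$nonlinearity$a, 1.1)
  expect_lt(mod$nonlinearity$b, 0.05)
  # optimizer contract: never worse than the unit-scale start
  nll_start <- nll(subunit_model(fit$bank), rec$X, rec$Y)
  expect_lte(attr(mod, "nll"), nll_start + 1e-12)
})

test_that("saturation is detected by held-out likelihood when present", {
  toy <- toy_cell(3, mean_rate = 0.3, nonlinearity = output_nonlinearity(1, 1),
                  seed = 15)
  X <- gauss_stim(8e4, 2, seed = 16)
  Y <- sample_spikes(firing_rate(toy, X), seed = 17)
  tr <- 1:6e4; te <- 60001:8e4
  fit <- fit_subunits(X[tr, ], Y$counts[tr], 3, seed = 18)
  m_free <- fit_output_nonlinearity(X[tr, ], Y$counts[tr], fit$bank)
  # nested b = 0 model: only scales and exponent
  E <- exp(X[tr, ] %*% t(fit$bank$K))
  obj0 <- function(th) {
    ws <- fit$bank$w * exp(th[1:3]); a <- exp(th[4])
    lam <- drop(E %*% ws)^a
    mean(lam) - sum(Y$counts[tr] * log(lam)) / length(tr)
  }
  th0 <- optim(rep(0, 4), obj0, method = "BFGS")$par
  lam_te0 <- drop(exp(X[te, ] %*% t(fit$bank$K)) %*%
                    (fit$bank$w * exp(th0[1:3])))^exp(th0[4])
  expect_lt(nll(firing_rate(m_free, X[te, ]), Y = Y$counts[te]),
            nll(lam_te0, Y = Y$counts[te]))
  expect_gt(m_free$nonlinearity$b, 0.1)
})
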