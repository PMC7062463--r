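test_that("generator_signal matches an elementwise brute-force oracle", {
  # trivial identities
  b0 <- subunit_bank(matrix(0, 1, 4), 1)
  X <- gauss_stim(5, 4, seed = 3)
  expect_equal(generator_signal(b0, X), rep(1, 5))
  K <- matrix(rnorm(4), 1, 4)
  b_sym <- subunit_bank(rbind(K, K), c(0.5, 0.5))
  expect_equal(generator_signal(b_sym, X),
               generator_signal(subunit_bank(K, 1), X))
  # random case vs scalar double loop
  set.seed(7)
  bank <- subunit_bank(matrix(rnorm(12), 3, 4), runif(3))
  G <- generator_signal(bank, X)
  oracle <- sapply(1:5, function(t) {
    s <- 0
    for (n in 1:3) s <- s + bank$w[n] * exp(sum(bank$K[n, ] * X[t, ]))
    s
  })
  expect_equal(G, oracle, tolerance = 1e-12)
  expect_error(generator_signal(bank, gauss_stim(5, 3)), "dimension")
})

test_that("firing rate applies the saturating output nonlinearity", {
  bank <- subunit_bank(matrix(rnorm(8, sd = 0.3), 2, 4), c(0.5, 0.2))
  X <- gauss_stim(50, 4, seed = 4)
  G <- generator_signal(bank, X)
  # identity when a = 1, b = 0
  m_id <- subunit_model(bank)
  expect_equal(firing_rate(m_id, X), G)
  # g(1) = 0.5 when a = 2, b = 1
  expect_equal(stclust:::apply_nonlinearity(output_nonlinearity(2, 1), 1), 0.5)
  # saturation: rate -> 1/b for large b at a = 1
  m_sat <- subunit_model(bank, output_nonlinearity(1, 1e6))
  expect_lt(max(firing_rate(m_sat, X)), 1.0000001e-6)
  # monotone in each weight
  G2 <- generator_signal(subunit_bank(bank$K, bank$w + c(0.1, 0)), X)
  expect_true(all(G2 >= G))
})

test_that("sample_spikes is Poisson, seeded and rejects negative rates", {
  expect_equal(sample_spikes(rep(0, 10))$counts, rep(0, 10))
  y1 <- sample_spikes(rep(2, 1e5), seed = 11)
  y2 <- sample_spikes(rep(2, 1e5), seed = 11)
  expect_identical(y1$counts, y2$counts)
  expect_lt(abs(mean(y1$counts) - 2), 3 * sqrt(2 / 1e5))
  expect_error(sample_spikes(c(1, -1)), "nonnegative")
})

test_that("nll matches direct Poisson summation and flags degenerate rates", {
  expect_equal(nll(rep(1, 10), Y = rep(0, 10)), 1.0)
  expect_equal(nll(rep(1, 10), Y = rep(1, 10)), 1.0)
  set.seed(5)
  lam <- runif(30, 0.1, 2)
  Y <- rpois(30, lam)
  expect_equal(nll(lam, Y = Y),
               sum(lam) / 30 - sum(Y * log(lam)) / 30, tolerance = 1e-12)
  expect_error(nll(c(0, 1), Y = c(1, 0)), "degenerate")
  # invariant to subunit permutation
  bank <- subunit_bank(matrix(rnorm(8, sd = 0.4), 2, 4), c(0.3, 0.6))
  bankp <- subunit_bank(bank$K[2:1, ], bank$w[2:1])
  X <- gauss_stim(100, 4, seed = 6)
  Yx <- sample_spikes(generator_signal(bank, X), seed = 7)
  expect_equal(nll(subunit_model(bank), X, Yx),
               nll(subunit_model(bankp), X, Yx))
})

test_that("expected_nll uses the Gaussian moment generating function", {
  b0 <- subunit_bank(matrix(0, 1, 3), 1)
  expect_equal(expected_nll(b0, matrix(0, 0, 3), numeric(0), 100), 1.0)
  k <- c(1, 1, 0)  # ||k||^2 = 2
  expect_equal(expected_nll(subunit_bank(rbind(k), 1), matrix(0, 0, 3),
                            numeric(0), 100), exp(1))
  # Monte-Carlo: expectation term within 2% of the empirical mean rate
  set.seed(8)
  bank <- subunit_bank(matrix(rnorm(6, sd = 0.5), 2, 3), c(0.4, 0.8))
  X <- gauss_stim(2e5, 3, seed = 9)
  emp <- mean(generator_signal(bank, X))
  ana <- sum(bank$w * exp(rowSums(bank$K^2) / 2))
  expect_lt(abs(ana - emp) / ana, 0.02)
})

test_that("subunit_strength is the Monte-Carlo mean drive", {
  expect_equal(subunit_strength(rep(0, 4), 1), 1)
  expect_equal(subunit_strength(rnorm(4), 0), 0)
  set.seed(10)
  k <- rnorm(3, sd = 0.5); w <- 0.7
  draws <- matrix(rnorm(3e6), 1e6, 3)
  emp <- mean(w * exp(drop(draws %*% k)))
  expect_lt(abs(subunit_strength(k, w) - emp) / emp, 0.02)
})

test_that("containers validate their invariants", {
  expect_error(stimulus_matrix(matrix(5 + rnorm(100), 50, 2)),
               "not standardized")
  expect_silent(stimulus_matrix(gauss_stim(5000, 2, seed = 2)))
  expect_error(spike_counts(c(1, -1)), "nonnegative")
  expect_error(spike_counts(c(1, 1.5)), "nonnegative integers")
  expect_error(subunit_bank(matrix(0, 2, 3), c(1, -1)), "nonnegative")
  expect_error(output_nonlinearity(a = 0), "a must be")
  expect_error(output_nonlinearity(b = -1), "b must be")
  expect_error(subunit_model(subunit_bank(matrix(0, 1, 4), 1),
                             grid_shape = c(3, 3)), "grid_shape")
})
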