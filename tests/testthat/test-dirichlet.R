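test_that("belief construction enforces positivity and tied symmetry", {
  expect_error(dirichlet_beliefs(matrix(c(2, 0, 1, 1), 2), matrix(1, 2, 2)),
               "strictly positive")
  expect_error(dirichlet_beliefs(matrix(c(3, 1, 2, 2), 2), matrix(1, 2, 2),
                                 tied = TRUE), "symmetric")
  expect_error(dirichlet_beliefs(matrix(1, 3, 3), matrix(1, 3, 3),
                                 tied = TRUE), "K = M = 2")
  b <- dirichlet_beliefs(matrix(2, 2, 2), matrix(c(9, 1, 1, 9), 2),
                         tied = TRUE)
  expect_true(b$tied)
})

test_that("expected parameters: Dirichlet means and geometric-mean estimates", {
  # the weak transition prior has mean 1/2 per cell
  b <- dirichlet_beliefs(matrix(2, 2, 2), matrix(c(8.5, 1.5, 1.5, 8.5), 2) * 1e5)
  ep <- expected_parameters(b)
  expect_equal(ep$A_mean, matrix(0.5, 2, 2))
  # strong concentrations: geometric-mean estimate converges to the mean
  expect_equal(ep$B_mean, matrix(c(0.85, 0.15, 0.15, 0.85), 2),
               tolerance = 1e-12)
  expect_lt(max(abs(ep$B_hat - ep$B_mean)), 1e-5)
  big <- dirichlet_beliefs(1e6 * matrix(c(0.9, 0.1, 0.1, 0.9), 2),
                           1e6 * matrix(0.5, 2, 2))
  expect_lt(max(abs(expected_parameters(big)$A_hat -
                      matrix(c(0.9, 0.1, 0.1, 0.9), 2))), 1e-6)
})

test_that("exp(E[ln theta]) is strictly below E[theta] (Jensen), checked by quadrature", {
  # Beta(2, 3) marginal of a Dirichlet row
  b <- dirichlet_beliefs(matrix(c(2, 2, 3, 3), 2), matrix(1, 2, 2))
  ep <- expected_parameters(b)
  q <- integrate(function(x) log(x) * dbeta(x, 2, 3), 0, 1)$value
  expect_equal(log(ep$A_hat[1, 1]), q, tolerance = 1e-6)
  expect_lt(ep$A_hat[1, 1], ep$A_mean[1, 1])
  # sub-stochastic rows
  expect_true(all(rowSums(ep$A_hat) < 1))
})

test_that("Dirichlet KL divergence matches quadrature and is non-negative", {
  expect_equal(dirichlet_kl(c(3, 2, 5), c(3, 2, 5)), 0)
  # KL(Beta(2,1) || Beta(1,1)) by 1-D quadrature of the integrand
  q <- integrate(function(x) dbeta(x, 2, 1) * (dbeta(x, 2, 1, log = TRUE) -
                                                 dbeta(x, 1, 1, log = TRUE)),
                 0, 1)$value
  expect_equal(dirichlet_kl(c(2, 1), c(1, 1)), q, tolerance = 1e-6)
  expect_error(dirichlet_kl(c(1, 2), c(1, 2, 3)), "same length")

  withr::local_seed(2)
  for (i in 1:1000) {
    k <- sample(2:4, 1)
    expect_gte(dirichlet_kl(rgamma(k, 2) + 0.05, rgamma(k, 2) + 0.05), 0)
  }
})

test_that("symmetric tying pools counts, conserves mass, and fixes symmetric input", {
  b <- dirichlet_beliefs(matrix(2, 2, 2), matrix(c(9, 1, 1, 9), 2), tied = TRUE)
  inc_a <- matrix(c(0.7, 0.1, 0.3, 0.9), 2)  # rows (.7,.3) and (.1,.9)
  inc_b <- matrix(c(1, 0, 0, 1), 2)
  tied <- tie_symmetric(inc_a, inc_b, b)
  expect_equal(tied$a, matrix(c(0.8, 0.2, 0.2, 0.8), 2))
  expect_equal(sum(tied$a), sum(inc_a))
  expect_equal(sum(tied$b), sum(inc_b))
  expect_equal(tied$a, t(tied$a))
  sym <- matrix(c(0.6, 0.4, 0.4, 0.6), 2)
  expect_equal(tie_symmetric(sym, sym, b)$a, sym)

  untied <- dirichlet_beliefs(matrix(2, 2, 2), matrix(1, 2, 2))
  expect_error(tie_symmetric(inc_a, inc_b, untied), "tied")
})

test_that("tied pooling reproduces the conjugate Beta posterior of the shared-rate model", {
  # deterministic state path: transition-type indicator counts are known
  states <- c(1L, 1L, 2L, 2L, 2L, 1L)   # 2 reversals, 3 stays
  counts <- matrix(0, 2, 2)
  for (t in 2:6) counts[states[t - 1], states[t]] <- counts[states[t - 1], states[t]] + 1
  b <- dirichlet_beliefs(matrix(2, 2, 2), matrix(2, 2, 2), tied = TRUE)
  pooled <- tie_symmetric(counts, matrix(0, 2, 2), b)$a
  post <- dirichlet_beliefs(b$Pi_a + pooled, b$Pi_b, tied = TRUE)
  tp <- tied_posterior(post)
  # per-row Beta over r: prior Beta(2,2) plus the per-row (averaged) counts
  expect_equal(tp$shape1[tp$parameter == "r"], 2 + 2 / 2)
  expect_equal(tp$shape2[tp$parameter == "r"], 2 + 3 / 2)
})

test_that("tied posteriors expose Beta summaries and beliefs round-trip as JSON", {
  b <- dirichlet_beliefs(matrix(c(30, 4, 4, 30), 2),
                         matrix(c(85, 15, 15, 85), 2), tied = TRUE)
  tp <- tied_posterior(b)
  expect_equal(tp$mean[tp$parameter == "r"], 4 / 34)
  expect_equal(tp$mean[tp$parameter == "v"], 85 / 100)
  path <- withr::local_tempfile(fileext = ".json")
  write_beliefs(b, path)
  b2 <- read_beliefs(path)
  expect_equal(b2$Pi_a, b$Pi_a)
  expect_equal(b2$Pi_b, b$Pi_b)
  expect_true(b2$tied)
})
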