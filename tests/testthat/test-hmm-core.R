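test_that("uninformative emissions leave the symmetric filter at 1/2", {
  p <- reversal_params(r = 0.1, v = 0.5)
  fwd <- forward_pass(c(1L, 2L, 1L, 1L), p)
  expect_equal(fwd$alpha, matrix(0.5, 4, 2), tolerance = 1e-14)
  g <- smoothed_marginals(fwd$alpha, backward_pass(c(1L, 2L, 1L, 1L), p, fwd$c))
  expect_equal(unclass(g), matrix(0.5, 4, 2), ignore_attr = TRUE,
               tolerance = 1e-14)
})

test_that("deterministic emissions pin beliefs to the observations", {
  p <- reversal_params(r = 0.1, v = 1)
  obs <- c(1L, 2L, 2L, 1L)
  fb <- forward_backward(obs, p)
  expect_equal(fb$alpha, one_hot(obs, 2) * 1, ignore_attr = TRUE)
  expect_equal(fb$gamma, one_hot(obs, 2) * 1, ignore_attr = TRUE)
})

test_that("filtered posteriors and evidence match path enumeration (K=2, T=3)", {
  p <- reversal_params(r = 0.1, v = 0.85)
  obs <- c(1L, 1L, 2L)
  fwd <- forward_pass(obs, p)
  en <- enumerate_posterior(obs, p)
  expect_equal(sum(log(fwd$c)), en$loglik, tolerance = 1e-12)
  # filtered marginal at each t = enumeration over the truncated sequence
  for (t in 1:3) {
    en_t <- enumerate_posterior(obs[1:t], p)
    expect_equal(fwd$alpha[t, ], en_t$gamma[t, ], tolerance = 1e-12)
  }
})

test_that("full-depth smoothing and dual-slice marginals match enumeration", {
  withr::local_seed(31)
  for (K in 2:3) {
    p <- rand_hmm(K, K)
    obs <- rand_obs(K, 5)
    fb <- forward_backward(obs, p)
    en <- enumerate_posterior(obs, p)
    expect_lt(max(abs(fb$gamma - en$gamma)), 1e-10)
    expect_lt(max(abs(fb$xi[, , 2:5] - en$xi[, , 2:5])), 1e-10)
    expect_lt(abs(fb$loglik - en$loglik), 1e-10)
  }
})

test_that("backward depth controls how far beliefs are revised", {
  p <- reversal_params(0.12, 0.8)
  obs <- c(1L, 2L, 2L, 1L, 2L)
  fwd <- forward_pass(obs, p)
  # depth 1: trivial all-ones message, smoothing collapses to filtering
  b1 <- backward_pass(obs, p, fwd$c, depth = 1)
  expect_equal(unclass(b1), matrix(1, 1, 2), ignore_attr = TRUE)
  g1 <- smoothed_marginals(fwd$alpha, b1)
  expect_equal(g1[1, ], fwd$alpha[5, ], tolerance = 1e-14)
  expect_equal(attr(g1, "times"), 5L)
  # intermediate depth agrees with the tail of the full messages
  bfull <- backward_pass(obs, p, fwd$c)
  b3 <- backward_pass(obs, p, fwd$c, depth = 3)
  expect_equal(unclass(b3), unclass(bfull)[3:5, ], ignore_attr = TRUE,
               tolerance = 1e-14)
  expect_error(backward_pass(obs, p, fwd$c, depth = 0), "positive")
  expect_error(backward_pass(obs, p, fwd$c, depth = 9), "exceed")
})

test_that("xi marginalization is consistent with gamma and honors structure", {
  withr::local_seed(7)
  for (i in 1:5) {
    p <- rand_hmm(3, 3)
    obs <- rand_obs(3, 8)
    fb <- forward_backward(obs, p)
    for (t in 2:8) {
      expect_equal(sum(fb$xi[, , t]), 1, tolerance = 1e-10)
      expect_equal(rowSums(fb$xi[, , t]), fb$gamma[t - 1, ], tolerance = 1e-8)
      expect_equal(colSums(fb$xi[, , t]), fb$gamma[t, ], tolerance = 1e-8)
    }
  }
  # identity transitions put no mass off the diagonal
  p0 <- reversal_params(r = 0, v = 0.85)
  fb0 <- forward_backward(c(1L, 2L, 1L), p0)
  for (t in 2:3) {
    expect_equal(fb0$xi[1, 2, t], 0)
    expect_equal(fb0$xi[2, 1, t], 0)
  }
})

test_that("scaled outputs equal the unscaled textbook recursions", {
  withr::local_seed(13)
  for (i in 1:5) {
    p <- rand_hmm(2 + i %% 2, 3)
    obs <- rand_obs(3, 12)
    un <- unscaled_smoother(obs, p)
    fb <- forward_backward(obs, p, want_xi = FALSE)
    expect_lt(max(abs(fb$alpha - un$alpha_filtered)), 1e-12)
    expect_lt(max(abs(fb$gamma - un$gamma)), 1e-12)
    expect_lt(abs(fb$loglik - un$loglik), 1e-12)
  }
})

test_that("long sequences do not underflow and impossible observations error", {
  p <- reversal_params(0.05, 0.9)
  obs <- sample_session(p, 1e5, seed = 4)
  fwd <- forward_pass(obs, p)
  expect_true(all(is.finite(fwd$alpha)), all(fwd$c > 0))

  pz <- hmm_params(diag(2), matrix(c(1, 0, 1, 0), 2, byrow = TRUE))
  expect_error(forward_pass(c(1L, 2L), pz), "trial 2")
})

test_that("enumeration oracle handles boundary cases and refuses huge instances", {
  p <- rand_hmm(2, 3)
  en <- enumerate_posterior(3L, p)
  expect_equal(en$gamma[1, ], p$d * p$B[, 3] / sum(p$d * p$B[, 3]))

  uni <- hmm_params(matrix(1 / 2, 2, 2), matrix(1 / 3, 2, 3))
  obs <- rand_obs(3, 6)
  expect_equal(enumerate_posterior(obs, uni)$loglik, 6 * log(1 / 3),
               tolerance = 1e-12)
  expect_error(enumerate_posterior(rand_obs(3, 25), rand_hmm(3, 3)),
               "too large")
})
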