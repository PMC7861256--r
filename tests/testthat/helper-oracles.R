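# Test fixtures and independent oracles (pure R, no message-passing reuse).

# random row-stochastic matrix (flat Dirichlet rows)
rand_stochastic <- function(nr, nc) {
  g <- matrix(rgamma(nr * nc, 1), nr, nc)
  g / rowSums(g)
}

rand_hmm <- function(K, M) hmm_params(rand_stochastic(K, K), rand_stochastic(K, M))

rand_obs <- function(M, T_) sample.int(M, T_, replace = TRUE)

# Unscaled forward-backward, straight from the textbook recursions, usable
# only for short sequences.  Kept deliberately independent of the package's
# scaled engine.
unscaled_smoother <- function(obs, params) {
  A <- params$A; B <- params$B; d <- params$d
  T_ <- length(obs); K <- params$K
  alpha <- matrix(0, T_, K)
  alpha[1, ] <- B[, obs[1]] * d
  if (T_ > 1)
    for (t in 2:T_) alpha[t, ] <- B[, obs[t]] * drop(t(A) %*% alpha[t - 1, ])
  beta <- matrix(0, T_, K)
  beta[T_, ] <- 1
  if (T_ > 1)
    for (t in (T_ - 1):1)
      beta[t, ] <- drop(A %*% (beta[t + 1, ] * B[, obs[t + 1]]))
  g <- alpha * beta
  list(gamma = g / rowSums(g), alpha_filtered = alpha / rowSums(alpha),
       loglik = log(sum(alpha[T_, ])))
}
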