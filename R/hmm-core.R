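#' Scaled forward pass (filtering)
#'
#' Runs the scaled forward recursion `alpha_t \propto (B o_t) * (A' alpha_{t-1})`
#' over a sequence of observations.  Each message is renormalized and the
#' per-step normalizers `c_t` are returned, so the recursion does not
#' underflow on long sequences and `sum(log(c))` is the log marginal
#' likelihood of the observations.
#'
#' @param observations A `task_session`, integer codes, or a one-hot matrix.
#' @param params An [hmm_params] object (point parameters, or variational
#'   point estimates from [expected_parameters]).
#' @param start_belief Length-`K` probability vector: the initial-state
#'   distribution `d` for a full session, or the filtered anchor belief for a
#'   sliding window.
#' @param transition_first If `TRUE`, `start_belief` is a filtered posterior
#'   at the timestep *before* the first observation and one transition is
#'   applied before the first emission (the fixed-lag window case).  If
#'   `FALSE` (default), `start_belief` is the prior over the first state
#'   itself.
#' @return A list with `alpha` (`T x K` matrix of filtered posteriors
#'   `p(x_t | o_1:t)`) and `c` (length-`T` scaling constants).
#' @examples
#' p <- reversal_params(0.1, 0.85)
#' fwd <- forward_pass(c(1L, 1L, 2L), p)
#' fwd$alpha
#' sum(log(fwd$c))  # log marginal likelihood
#' @export
forward_pass <- function(observations, params, start_belief = params$d,
                         transition_first = FALSE) {
  obs <- as_observation_codes(observations)
  check_obs_range(obs, params)
  check_belief(start_belief, params$K)
  cpp_forward(obs, params$A, params$B, start_belief, transition_first)
}

#' Scaled backward pass
#'
#' Runs the backward recursion
#' `beta_t = A (beta_{t+1} * B o_{t+1}) / c_{t+1}` for the last `depth`
#' timesteps of the sequence, starting from an all-ones message at the final
#' covered time.  Dividing by the forward scaling constants keeps the
#' messages on the same scale as `alpha`, so `alpha * beta` renormalizes to
#' the smoothed marginals.  `depth = T` gives the full fixed-interval
#' messages; `depth = 1` leaves only the trivial final message, reducing
#' smoothing to filtering.
#'
#' @inheritParams forward_pass
#' @param c Scaling constants from the matching [forward_pass].
#' @param depth Number of trailing timesteps to cover (1..T); default `T`.
#' @return A `depth x K` matrix of scaled backward messages with attribute
#'   `times` giving the covered (1-based) timesteps.
#' @export
backward_pass <- function(observations, params, c, depth = NULL) {
  obs <- as_observation_codes(observations)
  check_obs_range(obs, params)
  T_ <- length(obs)
  if (is.null(depth)) depth <- T_
  if (depth < 1) stop("`depth` must be a positive integer", call. = FALSE)
  if (depth > T_) stop("`depth` cannot exceed the sequence length", call. = FALSE)
  stopifnot(length(c) == T_)
  beta <- cpp_backward(obs, params$A, params$B, c, as.integer(depth))
  attr(beta, "times") <- (T_ - depth + 1):T_
  beta
}

#' Smoothed state marginals
#'
#' Combines aligned forward and backward messages into the smoothed marginals
#' `gamma_t \propto alpha_t * beta_t`, renormalized to sum to one.  When
#' `beta` covers only the last `depth` timesteps, `alpha` rows are matched by
#' the `times` attribute.
#'
#' @param alpha Forward messages (`T x K`).
#' @param beta Backward messages from [backward_pass].
#' @return Matrix of smoothed marginals, one row per covered timestep, with
#'   the same `times` attribute as `beta`.
#' @export
smoothed_marginals <- function(alpha, beta) {
  times <- attr(beta, "times")
  if (is.null(times)) {
    if (nrow(beta) != nrow(alpha))
      stop("`alpha` and `beta` must cover the same timesteps", call. = FALSE)
    times <- seq_len(nrow(alpha))
  }
  g <- alpha[times, , drop = FALSE] * beta
  s <- rowSums(g)
  if (any(s <= 0))
    stop("smoothed marginal is numerically degenerate at time ",
         times[which(s <= 0)[1]], call. = FALSE)
  g <- g / s
  attr(g, "times") <- times
  g
}

#' Dual-slice marginals
#'
#' The dual-slice marginal `xi_t` is the joint posterior over consecutive
#' hidden states `p(x_{t-1}, x_t | o_1:T)`,
#' `xi_t \propto A * (alpha_{t-1} ((B o_t) * beta_t)')`, the quantity whose
#' expected counts drive transition-matrix learning.  Marginalizing a slice
#' over its second (first) index recovers the smoothed marginal at `t-1`
#' (`t`).
#'
#' @inheritParams backward_pass
#' @param alpha,beta Aligned scaled messages covering the full sequence.
#' @return A `K x K x T` array; slice `t` (for `t >= 2`) is the joint over
#'   times `(t-1, t)` and slice 1 is `NA`.
#' @export
dual_slice_marginals <- function(alpha, beta, params, observations, c) {
  obs <- as_observation_codes(observations)
  T_ <- length(obs); K <- params$K
  if (T_ < 2) stop("dual-slice marginals need at least 2 timesteps", call. = FALSE)
  stopifnot(nrow(alpha) == T_, nrow(beta) == T_, length(c) == T_)
  xi <- array(NA_real_, c(K, K, T_))
  for (t in 2:T_) {
    bk <- params$B[, obs[t]] * beta[t, ] / c[t]
    sl <- params$A * tcrossprod(alpha[t - 1, ], bk)
    s <- sum(sl)
    if (!(s > 0))
      stop("dual-slice marginal at time ", t, " is numerically degenerate",
           call. = FALSE)
    xi[, , t] <- sl / s
  }
  xi
}

#' Full forward-backward smoothing
#'
#' Convenience wrapper running the scaled forward and backward passes and
#' assembling filtered posteriors, smoothed marginals, dual-slice marginals
#' and the log marginal likelihood in one call.
#'
#' @inheritParams forward_pass
#' @param want_xi Compute dual-slice marginals (default `TRUE`).
#' @return A list of class `forward_backward` with elements `alpha`, `c`,
#'   `beta`, `gamma`, `xi` (if requested) and `loglik`.
#' @examples
#' p <- reversal_params(0.1, 0.85)
#' fb <- forward_backward(c(1L, 1L, 2L), p)
#' fb$gamma
#' @export
forward_backward <- function(observations, params, start_belief = params$d,
                             transition_first = FALSE, want_xi = TRUE) {
  obs <- as_observation_codes(observations)
  check_obs_range(obs, params)
  check_belief(start_belief, params$K)
  out <- cpp_fb(obs, params$A, params$B, start_belief, transition_first,
                want_xi)
  class(out) <- "forward_backward"
  out
}

#' Exact posterior by path enumeration
#'
#' Brute-force test oracle: sums the joint probability of every one of the
#' `K^T` hidden-state paths to obtain exact smoothed marginals, dual-slice
#' marginals and the log marginal likelihood.  Implemented independently of
#' the message-passing engine (pure R, no recursions) and guarded to small
#' instances; intended for tests.
#'
#' @inheritParams forward_pass
#' @return A list with `gamma` (`T x K`), `xi` (`K x K x T`, slice 1 `NA`)
#'   and `loglik`.
#' @examples
#' p <- reversal_params(0.1, 0.85)
#' enumerate_posterior(c(1L, 1L, 2L), p)$loglik
#' @export
enumerate_posterior <- function(observations, params) {
  obs <- as_observation_codes(observations)
  check_obs_range(obs, params)
  K <- params$K; T_ <- length(obs)
  if (K^T_ > 1e6)
    stop("instance too large to enumerate (K^T > 1e6)", call. = FALSE)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  logp <- log(params$d[paths[, 1]]) + log(params$B[cbind(paths[, 1], obs[1])])
  if (T_ > 1)
    for (t in 2:T_)
      logp <- logp + log(params$A[cbind(paths[, t - 1], paths[, t])]) +
        log(params$B[cbind(paths[, t], obs[t])])
  m <- max(logp)
  if (!is.finite(m))
    stop("all state paths have probability zero", call. = FALSE)
  w <- exp(logp - m)
  Z <- sum(w)
  post <- w / Z
  gamma <- matrix(0, T_, K)
  for (t in seq_len(T_))
    gamma[t, ] <- vapply(seq_len(K),
                         function(k) sum(post[paths[, t] == k]), 0)
  xi <- array(NA_real_, c(K, K, T_))
  if (T_ > 1) {
    for (t in 2:T_) {
      sl <- matrix(0, K, K)
      for (j in seq_len(K))
        for (k in seq_len(K))
          sl[j, k] <- sum(post[paths[, t - 1] == j & paths[, t] == k])
      xi[, , t] <- sl
    }
  }
  list(gamma = gamma, xi = xi, loglik = m + log(Z))
}

check_obs_range <- function(obs, params) {
  if (any(obs > params$M))
    stop("observation code exceeds the number of observation categories M",
         call. = FALSE)
  invisible(obs)
}

check_belief <- function(b, K) {
  if (length(b) != K || any(b < 0) || abs(sum(b) - 1) > 1e-8)
    stop("start belief must be a length-K probability vector", call. = FALSE)
  invisible(b)
}
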