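#' Variational lower bound for the Dirichlet HMM
#'
#' `L = sum_t ln c_t - sum_rows KL(Dir(posterior) || Dir(prior))`, where the
#' `c_t` are the forward-pass normalizers computed under the current
#' variational point estimates and the KL terms run over the rows of both
#' concentration matrices.  The bound is the convergence monitor of
#' [vb_fit]: it never decreases across iterations.
#'
#' @param c Scaling constants from the most recent forward pass under the
#'   current variational estimates.
#' @param priors,posteriors [dirichlet_beliefs] before and after the
#'   concentration updates.
#' @return Scalar lower-bound value (nats).
#' @export
lower_bound <- function(c, priors, posteriors) {
  sum(log(c)) - kl_rows(posteriors$Pi_a, priors$Pi_a) -
    kl_rows(posteriors$Pi_b, priors$Pi_b)
}

kl_rows <- function(post, prior) {
  s <- 0
  for (j in seq_len(nrow(post))) s <- s + dirichlet_kl(post[j, ], prior[j, ])
  s
}

# Lean inner loop shared by vb_fit() and the sliding-window engine.  `start`
# is either the initial-state distribution (transition_first = FALSE) or the
# filtered anchor belief at the time preceding the window (TRUE); in the
# latter case the slice linking the anchor to the first covered time is part
# of the expected transition counts.
vb_engine <- function(obs, prior_a, prior_b, tied, start, transition_first,
                      tol_scale = 1e-6, max_iters = 500L) {
  T_ <- length(obs)
  tol <- tol_scale * T_
  # current parameter beliefs; the first state pass runs under the prior
  cur_a <- prior_a
  cur_b <- prior_b
  t0 <- if (transition_first) 1L else 2L
  L_prev <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  fb <- counts_a <- counts_b <- NULL
  for (it in seq_len(max_iters)) {
    A_hat <- exp_digamma_rows(cur_a)
    B_hat <- exp_digamma_rows(cur_b)
    fb <- cpp_fb(obs, A_hat, B_hat, start, transition_first, TRUE)
    # bound after the state update: evidence term under the estimates just
    # used, minus the KL of the beliefs that produced those estimates
    L <- fb$loglik - kl_rows(cur_a, prior_a) - kl_rows(cur_b, prior_b)
    trace <- c(trace, L)
    counts_a <- if (T_ >= t0) rowSums(fb$xi[, , t0:T_, drop = FALSE], dims = 2)
                else matrix(0, nrow(prior_a), ncol(prior_a))
    counts_b <- crossprod(fb$gamma, one_hot(obs, ncol(prior_b)))
    if (tied) {
      counts_a <- symmetrize2(counts_a)
      counts_b <- symmetrize2(counts_b)
    }
    cur_a <- prior_a + counts_a
    cur_b <- prior_b + counts_b
    if (abs(L - L_prev) < tol) { converged <- TRUE; break }
    L_prev <- L
  }
  post_a <- cur_a
  post_b <- cur_b
  list(fb = fb, post_a = post_a, post_b = post_b,
       counts_a = counts_a, counts_b = counts_b,
       A_hat = exp_digamma_rows(post_a), B_hat = exp_digamma_rows(post_b),
       L = trace[length(trace)], L_trace = trace,
       n_iters = length(trace), converged = converged)
}

#' Variational Bayes dual estimation for an HMM session
#'
#' Jointly infers hidden states and learns the transition/emission matrices
#' by alternating (i) a scaled forward-backward pass that substitutes the
#' variational point estimates `A_hat = exp(E[ln A])`, `B_hat = exp(E[ln B])`
#' for the unknown parameters, and (ii) conjugate Dirichlet concentration
#' updates that add the expected transition counts (summed dual-slice
#' marginals) and emission counts (smoothed marginals accumulated per
#' observed category) to the priors.  Iterations stop when the variational
#' lower bound changes by less than `tolerance_scale` times the number of
#' observations.
#'
#' The initial state distribution `d` is held fixed (uniform by default) and
#' is never learned.  For tied beliefs every count increment is symmetrized
#' with [tie_symmetric], so the posterior remains governed by single Beta
#' beliefs over the reversal rate and reliability.
#'
#' @inheritParams forward_pass
#' @param priors [dirichlet_beliefs] prior.
#' @param d Initial-state distribution (default uniform).
#' @param tolerance_scale Convergence tolerance per data point (default
#'   `1e-6`).
#' @param max_iters Iteration cap; if reached without convergence a warning
#'   of class `retroinfer_nonconvergence` carrying the lower-bound trace is
#'   signalled.
#' @return An object of class `vb_hmm`: `beliefs` (posterior), `priors`,
#'   `A_hat`, `B_hat`, `gamma`, `xi`, `alpha`, `c`, lower bound `L` with its
#'   trace, `n_iters` and `converged`.
#' @examples
#' sess <- sample_session(reversal_params(0.1, 0.85), 64, seed = 1)
#' fit <- vb_fit(sess, dual_estimation_prior(attr(sess, "params"), tied = TRUE))
#' glance(fit)
#' @export
vb_fit <- function(observations, priors, d = NULL, tolerance_scale = 1e-6,
                   max_iters = 500L) {
  stopifnot(inherits(priors, "dirichlet_beliefs"))
  obs <- as_observation_codes(observations)
  if (length(obs) < 2) stop("vb_fit() needs at least 2 trials", call. = FALSE)
  if (any(obs > priors$M))
    stop("observation code exceeds M", call. = FALSE)
  if (is.null(d)) d <- rep(1 / priors$K, priors$K)
  check_belief(d, priors$K)
  res <- vb_engine(obs, priors$Pi_a, priors$Pi_b, priors$tied, d,
                   transition_first = FALSE, tol_scale = tolerance_scale,
                   max_iters = max_iters)
  if (!res$converged) {
    w <- simpleWarning(sprintf(
      "variational updates did not converge in %d iterations", max_iters))
    class(w) <- c("retroinfer_nonconvergence", class(w))
    attr(w, "L_trace") <- res$L_trace
    warning(w)
  }
  structure(list(
    beliefs = dirichlet_beliefs(res$post_a, res$post_b, tied = priors$tied),
    priors = priors, d = d,
    A_hat = res$A_hat, B_hat = res$B_hat,
    gamma = res$fb$gamma, xi = res$fb$xi,
    alpha = res$fb$alpha, c = res$fb$c,
    L = res$L, L_trace = res$L_trace,
    n_iters = res$n_iters, converged = res$converged,
    n_trials = length(obs)), class = "vb_hmm")
}

#' @export
print.vb_hmm <- function(x, ...) {
  cat(sprintf("<vb_hmm> T = %d trials, L = %.4f after %d iteration%s%s\n",
              x$n_trials, x$L, x$n_iters, if (x$n_iters == 1) "" else "s",
              if (x$converged) "" else " (not converged)"))
  if (x$beliefs$tied) print(tied_posterior(x$beliefs))
  invisible(x)
}

#' Tidy a variational HMM fit
#'
#' @param x A `vb_hmm` object.
#' @param ... Unused.
#' @return One row per Dirichlet concentration: `matrix` ("transition" or
#'   "emission"), `from_state`, `to`, `concentration`, `prior`, `mean`.
#' @export
tidy.vb_hmm <- function(x, ...) {
  longify <- function(post, prior, label) {
    tibble::tibble(
      matrix = label,
      from_state = as.integer(row(post)),
      to = as.integer(col(post)),
      concentration = as.numeric(post),
      prior = as.numeric(prior),
      mean = as.numeric(post / rowSums(post)))
  }
  dplyr::bind_rows(
    longify(x$beliefs$Pi_a, x$priors$Pi_a, "transition"),
    longify(x$beliefs$Pi_b, x$priors$Pi_b, "emission"))
}

#' @rdname tidy.vb_hmm
#' @return `glance()` returns a one-row tibble with `n_trials`, `L`,
#'   `n_iters`, `converged` and the forward log-normalizer `log_evidence`.
#' @export
glance.vb_hmm <- function(x, ...) {
  tibble::tibble(n_trials = x$n_trials, L = x$L, n_iters = x$n_iters,
                 converged = x$converged, log_evidence = sum(log(x$c)))
}
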