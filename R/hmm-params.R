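#' Hidden Markov model parameters
#'
#' Bundles the point parameters of a discrete HMM: a `K x K` row-stochastic
#' transition matrix `A` (`A[j, k]` is the probability of moving from hidden
#' state `j` to state `k` between trials), a `K x M` row-stochastic emission
#' matrix `B` (`B[j, m]` is the probability of observing outcome `m` while in
#' state `j`), and a length-`K` probability vector `d` over the initial
#' hidden state.
#'
#' @param A `K x K` transition matrix; rows must sum to 1.
#' @param B `K x M` emission matrix; rows must sum to 1.
#' @param d Initial-state distribution; defaults to uniform over the `K`
#'   states.
#'
#' @return An object of class `hmm_params`: a list with elements `A`, `B`,
#'   `d`, `K` and `M`.
#' @examples
#' p <- hmm_params(matrix(c(.9, .1, .1, .9), 2, byrow = TRUE),
#'                 matrix(c(.85, .15, .15, .85), 2, byrow = TRUE))
#' p$K
#' @export
hmm_params <- function(A, B, d = NULL) {
  A <- as.matrix(A)
  B <- as.matrix(B)
  K <- nrow(A)
  if (ncol(A) != K) stop("`A` must be square", call. = FALSE)
  if (nrow(B) != K) stop("`B` must have one row per hidden state", call. = FALSE)
  if (is.null(d)) d <- rep(1 / K, K)
  d <- as.numeric(d)
  if (length(d) != K) stop("`d` must have length K", call. = FALSE)
  check_stochastic(A, "A")
  check_stochastic(B, "B")
  if (any(d < 0) || abs(sum(d) - 1) > 1e-12)
    stop("`d` must be a probability vector whose entries sum to 1", call. = FALSE)
  structure(list(A = A, B = B, d = d, K = K, M = ncol(B)),
            class = "hmm_params")
}

check_stochastic <- function(mat, name) {
  if (any(mat < 0) || any(mat > 1))
    stop(sprintf("entries of `%s` must lie in [0, 1]", name), call. = FALSE)
  if (any(abs(rowSums(mat) - 1) > 1e-12))
    stop(sprintf("rows of `%s` must sum to 1", name), call. = FALSE)
  invisible(mat)
}

# Variational point estimates exp(E[ln theta]) are sub-stochastic; they share
# the container but skip the row-sum-equals-one check.
new_variational_params <- function(A_hat, B_hat, d) {
  structure(list(A = A_hat, B = B_hat, d = d, K = nrow(A_hat),
                 M = ncol(B_hat), variational = TRUE),
            class = "hmm_params")
}

#' @export
print.hmm_params <- function(x, ...) {
  cat(sprintf("<hmm_params> K = %d states, M = %d observations\n", x$K, x$M))
  cat("A (transitions):\n")
  print(round(x$A, 4))
  cat("B (emissions):\n")
  print(round(x$B, 4))
  cat("d:", round(x$d, 4), "\n")
  invisible(x)
}

#' Probabilistic reversal task parameters
#'
#' The two-state reversal task is an HMM in which the hidden state switches
#' with probability `r` per trial and each trial's binary observation reports
#' the current state correctly with probability `v`:
#' `A = [[1-r, r], [r, 1-r]]`, `B = [[v, 1-v], [1-v, v]]`, with a uniform
#' initial distribution.
#'
#' @param r Per-trial reversal probability, in \[0, 1\].
#' @param v Observation reliability, in \[0, 1\].
#' @return An [hmm_params] object with `K = M = 2`.
#' @examples
#' reversal_params(r = 0.1, v = 0.85)
#' @export
reversal_params <- function(r, v) {
  stopifnot(length(r) == 1, length(v) == 1)
  if (r < 0 || r > 1) stop("`r` must lie in [0, 1]", call. = FALSE)
  if (v < 0 || v > 1) stop("`v` must lie in [0, 1]", call. = FALSE)
  hmm_params(A = matrix(c(1 - r, r, r, 1 - r), 2, byrow = TRUE),
             B = matrix(c(v, 1 - v, 1 - v, v), 2, byrow = TRUE))
}

#' Random three-state HMM parameters
#'
#' Draws each transition row from a flat Dirichlet over the simplex and builds
#' the emission matrix from a common diagonal reliability, with the remaining
#' probability split equally over the off-diagonal outcomes.  This is the
#' generator used by the random-HMM simulation study, where the diagonal is
#' swept over 0.65 to 0.95 in steps of 0.05 to vary perceptual uncertainty.
#'
#' @param emission_diag Probability that the observation matches the hidden
#'   state, in \[0, 1\].
#' @param K,M Number of hidden states and observation categories (default 3).
#' @param seed Optional integer seed; when supplied the draw is reproducible
#'   and the session RNG state is left untouched.
#' @return An [hmm_params] object.
#' @examples
#' random_hmm_params(emission_diag = 0.8, seed = 1)
#' @export
random_hmm_params <- function(emission_diag, K = 3, M = 3, seed = NULL) {
  if (emission_diag < 0 || emission_diag > 1)
    stop("`emission_diag` must lie in [0, 1]", call. = FALSE)
  draw <- function() {
    g <- matrix(rgamma(K * K, shape = 1), K, K)
    g / rowSums(g)
  }
  A <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  B <- matrix((1 - emission_diag) / (M - 1), K, M)
  diag(B) <- emission_diag
  hmm_params(A = A, B = B)
}
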