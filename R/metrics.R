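#' Log accuracy of state beliefs
#'
#' The log-probability a sequence of marginal beliefs assigns to the realized
#' hidden-state path, `sum_t ln(belief_t[x_t])`.  Zero (or better) is one-hot
#' correct beliefs; uniform beliefs over `K` states give `T * ln(1/K)`.
#' A belief of exactly zero at a true state yields `-Inf` with a warning and
#' a `zero_belief` attribute rather than an error.
#'
#' @param beliefs `T x K` matrix of per-trial probability vectors (or a
#'   `fri_trajectory`; then `which` selects the estimate).
#' @param true_states Integer vector of realized states (or a `task_session`).
#' @param which For a trajectory: `"retrospective"` (default) or `"online"`.
#' @return Scalar log accuracy (<= 0).
#' @examples
#' state_log_accuracy(matrix(0.5, 4, 2), c(1L, 2L, 1L, 1L))  # 4 * log(0.5)
#' @export
state_log_accuracy <- function(beliefs, true_states,
                               which = c("retrospective", "online")) {
  if (inherits(beliefs, "fri_trajectory")) {
    which <- match.arg(which)
    b <- if (which == "online") beliefs$online else beliefs$final
    if (missing(true_states)) true_states <- beliefs$session$state
    beliefs <- b
  }
  if (is.data.frame(true_states)) true_states <- true_states$state
  true_states <- as.integer(true_states)
  if (nrow(beliefs) != length(true_states))
    stop("belief and state sequences must have the same length", call. = FALSE)
  p <- beliefs[cbind(seq_along(true_states), true_states)]
  if (any(p == 0)) {
    warning("belief of exactly zero at a realized state; returning -Inf",
            call. = FALSE)
    return(structure(-Inf, zero_belief = TRUE))
  }
  sum(log(p))
}

#' Log accuracy of parameter beliefs
#'
#' How much posterior density the agent's parameter beliefs place on the
#' generating parameters.  For tied beliefs, supply `true_r`: the value is
#' the log density of the implied Beta posterior over the reversal rate `r`
#' evaluated at `true_r`.  For untied beliefs, supply the true transition
#' matrix `true_A`: the value is the sum over rows of the log Dirichlet
#' posterior density at the true row.
#'
#' @param beliefs A [dirichlet_beliefs] object (e.g. a trajectory's final
#'   beliefs or a per-trial snapshot).
#' @param true_r True reversal rate in (0, 1); tied beliefs only.
#' @param true_A True `K x K` transition matrix; untied alternative.
#' @return Scalar log density.
#' @examples
#' b <- dirichlet_beliefs(matrix(2, 2, 2), matrix(2, 2, 2), tied = TRUE)
#' parameter_log_accuracy(b, true_r = 0.5)  # log(1.5) for a Beta(2, 2)
#' @export
parameter_log_accuracy <- function(beliefs, true_r = NULL, true_A = NULL) {
  stopifnot(inherits(beliefs, "dirichlet_beliefs"))
  if (is.null(true_r) == is.null(true_A))
    stop("supply exactly one of `true_r` or `true_A`", call. = FALSE)
  if (!is.null(true_r)) {
    if (!beliefs$tied)
      stop("`true_r` scoring requires tied beliefs; pass `true_A` instead",
           call. = FALSE)
    dbeta(true_r, shape1 = beliefs$Pi_a[1, 2], shape2 = beliefs$Pi_a[1, 1],
          log = TRUE)
  } else {
    true_A <- as.matrix(true_A)
    stopifnot(nrow(true_A) == beliefs$K, ncol(true_A) == beliefs$K)
    s <- 0
    for (j in seq_len(beliefs$K))
      s <- s + log_ddirichlet(true_A[j, ], beliefs$Pi_a[j, ])
    s
  }
}

# log density of Dir(alpha) at x on the simplex
log_ddirichlet <- function(x, alpha) {
  lgamma(sum(alpha)) - sum(lgamma(alpha)) + sum((alpha - 1) * log(x))
}

#' Per-trial parameter log accuracy along a trajectory
#'
#' Applies [parameter_log_accuracy] to every per-trial parameter-belief
#' snapshot of a dual-estimation trajectory, giving the learning curve of
#' the agent's best-available estimate.
#'
#' @param trajectory A `fri_trajectory` run with `priors`.
#' @inheritParams parameter_log_accuracy
#' @return Numeric vector, one value per trial (offline trajectories carry a
#'   single final estimate and return a constant vector).
#' @export
parameter_accuracy_trajectory <- function(trajectory, true_r = NULL,
                                          true_A = NULL) {
  stopifnot(inherits(trajectory, "fri_trajectory"))
  if (!trajectory$learn)
    stop("parameter accuracy requires a dual-estimation trajectory",
         call. = FALSE)
  if (is.null(trajectory$snapshots)) {
    val <- parameter_log_accuracy(trajectory$final_beliefs, true_r = true_r,
                                  true_A = true_A)
    return(rep(val, trajectory$n_trials))
  }
  vapply(trajectory$snapshots, parameter_log_accuracy, numeric(1),
         true_r = true_r, true_A = true_A)
}

#' Bootstrap standard error of a mean
#'
#' Nonparametric bootstrap SE used to attach uncertainty to ensemble means in
#' the simulation studies.
#'
#' @param x Numeric vector.
#' @param n_boot Number of resamples (default 1000).
#' @return Scalar standard error.
#' @export
boot_se <- function(x, n_boot = 1000L) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(NA_real_)
  idx <- matrix(sample.int(length(x), length(x) * n_boot, replace = TRUE),
                nrow = n_boot)
  stats::sd(rowMeans(matrix(x[idx], nrow = n_boot)))
}
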