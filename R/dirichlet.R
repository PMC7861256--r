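#' Dirichlet beliefs over HMM parameters
#'
#' An agent's beliefs about the transition and emission matrices: each row of
#' `A` (resp. `B`) carries an independent Dirichlet distribution whose
#' concentration parameters are the rows of `Pi_a` (`Pi_b`).  Learning adds
#' expected transition/emission counts to these concentrations.
#'
#' With `tied = TRUE` (the two-state reversal task) the beliefs are
#' constrained to the symmetric parameterization `A = [[1-r, r], [r, 1-r]]`,
#' `B = [[v, 1-v], [1-v, v]]`: both rows of `Pi_a` share one Beta belief over
#' the reversal rate `r`, and both rows of `Pi_b` one Beta belief over the
#' reliability `v`.  Updates must then go through [tie_symmetric] so the
#' matrices stay exactly symmetric.
#'
#' @param Pi_a `K x K` matrix of strictly positive concentrations.
#' @param Pi_b `K x M` matrix of strictly positive concentrations.
#' @param tied Use the symmetric reversal-task parameterization (requires
#'   `K = M = 2` and symmetric matrices).
#' @return An object of class `dirichlet_beliefs`.
#' @examples
#' dirichlet_beliefs(matrix(2, 2, 2), matrix(c(85, 15, 15, 85), 2), tied = TRUE)
#' @export
dirichlet_beliefs <- function(Pi_a, Pi_b, tied = FALSE) {
  Pi_a <- as.matrix(Pi_a); Pi_b <- as.matrix(Pi_b)
  if (any(Pi_a <= 0) || any(Pi_b <= 0))
    stop("concentration parameters must be strictly positive", call. = FALSE)
  if (nrow(Pi_a) != ncol(Pi_a)) stop("`Pi_a` must be square", call. = FALSE)
  if (nrow(Pi_b) != nrow(Pi_a))
    stop("`Pi_a` and `Pi_b` must have the same number of rows", call. = FALSE)
  if (tied) {
    if (nrow(Pi_a) != 2 || ncol(Pi_b) != 2)
      stop("tied beliefs require K = M = 2", call. = FALSE)
    for (m in list(Pi_a, Pi_b))
      if (abs(m[1, 1] - m[2, 2]) > 1e-8 || abs(m[1, 2] - m[2, 1]) > 1e-8)
        stop("tied beliefs require symmetric concentration matrices",
             call. = FALSE)
  }
  structure(list(Pi_a = Pi_a, Pi_b = Pi_b, tied = tied,
                 K = nrow(Pi_a), M = ncol(Pi_b)),
            class = "dirichlet_beliefs")
}

#' @export
print.dirichlet_beliefs <- function(x, ...) {
  cat(sprintf("<dirichlet_beliefs> K = %d, M = %d%s\n", x$K, x$M,
              if (x$tied) ", tied (reversal-task symmetry)" else ""))
  cat("Pi_a:\n"); print(signif(x$Pi_a, 6))
  cat("Pi_b:\n"); print(signif(x$Pi_b, 6))
  if (x$tied) {
    tp <- tied_posterior(x)
    cat(sprintf("implied r ~ Beta(%.3g, %.3g), v ~ Beta(%.3g, %.3g)\n",
                tp$shape1[1], tp$shape2[1], tp$shape1[2], tp$shape2[2]))
  }
  invisible(x)
}

#' Strong priors that pin parameters to known values
#'
#' Scales the true matrices by a large concentration (default `1e6`) so the
#' Dirichlet beliefs are effectively point masses at the generating
#' parameters: the "pure inference" prior regime.
#'
#' @param params True [hmm_params]; all entries must be positive.
#' @param strength Total concentration per row.
#' @param tied Tie symmetrically (reversal task).
#' @return A `dirichlet_beliefs` object.
#' @export
pure_inference_prior <- function(params, strength = 1e6, tied = FALSE) {
  dirichlet_beliefs(strength * params$A, strength * params$B, tied = tied)
}

#' Weak transition prior for dual estimation
#'
#' The dual-estimation regime: emissions stay pinned at their true values
#' (concentration `strength * B`) while every transition concentration is set
#' to a weak common value (default 2), so beliefs about the transition
#' structure are driven almost entirely by the data.
#'
#' @inheritParams pure_inference_prior
#' @param transition_prior Common concentration for every entry of `Pi_a`.
#' @return A `dirichlet_beliefs` object.
#' @examples
#' dual_estimation_prior(reversal_params(0.1, 0.85), tied = TRUE)
#' @export
dual_estimation_prior <- function(params, transition_prior = 2,
                                  strength = 1e6, tied = FALSE) {
  dirichlet_beliefs(matrix(transition_prior, params$K, params$K),
                    strength * params$B, tied = tied)
}

#' Variational and mean point estimates of the parameters
#'
#' For each Dirichlet row the geometric-mean point estimate used inside the
#' message passing is `exp(E[ln theta_jk]) = exp(digamma(pi_jk) -
#' digamma(sum_k pi_jk))`; by Jensen's inequality it is entrywise below the
#' arithmetic mean `pi_jk / sum_k pi_jk`, so the rows are sub-stochastic.
#'
#' @param beliefs A [dirichlet_beliefs] object.
#' @param d Initial-state distribution attached to the returned variational
#'   parameter set (uniform by default).
#' @return A list with `A_hat`, `B_hat` (exponentiated expected logs),
#'   `A_mean`, `B_mean` (Dirichlet means), and `params`, an [hmm_params]-like
#'   object carrying `A_hat`/`B_hat` for use in [forward_backward].
#' @examples
#' b <- dual_estimation_prior(reversal_params(0.1, 0.85), tied = TRUE)
#' expected_parameters(b)$A_mean
#' @export
expected_parameters <- function(beliefs, d = NULL) {
  stopifnot(inherits(beliefs, "dirichlet_beliefs"))
  if (is.null(d)) d <- rep(1 / beliefs$K, beliefs$K)
  A_hat <- exp_digamma_rows(beliefs$Pi_a)
  B_hat <- exp_digamma_rows(beliefs$Pi_b)
  list(A_hat = A_hat, B_hat = B_hat,
       A_mean = beliefs$Pi_a / rowSums(beliefs$Pi_a),
       B_mean = beliefs$Pi_b / rowSums(beliefs$Pi_b),
       params = new_variational_params(A_hat, B_hat, d))
}

exp_digamma_rows <- function(Pi) {
  exp(digamma(Pi) - digamma(rowSums(Pi)))
}

#' Kullback-Leibler divergence between Dirichlet distributions
#'
#' Closed form for `KL(Dir(p) || Dir(q))` over a common simplex:
#' difference of log multivariate Beta functions plus the digamma-weighted
#' concentration differences.
#'
#' @param p,q Vectors of strictly positive concentration parameters of equal
#'   length.
#' @return Non-negative scalar divergence in nats.
#' @examples
#' dirichlet_kl(c(2, 1), c(1, 1))  # KL(Beta(2,1) || Beta(1,1))
#' @export
dirichlet_kl <- function(p, q) {
  if (length(p) != length(q))
    stop("`p` and `q` must have the same length", call. = FALSE)
  if (any(p <= 0) || any(q <= 0))
    stop("concentration parameters must be strictly positive", call. = FALSE)
  sp <- sum(p)
  lgamma(sp) - sum(lgamma(p)) - lgamma(sum(q)) + sum(lgamma(q)) +
    sum((p - q) * (digamma(p) - digamma(sp)))
}

#' Symmetric tying of expected-count increments
#'
#' Projects raw 2x2 expected-count increments onto the symmetric subspace of
#' the reversal-task parameterization: the two diagonal cells are pooled and
#' shared equally, as are the two off-diagonal cells.  Total pseudo-count
#' mass is conserved, the updated concentration matrices remain exactly
#' symmetric, and the update is the exact coordinate-ascent step for a
#' variational family constrained to give both rows the same Beta belief
#' (over the reversal rate `r` for `A`, over the reliability `v` for `B`).
#'
#' @param count_increment_a `2 x 2` expected transition counts.
#' @param count_increment_b `2 x 2` expected emission counts.
#' @param beliefs The (tied) beliefs being updated; used only to validate
#'   that tying applies.
#' @return A list with symmetric `a` and `b` increments.
#' @examples
#' b <- dual_estimation_prior(reversal_params(0.1, 0.85), tied = TRUE)
#' tie_symmetric(matrix(c(.7, .1, .3, .9), 2), matrix(c(1, 0, 0, 1), 2), b)
#' @export
tie_symmetric <- function(count_increment_a, count_increment_b,
                          beliefs = NULL) {
  if (!is.null(beliefs)) {
    stopifnot(inherits(beliefs, "dirichlet_beliefs"))
    if (!beliefs$tied)
      stop("`tie_symmetric()` requires tied beliefs", call. = FALSE)
  }
  list(a = symmetrize2(count_increment_a), b = symmetrize2(count_increment_b))
}

symmetrize2 <- function(m) {
  stopifnot(nrow(m) == 2, ncol(m) == 2)
  dg <- (m[1, 1] + m[2, 2]) / 2
  off <- (m[1, 2] + m[2, 1]) / 2
  matrix(c(dg, off, off, dg), 2)
}

#' Implied Beta posteriors of tied beliefs
#'
#' For tied beliefs each row of `Pi_a` is `Dir(stay, reverse)`, a Beta belief
#' over the reversal rate `r` (and analogously `Pi_b` over the reliability
#' `v`).  Returns the Beta parameters with posterior means and standard
#' deviations.
#'
#' @param beliefs A tied [dirichlet_beliefs] object.
#' @return A tibble with one row per parameter (`r`, `v`): columns
#'   `parameter`, `shape1`, `shape2`, `mean`, `sd`.
#' @export
tied_posterior <- function(beliefs) {
  stopifnot(inherits(beliefs, "dirichlet_beliefs"))
  if (!beliefs$tied)
    stop("`tied_posterior()` requires tied beliefs", call. = FALSE)
  # r is the off-diagonal (reversal) direction; v the diagonal (match) one
  mk <- function(shape1, shape2) {
    s <- shape1 + shape2
    c(mean = shape1 / s, sd = sqrt(shape1 * shape2 / (s^2 * (s + 1))))
  }
  r <- mk(beliefs$Pi_a[1, 2], beliefs$Pi_a[1, 1])
  v <- mk(beliefs$Pi_b[1, 1], beliefs$Pi_b[1, 2])
  tibble::tibble(parameter = c("r", "v"),
                 shape1 = c(beliefs$Pi_a[1, 2], beliefs$Pi_b[1, 1]),
                 shape2 = c(beliefs$Pi_a[1, 1], beliefs$Pi_b[1, 2]),
                 mean = unname(c(r["mean"], v["mean"])),
                 sd = unname(c(r["sd"], v["sd"])))
}

#' Serialize beliefs to and from JSON
#'
#' @param beliefs A [dirichlet_beliefs] object.
#' @param path File path.
#' @return `read_beliefs()` returns a `dirichlet_beliefs` object;
#'   `write_beliefs()` returns `beliefs` invisibly.
#' @export
write_beliefs <- function(beliefs, path) {
  jsonlite::write_json(list(Pi_a = beliefs$Pi_a, Pi_b = beliefs$Pi_b,
                            tied = beliefs$tied),
                       path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(beliefs)
}

#' @rdname write_beliefs
#' @export
read_beliefs <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  dirichlet_beliefs(x$Pi_a, x$Pi_b, tied = isTRUE(x$tied))
}
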