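#' Initialize a finite-retrospective-inference agent
#'
#' Creates the mutable state of a sliding-window agent that performs
#' fixed-lag smoothing with window length `n`: on every trial the agent
#' re-estimates beliefs about the states inside the window (seeded by the
#' filtered "anchor" belief at the timestep just before the window) and, when
#' a timestep leaves the window, banks its final smoothed marginal and
#' dual-slice marginal into the fixed-lag Dirichlet accumulators exactly
#' once.  Supply `priors` for dual estimation (states and parameters learned
#' together) or `params` for pure inference with known parameters.
#'
#' @param n Window length in trials (>= 1).
#' @param priors [dirichlet_beliefs] prior for dual estimation.
#' @param params [hmm_params] for pure inference (mutually exclusive with
#'   `priors`).
#' @param d Initial-state distribution (default uniform).
#' @param tolerance_scale,max_iters Within-window variational convergence
#'   control, as in [vb_fit].
#' @return A `window_state` list: current time `t`, window length `n`, the
#'   anchor belief, accumulated concentrations, and the window's
#'   observations.
#' @seealso [fri_step()], [run_session()]
#' @export
fri_init <- function(n, priors = NULL, params = NULL, d = NULL,
                     tolerance_scale = 1e-6, max_iters = 500L) {
  if (is.null(priors) == is.null(params))
    stop("supply exactly one of `priors` (dual estimation) or `params` (pure inference)",
         call. = FALSE)
  n <- as.integer(n)
  if (n < 1) stop("window length `n` must be >= 1", call. = FALSE)
  learn <- !is.null(priors)
  K <- if (learn) priors$K else params$K
  M <- if (learn) priors$M else params$M
  if (is.null(d)) d <- rep(1 / K, K)
  check_belief(d, K)
  structure(list(
    t = 0L, n = n, K = K, M = M, learn = learn,
    priors = priors, params = params, d = d,
    anchor = d,                # p(x_{f-1} | o_1:f-1); d while the window starts at trial 1
    anchor_transition = FALSE, # becomes TRUE once the anchor is a filtered posterior
    accum_a = if (learn) priors$Pi_a else NULL,  # fixed-lag concentrations
    accum_b = if (learn) priors$Pi_b else NULL,
    window_obs = integer(0),
    tolerance_scale = tolerance_scale, max_iters = as.integer(max_iters),
    last_fit = NULL), class = "window_state")
}

#' Advance a finite-retrospective agent by one observation
#'
#' Appends the observation, runs within-window smoothing (a converged
#' variational fit under dual estimation, a single forward-backward pass
#' under pure inference), and, once the window is full, retires its oldest
#' timestep: that trial's smoothed marginal (and the dual-slice marginal
#' linking it to its predecessor) is added once to the fixed-lag
#' accumulators, and the anchor advances to the filtered posterior at the
#' retired time.  Within-window expected counts are added on top of the
#' accumulators to form the agent's full current parameter estimate, so no
#' observation is ever double counted however much successive windows
#' overlap.
#'
#' @param state A `window_state` from [fri_init] or a previous step.
#' @param observation A single observation: integer code or length-`M`
#'   one-hot vector.
#' @return A list with `state` (updated), `online` (the new filtered belief
#'   `p(x_t | o_1:t)`), `finalized` (`NULL`, or `list(trial=, belief=)` for a
#'   trial that just left the window), and `estimate` (the full posterior
#'   [dirichlet_beliefs] at this trial under dual estimation, else `NULL`).
#' @export
fri_step <- function(state, observation) {
  stopifnot(inherits(state, "window_state"))
  o <- if (length(observation) > 1) which(observation == 1) else as.integer(observation)
  if (length(o) != 1 || is.na(o) || o < 1 || o > state$M)
    stop("`observation` must be a single 1..M code or one-hot vector", call. = FALSE)
  state$t <- state$t + 1L
  state$window_obs <- c(state$window_obs, o)

  if (state$learn) {
    fit <- vb_engine(state$window_obs, state$accum_a, state$accum_b,
                     state$priors$tied, state$anchor, state$anchor_transition,
                     state$tolerance_scale, state$max_iters)
    if (!fit$converged)
      warning(sprintf("window ending at trial %d: variational updates hit max_iters",
                      state$t), call. = FALSE)
    fb <- fit$fb
    estimate <- dirichlet_beliefs(fit$post_a, fit$post_b,
                                  tied = state$priors$tied)
  } else {
    fit <- NULL
    fb <- cpp_fb(state$window_obs, state$params$A, state$params$B,
                 state$anchor, state$anchor_transition, FALSE)
    estimate <- NULL
  }
  online <- fb$alpha[nrow(fb$alpha), ]  # beta at the window end is all-ones
  state$last_fit <- list(gamma = fb$gamma,
                         first_trial = state$t - length(state$window_obs) + 1L)

  finalized <- NULL
  if (length(state$window_obs) == state$n) {
    first <- state$t - state$n + 1L
    finalized <- list(trial = first, belief = fb$gamma[1, ])
    if (state$learn) {
      inc_b <- tcrossprod(fb$gamma[1, ], one_hot(state$window_obs[1], state$M)[1, ])
      inc_a <- if (state$anchor_transition) fb$xi[, , 1] else NULL
      if (state$priors$tied) {
        inc_b <- symmetrize2(inc_b)
        if (!is.null(inc_a)) inc_a <- symmetrize2(inc_a)
      }
      state$accum_b <- state$accum_b + inc_b
      if (!is.null(inc_a)) state$accum_a <- state$accum_a + inc_a
    }
    state$anchor <- fb$alpha[1, ]   # filtered posterior at the retired time
    state$anchor_transition <- TRUE
    state$window_obs <- state$window_obs[-1]
  }
  list(state = state, online = online, finalized = finalized,
       estimate = estimate)
}

#' Run a finite-retrospective agent over a whole session
#'
#' Iterates [fri_step] over the `T` trials of a session and assembles the
#' belief trajectory: the online filtered belief recorded as each trial
#' arrives, the final retrospective belief recorded when each trial leaves
#' the window (trials still inside the window at session end take their
#' marginals from the last converged window fit), and, under dual
#' estimation, the per-trial posterior parameter beliefs.
#'
#' @param session A `task_session` tibble (or anything
#'   [as_observation_codes] accepts; then `true_state` scoring columns are
#'   unavailable).
#' @inheritParams fri_init
#' @return A `fri_trajectory` object; see [tidy.fri_trajectory] and
#'   [glance.fri_trajectory].
#' @examples
#' sess <- sample_session(reversal_params(0.1, 0.85), 32, seed = 2)
#' traj <- run_session(sess, n = 4,
#'                     priors = dual_estimation_prior(attr(sess, "params"),
#'                                                    tied = TRUE))
#' glance(traj)
#' @export
run_session <- function(session, n, priors = NULL, params = NULL, d = NULL,
                        tolerance_scale = 1e-6, max_iters = 500L) {
  obs <- as_observation_codes(session)
  T_ <- length(obs)
  if (n < 1 || n > T_)
    stop("window length `n` must lie in [1, T]", call. = FALSE)
  st <- fri_init(n, priors = priors, params = params, d = d,
                 tolerance_scale = tolerance_scale, max_iters = max_iters)
  K <- st$K
  online <- final <- matrix(NA_real_, T_, K)
  snapshots <- if (st$learn) vector("list", T_) else NULL
  for (t in seq_len(T_)) {
    stepped <- fri_step(st, obs[t])
    st <- stepped$state
    online[t, ] <- stepped$online
    if (!is.null(stepped$finalized))
      final[stepped$finalized$trial, ] <- stepped$finalized$belief
    if (st$learn) snapshots[[t]] <- stepped$estimate
  }
  # flush trials still inside the window from the last converged smoother
  lf <- st$last_fit
  remaining <- which(is.na(final[, 1]))
  if (length(remaining))
    final[remaining, ] <- lf$gamma[remaining - lf$first_trial + 1L, , drop = FALSE]
  new_fri_trajectory(session = session, online = online, final = final,
                     snapshots = snapshots, n = as.integer(n),
                     learn = st$learn, priors = priors, params = params,
                     final_beliefs = if (st$learn) snapshots[[T_]] else NULL,
                     offline = FALSE, d = st$d)
}

#' Offline (fixed-interval) reference agent
#'
#' The comparison agent that sees the whole session at once: a single
#' variational fit (or, for pure inference, one full forward-backward pass)
#' over all `T` trials.  Retrospective beliefs are the full smoothed
#' marginals; the agent's filtered beliefs are recomputed under its final
#' converged parameter estimates.  Equivalent to [run_session] with
#' `n = T` in its final retrospective beliefs and final parameter estimates.
#'
#' @inheritParams run_session
#' @return A `fri_trajectory` object flagged `offline`.
#' @export
run_offline <- function(session, priors = NULL, params = NULL, d = NULL,
                        tolerance_scale = 1e-6, max_iters = 500L) {
  if (is.null(priors) == is.null(params))
    stop("supply exactly one of `priors` or `params`", call. = FALSE)
  obs <- as_observation_codes(session)
  T_ <- length(obs)
  if (!is.null(priors)) {
    fit <- vb_fit(obs, priors, d = d, tolerance_scale = tolerance_scale,
                  max_iters = max_iters)
    filtered <- cpp_forward(obs, fit$A_hat, fit$B_hat, fit$d, FALSE)$alpha
    new_fri_trajectory(session = session, online = filtered,
                       final = fit$gamma,
                       snapshots = NULL, n = T_, learn = TRUE,
                       priors = priors, params = NULL,
                       final_beliefs = fit$beliefs, offline = TRUE, d = fit$d)
  } else {
    if (is.null(d)) d <- params$d
    fb <- forward_backward(obs, params, start_belief = d, want_xi = FALSE)
    new_fri_trajectory(session = session, online = fb$alpha, final = fb$gamma,
                       snapshots = NULL, n = T_, learn = FALSE,
                       priors = NULL, params = params, final_beliefs = NULL,
                       offline = TRUE, d = d)
  }
}

new_fri_trajectory <- function(session, online, final, snapshots, n, learn,
                               priors, params, final_beliefs, offline, d) {
  structure(list(session = session, online = online, final = final,
                 snapshots = snapshots, n = n, learn = learn,
                 priors = priors, params = params,
                 final_beliefs = final_beliefs, offline = offline, d = d,
                 n_trials = nrow(online), K = ncol(online)),
            class = "fri_trajectory")
}

#' @export
print.fri_trajectory <- function(x, ...) {
  cat(sprintf("<fri_trajectory> %s agent, %s, T = %d trials, K = %d states\n",
              if (x$offline) "offline (fixed-interval)"
              else sprintf("fixed-lag (n = %d)", x$n),
              if (x$learn) "dual estimation" else "pure inference",
              x$n_trials, x$K))
  print(glance(x))
  invisible(x)
}

#' Tidy a belief trajectory
#'
#' @param x A `fri_trajectory`.
#' @param ... Unused.
#' @return A long tibble: `trial`, `estimate` ("online" or "retrospective"),
#'   `state`, `probability`, plus `true_state` and `observation` when the
#'   session carries them.
#' @export
tidy.fri_trajectory <- function(x, ...) {
  K <- x$K
  wide <- function(mat, label) {
    df <- tibble::as_tibble(mat, .name_repair = ~ paste0("s", seq_len(K)))
    df$trial <- seq_len(nrow(mat))
    df$estimate <- label
    tidyr::pivot_longer(df, cols = dplyr::all_of(paste0("s", seq_len(K))),
                        names_to = "state", values_to = "probability",
                        names_prefix = "s", names_transform = as.integer)
  }
  out <- dplyr::bind_rows(wide(x$online, "online"),
                          wide(x$final, "retrospective"))
  if (is.data.frame(x$session) && all(c("state", "observation") %in% names(x$session)))
    out <- dplyr::left_join(
      out,
      tibble::tibble(trial = x$session$trial, true_state = x$session$state,
                     observation = x$session$observation),
      by = "trial")
  dplyr::arrange(out, .data$estimate, .data$trial, .data$state)
}

#' Trajectory summary
#'
#' One-row summary of a trajectory: the log-probability the online and final
#' retrospective marginals assign to the realized hidden-state path and,
#' under tied dual estimation, the final posterior over the reversal rate.
#'
#' @param x A `fri_trajectory`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.fri_trajectory <- function(x, ...) {
  out <- tibble::tibble(n_window = x$n, n_trials = x$n_trials,
                        offline = x$offline, learn = x$learn)
  if (is.data.frame(x$session) && "state" %in% names(x$session)) {
    truth <- x$session$state
    out$state_log_retrospective <- state_log_accuracy(x$final, truth)
    out$state_log_online <- state_log_accuracy(x$online, truth)
  }
  if (x$learn && !is.null(x$final_beliefs) && x$final_beliefs$tied) {
    tp <- tied_posterior(x$final_beliefs)
    out$r_mean <- tp$mean[tp$parameter == "r"]
    out$r_sd <- tp$sd[tp$parameter == "r"]
  }
  out
}

#' Plot a belief trajectory
#'
#' Shows the probability assigned to each hidden state across trials, for the
#' online (filtered) and final retrospective estimates, with the true states
#' (crosses at probability 1) and observations (open circles at 0) overlaid
#' when available.
#'
#' @param object A `fri_trajectory`.
#' @param states Which states to draw (default state 2, matching the usual
#'   single-panel reversal-task display when `K = 2`; use `1:K` to facet).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fri_trajectory <- function(object, states = NULL, ...) {
  if (is.null(states)) states <- if (object$K == 2) 2L else seq_len(object$K)
  df <- dplyr::filter(tidy(object), .data$state %in% states)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$trial,
                                        y = .data$probability,
                                        colour = .data$estimate)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ state, ncol = 1,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "trial", y = "belief p(state)",
                  colour = NULL,
                  title = sprintf("%s, %s",
                                  if (object$offline) "offline smoothing"
                                  else sprintf("fixed-lag window n = %d", object$n),
                                  if (object$learn) "dual estimation"
                                  else "pure inference")) +
    ggplot2::ylim(0, 1)
  if ("true_state" %in% names(df)) {
    marks <- dplyr::distinct(df, .data$trial, .data$true_state,
                             .data$observation, .data$state)
    p <- p +
      ggplot2::geom_point(data = marks,
                          ggplot2::aes(x = .data$trial,
                                       y = as.numeric(.data$true_state == .data$state)),
                          inherit.aes = FALSE, shape = 4, colour = "black",
                          size = 1.5) +
      ggplot2::geom_point(data = marks,
                          ggplot2::aes(x = .data$trial,
                                       y = as.numeric(.data$observation == .data$state)),
                          inherit.aes = FALSE, shape = 1, colour = "red",
                          size = 1.2, alpha = 0.6)
  }
  p
}
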