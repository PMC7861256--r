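test_that("a window of one is exactly filtering under pure inference", {
  p <- reversal_params(0.1, 0.85)
  sess <- sample_session(p, 64, seed = 1)
  traj <- run_session(sess, n = 1, params = p)
  fwd <- forward_pass(sess, p)
  expect_identical(traj$online, fwd$alpha)
  expect_identical(traj$final, traj$online)
})

test_that("a full-length window is exactly fixed-interval smoothing under pure inference", {
  p <- random_hmm_params(0.8, seed = 6)
  sess <- sample_session(p, 48, seed = 2)
  traj <- run_session(sess, n = 48, params = p)
  fb <- forward_backward(sess, p, want_xi = FALSE)
  expect_equal(traj$final, fb$gamma, tolerance = 1e-12)
  off <- run_offline(sess, params = p)
  expect_equal(traj$final, off$final, tolerance = 1e-12)
})

test_that("online filtered beliefs are window-independent when parameters are known", {
  p <- reversal_params(0.1, 0.85)
  sess <- sample_session(p, 40, seed = 3)
  ref <- run_session(sess, 1, params = p)$online
  for (n in c(2, 5, 16, 40))
    expect_identical(run_session(sess, n, params = p)$online, ref)
})

test_that("intermediate windows interpolate between filtering and smoothing", {
  p <- reversal_params(0.1, 0.85)
  sess <- sample_session(p, 32, seed = 8)
  fwd <- forward_pass(sess, p)
  fb <- forward_backward(sess, p, want_xi = FALSE)
  traj <- run_session(sess, n = 4, params = p)
  # each finalized belief conditions on observations up to its window's end:
  # p(x_t | o_1:t+3), computable by smoothing the truncated session
  for (t in c(1, 7, 20)) {
    fbt <- forward_backward(sess$observation[1:(t + 3)], p, want_xi = FALSE)
    expect_equal(traj$final[t, ], fbt$gamma[t, ], tolerance = 1e-12)
  }
  # trials still in the window at session end get full-smoothing beliefs
  expect_equal(traj$final[30:32, ], fb$gamma[30:32, ], tolerance = 1e-12)
})

test_that("sliding-window accumulation never double-counts evidence", {
  p <- reversal_params(0.1, 0.85)
  sess <- sample_session(p, 50, seed = 4)
  priors <- dual_estimation_prior(p, tied = TRUE)
  for (n in c(1, 3, 8, 50)) {
    traj <- run_session(sess, n, priors = priors)
    expect_equal(sum(traj$final_beliefs$Pi_a - priors$Pi_a), 49,
                 tolerance = 1e-8)
    expect_equal(sum(traj$final_beliefs$Pi_b - priors$Pi_b), 50,
                 tolerance = 1e-8)
    # snapshots at every trial t carry t-1 and t units of evidence
    for (t in c(1, 2, 25)) {
      expect_equal(sum(traj$snapshots[[t]]$Pi_a - priors$Pi_a), t - 1,
                   tolerance = 1e-8)
      expect_equal(sum(traj$snapshots[[t]]$Pi_b - priors$Pi_b), t,
                   tolerance = 1e-8)
    }
  }
  # untied accumulation conserves mass too
  p3 <- random_hmm_params(0.8, seed = 9)
  sess3 <- sample_session(p3, 30, seed = 10)
  pri3 <- dirichlet_beliefs(matrix(2, 3, 3), 1e6 * p3$B)
  tr3 <- run_session(sess3, 5, priors = pri3)
  expect_equal(sum(tr3$final_beliefs$Pi_a - pri3$Pi_a), 29, tolerance = 1e-8)
  expect_equal(sum(tr3$final_beliefs$Pi_b - pri3$Pi_b), 30, tolerance = 1e-8)
})

test_that("dual estimation with a full window reproduces the offline fit", {
  p <- reversal_params(0.1, 0.85)
  sess <- sample_session(p, 64, seed = 5)
  priors <- dual_estimation_prior(p, tied = TRUE)
  trT <- run_session(sess, 64, priors = priors)
  off <- run_offline(sess, priors = priors)
  expect_lt(max(abs(trT$final - off$final)), 1e-6)
  expect_lt(max(abs(trT$final_beliefs$Pi_a - off$final_beliefs$Pi_a)), 1e-6)
  expect_lt(max(abs(trT$final_beliefs$Pi_b - off$final_beliefs$Pi_b)), 1e-6)
})

test_that("identical seeds and configs reproduce trajectories bit for bit", {
  p <- reversal_params(0.1, 0.85)
  priors <- dual_estimation_prior(p, tied = TRUE)
  run <- function() {
    sess <- sample_session(p, 32, seed = 77)
    run_session(sess, 4, priors = priors)
  }
  a <- run(); b <- run()
  expect_identical(a$online, b$online)
  expect_identical(a$final, b$final)
  expect_identical(a$final_beliefs, b$final_beliefs)
})

test_that("noiseless sessions drive reliability beliefs toward 1", {
  p <- reversal_params(r = 0.05, v = 1)
  sess <- sample_session(p, 48, seed = 12)
  # v = 1 makes every observation match its state
  expect_identical(sess$observation, sess$state)
  # pure inference: deterministic emissions give one-hot online beliefs
  pure <- run_session(sess, 4, params = p)
  expect_true(all(pure$online %in% c(0, 1)))
  expect_true(all(pure$online[cbind(1:48, sess$state)] == 1))
  # learning v needs a prior that breaks the tied model's v <-> 1-v label
  # symmetry; a weak Beta(2, 1) belief over v suffices
  pri <- dirichlet_beliefs(matrix(2, 2, 2), matrix(c(2, 1, 1, 2), 2),
                           tied = TRUE)
  traj <- run_session(sess, 4, priors = pri)
  v_means <- vapply(traj$snapshots,
                    function(b) tied_posterior(b)$mean[2], numeric(1))
  expect_gt(v_means[48], v_means[1])
  expect_gt(v_means[48], 0.9)
})

test_that("retrospection improves state log-scores on most reversal sessions", {
  p <- reversal_params(0.1, 0.85)
  better <- logical(100)
  for (i in 1:100) {
    sess <- sample_session(p, 64, seed = 1000 + i)
    traj <- run_session(sess, 2, params = p)
    better[i] <- state_log_accuracy(traj$final, sess$state) >=
      state_log_accuracy(traj$online, sess$state)
  }
  expect_gte(sum(better), 95)
})

test_that("offline filtered beliefs outperform online ones under dual estimation", {
  p <- reversal_params(0.1, 0.85)
  priors <- dual_estimation_prior(p, tied = TRUE)
  diffs <- numeric(40)
  for (i in 1:40) {
    sess <- sample_session(p, 64, seed = 2000 + i)
    on <- run_session(sess, 4, priors = priors)
    off <- run_offline(sess, priors = priors)
    diffs[i] <- state_log_accuracy(off$online, sess$state) -
      state_log_accuracy(on$online, sess$state)
  }
  expect_gt(mean(diffs), 0)
})

test_that("fri_step exposes the window state machine and validates input", {
  p <- reversal_params(0.1, 0.85)
  st <- fri_init(2, params = p)
  expect_error(fri_step(st, 5L), "1..M")
  s1 <- fri_step(st, 1L)
  expect_null(s1$finalized)            # window not yet full
  expect_equal(sum(s1$online), 1, tolerance = 1e-12)
  s2 <- fri_step(s1$state, c(0L, 1L))  # one-hot form
  expect_equal(s2$finalized$trial, 1L)
  expect_equal(sum(s2$finalized$belief), 1, tolerance = 1e-12)
  expect_error(fri_init(0, params = p), ">= 1")
  expect_error(fri_init(2), "exactly one")
  expect_error(fri_init(2, params = p, priors = dual_estimation_prior(p, tied = TRUE)),
               "exactly one")
})

test_that("trajectories tidy, glance and plot", {
  p <- reversal_params(0.1, 0.85)
  sess <- sample_session(p, 16, seed = 14)
  traj <- run_session(sess, 4, priors = dual_estimation_prior(p, tied = TRUE))
  td <- tidy(traj)
  expect_equal(nrow(td), 16 * 2 * 2)
  expect_true(all(c("trial", "estimate", "state", "probability",
                    "true_state", "observation") %in% names(td)))
  sums <- dplyr::summarise(dplyr::group_by(td, estimate, trial),
                           s = sum(probability))
  expect_equal(sums$s, rep(1, 32), tolerance = 1e-9)
  g <- glance(traj)
  expect_lte(g$state_log_retrospective, 0)
  expect_s3_class(autoplot(traj), "ggplot")
})
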