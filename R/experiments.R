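#' Configure a simulation study
#'
#' Bundles and validates the settings of the two simulation studies.  The
#' reversal study simulates `replicates` sessions of a two-state
#' probabilistic reversal task (reversal rate `r`, reliability `v`); the
#' random-HMM study simulates `replicates` instantiations of each of
#' `n_hmms` randomly drawn three-state HMMs at each emission-diagonal value
#' in `emission_diags`.  Every replicate is run once per window length plus
#' once by the offline fixed-interval reference agent, under one of two
#' prior regimes: `pure_inference` (concentrations `strength` times the true
#' matrices, pinning parameters to their true values) or `dual_estimation`
#' (emissions pinned, every transition concentration set to
#' `transition_prior` so the transition structure must be learned).
#'
#' @param task `"reversal"` or `"random_hmm"`.
#' @param regime `"pure_inference"` or `"dual_estimation"`.
#' @param r,v Reversal-task generative parameters.
#' @param emission_diags Diagonal emission reliabilities swept in the
#'   random-HMM study.
#' @param n_hmms Number of random HMMs drawn.
#' @param n_trials Session length `T`.
#' @param replicates Sessions per condition (>= 1).
#' @param windows Fixed-lag window lengths, all within `[1, n_trials]`.
#' @param transition_prior,strength Prior concentrations (see
#'   [dual_estimation_prior]).
#' @param seed Master seed; every session and bootstrap draw derives from it.
#' @param n_boot Bootstrap resamples for ensemble standard errors.
#' @return An `experiment_config` list.
#' @examples
#' experiment_config(task = "reversal", regime = "pure_inference",
#'                   replicates = 2, n_trials = 16, windows = c(1, 4))
#' @export
experiment_config <- function(task = c("reversal", "random_hmm"),
                              regime = c("pure_inference", "dual_estimation"),
                              r = 0.1, v = 0.85,
                              emission_diags = c(0.65, 0.80, 0.95),
                              n_hmms = 2,
                              n_trials = 128, replicates = 100,
                              windows = c(1, 2, 4, 8, 16),
                              transition_prior = 2, strength = 1e6,
                              seed = 1, n_boot = 1000) {
  task <- match.arg(task)
  regime <- match.arg(regime)
  windows <- sort(unique(as.integer(windows)))
  if (replicates < 1) stop("`replicates` must be >= 1", call. = FALSE)
  if (any(windows < 1) || any(windows > n_trials))
    stop("`windows` must lie within [1, n_trials]", call. = FALSE)
  if (r < 0 || r > 1 || v < 0 || v > 1)
    stop("`r` and `v` must lie in [0, 1]", call. = FALSE)
  structure(list(task = task, regime = regime, r = r, v = v,
                 emission_diags = emission_diags, n_hmms = as.integer(n_hmms),
                 n_trials = as.integer(n_trials),
                 replicates = as.integer(replicates), windows = windows,
                 transition_prior = transition_prior, strength = strength,
                 seed = as.integer(seed), n_boot = as.integer(n_boot)),
            class = "experiment_config")
}

#' Read an experiment configuration from JSON or YAML
#'
#' Keys match the arguments of [experiment_config]; unknown keys are
#' rejected.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return An `experiment_config`.
#' @examples
#' read_experiment_config(system.file("extdata", "reversal_small.json",
#'                                    package = "retroinfer"))
#' @export
read_experiment_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(experiment_config))
  bad <- setdiff(names(x), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(experiment_config, x)
}

#' Run a simulation study
#'
#' Executes the configured study: for each replicate one session is sampled
#' and analysed by every fixed-lag agent (one per window length) and by the
#' offline fixed-interval agent, all on the same data so comparisons are
#' paired.  Per run the study records the log accuracy of the final
#' retrospective and online filtered state beliefs and, under dual
#' estimation, the final and trial-averaged parameter log accuracy and the
#' posterior-mean error of the reversal rate.  A failed run is recorded with
#' its error message and does not abort the sweep.
#'
#' @param config An [experiment_config].
#' @return A `fri_experiment` with `$results` (one row per replicate x
#'   agent), `$summary` (ensemble means with bootstrap standard errors and
#'   per-replicate differences from the offline reference) and `$config`.
#' @examples
#' cfg <- experiment_config(task = "reversal", regime = "pure_inference",
#'                          replicates = 2, n_trials = 16, windows = c(1, 4),
#'                          n_boot = 50)
#' run_experiment(cfg)$summary
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  withr::local_seed(config$seed)
  results <-
    if (config$task == "reversal") run_reversal_study(config)
    else run_random_hmm_study(config)
  out <- structure(list(results = results,
                        summary = summarize_results(results, config$n_boot),
                        config = config),
                   class = "fri_experiment")
  out
}

run_reversal_study <- function(config) {
  params <- reversal_params(config$r, config$v)
  agents <- make_agents(config, params, tied = TRUE)
  seeds <- sample.int(.Machine$integer.max - 1L, config$replicates)
  purrr::map_dfr(seq_len(config$replicates), function(rep) {
    sess <- sample_session(params, config$n_trials, seed = seeds[rep])
    runs <- run_agents(sess, config, agents)
    runs$task <- "reversal"; runs$replicate <- rep
    runs
  })
}

run_random_hmm_study <- function(config) {
  hmm_seeds <- sample.int(.Machine$integer.max - 1L, config$n_hmms)
  purrr::map_dfr(seq_len(config$n_hmms), function(h) {
    base <- random_hmm_params(emission_diag = config$emission_diags[1],
                              seed = hmm_seeds[h])
    purrr::map_dfr(config$emission_diags, function(diag_v) {
      M <- base$M
      B <- matrix((1 - diag_v) / (M - 1), base$K, M); diag(B) <- diag_v
      params <- hmm_params(base$A, B)
      agents <- make_agents(config, params, tied = FALSE)
      seeds <- sample.int(.Machine$integer.max - 1L, config$replicates)
      purrr::map_dfr(seq_len(config$replicates), function(rep) {
        sess <- sample_session(params, config$n_trials, seed = seeds[rep])
        runs <- run_agents(sess, config, agents)
        runs$task <- "random_hmm"; runs$hmm <- h
        runs$emission_diag <- diag_v; runs$replicate <- rep
        runs
      })
    })
  })
}

# Prior/parameter setup shared by both studies.  Pure inference holds the
# parameters fixed at the strong-prior variational point estimates (the
# learning update is inert at concentration `strength`), so the within-window
# fit is a single forward-backward pass.
make_agents <- function(config, params, tied) {
  if (config$regime == "pure_inference") {
    strong <- pure_inference_prior(params, strength = config$strength,
                                   tied = tied)
    list(params = expected_parameters(strong)$params, priors = NULL,
         true_params = params)
  } else {
    list(params = NULL,
         priors = dual_estimation_prior(params,
                                        transition_prior = config$transition_prior,
                                        strength = config$strength,
                                        tied = tied),
         true_params = params)
  }
}

run_agents <- function(sess, config, agents) {
  one <- function(window) {
    tryCatch({
      traj <- if (is.na(window))
        run_offline(sess, priors = agents$priors, params = agents$params)
      else run_session(sess, n = window, priors = agents$priors,
                       params = agents$params)
      measure_run(traj, sess, agents, window)
    }, error = function(e) {
      tibble::tibble(agent = if (is.na(window)) "offline" else "fixed_lag",
                     window = window, error = conditionMessage(e))
    })
  }
  purrr::map_dfr(c(config$windows, NA_integer_), one)
}

measure_run <- function(traj, sess, agents, window) {
  row <- tibble::tibble(
    agent = if (is.na(window)) "offline" else "fixed_lag",
    window = window,
    state_log_retro = state_log_accuracy(traj$final, sess$state),
    state_log_online = state_log_accuracy(traj$online, sess$state),
    error = NA_character_)
  if (traj$learn) {
    tied <- traj$final_beliefs$tied
    true_r <- if (tied) agents$true_params$A[1, 2] else NULL
    true_A <- if (tied) NULL else agents$true_params$A
    row$param_log_final <- parameter_log_accuracy(traj$final_beliefs,
                                                  true_r = true_r,
                                                  true_A = true_A)
    row$param_log_mean <- mean(parameter_accuracy_trajectory(
      traj, true_r = true_r, true_A = true_A))
    if (tied) {
      tp <- tied_posterior(traj$final_beliefs)
      row$r_mean <- tp$mean[tp$parameter == "r"]
      row$r_abs_error <- abs(row$r_mean - true_r)
    }
  }
  row
}

summarize_results <- function(results, n_boot) {
  metrics <- intersect(c("state_log_retro", "state_log_online",
                         "param_log_final", "param_log_mean", "r_abs_error"),
                       names(results))
  group_vars <- intersect(c("task", "emission_diag", "agent", "window"),
                          names(results))
  rep_vars <- intersect(c("task", "hmm", "emission_diag", "replicate"),
                        names(results))
  long <- tidyr::pivot_longer(results, cols = dplyr::all_of(metrics),
                              names_to = "metric", values_to = "value")
  offline <- dplyr::select(
    dplyr::filter(long, .data$agent == "offline"),
    dplyr::all_of(c(rep_vars, "metric")), offline_value = "value")
  long <- dplyr::left_join(long, offline, by = c(rep_vars, "metric"))
  long$rel_value <- long$value - long$offline_value
  dplyr::summarise(
    dplyr::group_by(long, dplyr::across(dplyr::all_of(c(group_vars, "metric")))),
    n = sum(is.finite(.data$value)),
    mean = mean(.data$value[is.finite(.data$value)]),
    se = boot_se(.data$value, n_boot),
    mean_rel_offline = mean(.data$rel_value[is.finite(.data$rel_value)]),
    se_rel_offline = boot_se(.data$rel_value, n_boot),
    .groups = "drop")
}

#' @export
print.fri_experiment <- function(x, ...) {
  cat(sprintf("<fri_experiment> %s study, %s regime, %d replicates, T = %d\n",
              x$config$task, x$config$regime, x$config$replicates,
              x$config$n_trials))
  n_err <- sum(!is.na(x$results$error))
  if (n_err) cat(sprintf("  %d failed run(s); see $results$error\n", n_err))
  print(x$summary, n = 30)
  invisible(x)
}

#' @export
tidy.fri_experiment <- function(x, ...) x$results

#' @export
glance.fri_experiment <- function(x, ...) {
  tibble::tibble(task = x$config$task, regime = x$config$regime,
                 replicates = x$config$replicates,
                 n_trials = x$config$n_trials,
                 n_windows = length(x$config$windows),
                 failed_runs = sum(!is.na(x$results$error)),
                 seed = x$config$seed)
}

#' Plot ensemble accuracy against window length
#'
#' Mean log accuracy (with bootstrap standard-error bars) of each metric as
#' a function of fixed-lag window length; the offline fixed-interval
#' reference is drawn as a dashed horizontal line.
#'
#' @param object A `fri_experiment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fri_experiment <- function(object, ...) {
  s <- object$summary
  online <- dplyr::filter(s, .data$agent == "fixed_lag")
  offline <- dplyr::filter(s, .data$agent == "offline")
  p <- ggplot2::ggplot(online, ggplot2::aes(x = .data$window, y = .data$mean)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$se,
                                          ymax = .data$mean + .data$se),
                             size = 0.25) +
    ggplot2::geom_hline(data = offline,
                        ggplot2::aes(yintercept = .data$mean),
                        linetype = "dashed") +
    ggplot2::scale_x_continuous(trans = "log2") +
    ggplot2::labs(x = "window length n (log scale)", y = "ensemble mean",
                  title = sprintf("%s study, %s", object$config$task,
                                  gsub("_", " ", object$config$regime)),
                  subtitle = "dashed: offline fixed-interval reference")
  if ("emission_diag" %in% names(s) && length(unique(s$emission_diag)) > 1)
    p + ggplot2::facet_grid(metric ~ emission_diag, scales = "free_y")
  else p + ggplot2::facet_wrap(~ metric, scales = "free_y")
}

#' Write study results to CSV
#'
#' @param x A `fri_experiment`.
#' @param path Output CSV for per-replicate results.
#' @param summary_path Optional CSV for the ensemble summary (defaults to
#'   `path` with a `_summary.csv` suffix).
#' @return `x`, invisibly.
#' @export
write_results <- function(x, path, summary_path = NULL) {
  stopifnot(inherits(x, "fri_experiment"))
  if (is.null(summary_path))
    summary_path <- sub("\\.csv$", "_summary.csv", path)
  readr::write_csv(x$results, path)
  readr::write_csv(x$summary, summary_path)
  invisible(x)
}
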