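#' Simulate a task session from an HMM
#'
#' Samples a hidden state path `x_1:T` (the first state from `d`, each
#' subsequent state from the transition row of its predecessor) and the
#' matching observations `o_1:T` from the emission rows.
#'
#' @param params An [hmm_params] object.
#' @param n_trials Number of trials `T` (>= 1).
#' @param seed Optional integer seed; when supplied the session is
#'   reproducible and the caller's RNG state is left untouched.
#' @return A tibble of class `task_session` with integer columns `trial`,
#'   `state` (1..K) and `observation` (1..M), and attributes `K`, `M` and
#'   `params`.
#' @examples
#' sess <- sample_session(reversal_params(0.1, 0.85), n_trials = 16, seed = 1)
#' head(sess)
#' @export
sample_session <- function(params, n_trials, seed = NULL) {
  stopifnot(inherits(params, "hmm_params"), n_trials >= 1)
  if (!is.null(seed))
    return(withr::with_seed(seed, sample_session(params, n_trials)))
  K <- params$K; M <- params$M
  x <- integer(n_trials)
  x[1] <- sample.int(K, 1L, prob = params$d)
  if (n_trials > 1) {
    u <- runif(n_trials - 1)
    cumA <- t(apply(params$A, 1, cumsum))
    for (t in 2:n_trials)
      x[t] <- 1L + sum(u[t - 1] > cumA[x[t - 1], ])
  }
  o <- integer(n_trials)
  for (k in seq_len(K)) {
    idx <- which(x == k)
    if (length(idx))
      o[idx] <- sample.int(M, length(idx), replace = TRUE, prob = params$B[k, ])
  }
  new_task_session(tibble::tibble(trial = seq_len(n_trials),
                                  state = x, observation = o),
                   K = K, M = M, params = params)
}

new_task_session <- function(df, K, M, params = NULL) {
  structure(df, K = K, M = M, params = params,
            class = c("task_session", class(df)))
}

#' Coerce observations to integer codes
#'
#' Accepts a `task_session` tibble, a plain integer vector of codes, or a
#' one-hot matrix with one row per trial, and returns the 1-based integer
#' codes used by the inference engine.
#'
#' @param x Observations in any of the supported forms.
#' @return Integer vector of observation codes.
#' @export
as_observation_codes <- function(x) {
  if (inherits(x, "task_session") || (is.data.frame(x) && "observation" %in% names(x)))
    return(as.integer(x$observation))
  if (is.matrix(x)) {
    if (any(rowSums(x) != 1) || !all(x %in% c(0, 1)))
      stop("one-hot rows must contain a single 1", call. = FALSE)
    return(as.integer(max.col(x)))
  }
  xi <- as.integer(x)
  if (length(xi) == 0 || any(is.na(xi)) || any(xi < 1))
    stop("observations must be positive integer codes", call. = FALSE)
  xi
}

#' One-hot encoding of integer codes
#'
#' @param codes Integer vector of 1-based category codes.
#' @param size Number of categories.
#' @return A `length(codes) x size` 0/1 matrix with unit row sums.
#' @export
one_hot <- function(codes, size) {
  codes <- as.integer(codes)
  stopifnot(all(codes >= 1), all(codes <= size))
  m <- matrix(0L, length(codes), size)
  m[cbind(seq_along(codes), codes)] <- 1L
  m
}

#' Read and write task sessions as CSV
#'
#' Sessions serialize to plain CSV with integer-coded columns
#' `trial,true_state,observation` (1-based).
#'
#' @param session A `task_session` tibble.
#' @param path File path.
#' @param K,M State/observation space sizes when reading; inferred from the
#'   data if omitted.
#' @return `write_session()` returns `session` invisibly; `read_session()`
#'   returns a `task_session` tibble.
#' @export
write_session <- function(session, path) {
  df <- tibble::tibble(trial = session$trial,
                       true_state = session$state,
                       observation = session$observation)
  readr::write_csv(df, path)
  invisible(session)
}

#' @rdname write_session
#' @export
read_session <- function(path, K = NULL, M = NULL) {
  df <- readr::read_csv(path, col_types = readr::cols(
    trial = readr::col_integer(),
    true_state = readr::col_integer(),
    observation = readr::col_integer()))
  if (is.null(K)) K <- max(df$true_state)
  if (is.null(M)) M <- max(df$observation)
  new_task_session(tibble::tibble(trial = df$trial, state = df$true_state,
                                  observation = df$observation),
                   K = K, M = M)
}
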