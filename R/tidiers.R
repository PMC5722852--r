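#' Tidy a training result
#'
#' One row per restart with its final loss, iteration count, convergence
#' flag and seed (the fitted parameter objects are dropped; use
#' [select_best()] to retrieve the winner).
#'
#' @param x An `mlp_training` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.mlp_training <- function(x, ...) {
  dplyr::select(x$restarts, "restart", "mu", "iterations", "converged",
                "diverged", "seed")
}

#' Summarize a training result in one row
#'
#' @param x An `mlp_training` object.
#' @param ... Unused.
#' @return A one-row tibble: best loss, best restart index, restart count,
#'   parameter count, fraction of converged restarts.
#' @export
glance.mlp_training <- function(x, ...) {
  tibble(
    best_mu = x$restarts$mu[x$best_index],
    best_restart = x$best_index,
    n_restarts = nrow(x$restarts),
    n_params = n_params(x$restarts$params[[1]]),
    prop_converged = mean(x$restarts$converged),
    n_trials = x$n_trials
  )
}

#' Tidy a cross-subject accuracy table
#'
#' @param x An `xsub_matrix`.
#' @param ... Unused.
#' @return The underlying tibble (`h`, `r`, `rho`).
#' @export
tidy.xsub_matrix <- function(x, ...) as_tibble(x)

#' Tidy a difference trace into long format
#'
#' @param x An `erp_diff`.
#' @param ... Unused.
#' @return A tibble with `channel`, `time` (seconds), `delta`.
#' @export
tidy.erp_diff <- function(x, ...) {
  n <- ncol(x$delta)
  tibble(
    channel = rep(x$channels, each = n),
    time = rep((seq_len(n) - 1) / x$fs, times = nrow(x$delta)),
    delta = as.vector(t(x$delta))
  )
}

#' Tidy a time-frequency map into long format
#'
#' @param x An `eeg_tfmap`.
#' @param ... Unused.
#' @return A tibble with `freq`, `time`, `energy`, `coi`.
#' @export
tidy.eeg_tfmap <- function(x, ...) {
  tibble(
    freq = rep(x$freq, times = length(x$time)),
    time = rep(x$time, each = length(x$freq)),
    energy = as.vector(x$energy),
    coi = if (!is.null(x$coi)) as.vector(x$coi) else FALSE
  )
}
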