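#' Construct or initialize multilayer-perceptron parameters
#'
#' The classifier is a feedforward perceptron with logistic units applied
#' *sample-wise*: the input is the 19-vector of channel values at one time
#' sample, propagated through two hidden layers (sizes `h1`, `h2`) to a
#' single output unit, `u = F(W3' F2(W2' F1(W1' x - theta1) - theta2) -
#' theta3)` with `F(eta) = 1/(1 + exp(-eta))`. `mlp_params()` assembles
#' explicit matrices; `init_mlp()` draws all weights and thresholds
#' uniformly from `(-init_range, init_range)` under a seed.
#'
#' @param W1,W2,W3 Weight matrices of sizes `n_in x h1`, `h1 x h2`,
#'   `h2 x 1`.
#' @param theta1,theta2 Threshold vectors of lengths `h1`, `h2`.
#' @param theta3 Scalar output threshold.
#' @return An object of class `mlp_params`.
#' @export
mlp_params <- function(W1, theta1, W2, theta2, W3, theta3) {
  W1 <- as.matrix(W1); W2 <- as.matrix(W2); W3 <- as.matrix(W3)
  if (ncol(W1) != length(theta1) || ncol(W2) != length(theta2) ||
      ncol(W3) != 1L || length(theta3) != 1L ||
      nrow(W2) != ncol(W1) || nrow(W3) != ncol(W2)) {
    abort("inconsistent layer dimensions")
  }
  p <- list(W1 = W1, theta1 = as.numeric(theta1),
            W2 = W2, theta2 = as.numeric(theta2),
            W3 = W3, theta3 = as.numeric(theta3))
  if (!all(vapply(p, function(z) all(is.finite(z)), logical(1)))) {
    abort("all parameters must be finite")
  }
  structure(p, class = "mlp_params")
}

#' @rdname mlp_params
#' @param n_in Number of inputs (EEG channels), default 19.
#' @param h1,h2 Hidden-layer sizes (defaults 19 and 5).
#' @param seed Integer seed for the initialization draw.
#' @param init_range Half-width of the uniform initialization interval.
#' @export
init_mlp <- function(n_in = 19L, h1 = 19L, h2 = 5L, seed = 1L,
                     init_range = 0.5) {
  local_seed(seed, {
    r <- function(n) runif(n, -init_range, init_range)
    mlp_params(
      W1 = matrix(r(n_in * h1), n_in, h1), theta1 = r(h1),
      W2 = matrix(r(h1 * h2), h1, h2), theta2 = r(h2),
      W3 = matrix(r(h2), h2, 1), theta3 = r(1)
    )
  })
}

#' @export
print.mlp_params <- function(x, ...) {
  cat(sprintf("<mlp_params> %d-%d-%d-1 logistic perceptron (%d parameters)\n",
              nrow(x$W1), ncol(x$W1), ncol(x$W2), n_params(x)))
  invisible(x)
}

n_params <- function(p) {
  length(p$W1) + length(p$theta1) + length(p$W2) + length(p$theta2) +
    length(p$W3) + 1L
}

# Forward pass over a samples-by-channels matrix X; returns activations for
# reuse by the Jacobian.
fwd_matrix <- function(params, X) {
  n <- nrow(X)
  A1 <- logistic(X %*% params$W1 - rep(params$theta1, each = n))
  A2 <- logistic(A1 %*% params$W2 - rep(params$theta2, each = n))
  u <- logistic(drop(A2 %*% params$W3) - params$theta3)
  list(A1 = A1, A2 = A2, u = u)
}

#' Propagate one time sample through the network
#'
#' @param params An `mlp_params` object.
#' @param x Numeric input vector (one value per channel, nominally scaled to
#'   `[-1, 1]`).
#' @return The scalar output `u` in (0, 1).
#' @examples
#' p <- init_mlp(seed = 1)
#' forward_sample(p, rep(0, 19)) # logistic network output
#' @export
forward_sample <- function(params, x) {
  stopifnot(inherits(params, "mlp_params"))
  if (length(x) != nrow(params$W1)) {
    abort(sprintf("input has length %d; network expects %d", length(x),
                  nrow(params$W1)))
  }
  if (any(!is.finite(x))) abort("non-finite input sample")
  fwd_matrix(params, matrix(x, nrow = 1L))$u
}

#' Trial decision statistic: mean squared network output
#'
#' Applies the network independently to every time sample of a trial and
#' returns `y = mean(u(t_i)^2)`, the statistic on which the left/right
#' decision is based.
#'
#' @param params An `mlp_params` object.
#' @param trial A channels-by-samples matrix (one trial), or one row of an
#'   `eeg_trials` tibble's `data` column.
#' @return Scalar `y` in (0, 1).
#' @export
forward_trial <- function(params, trial) {
  stopifnot(inherits(params, "mlp_params"))
  trial <- as.matrix(trial)
  if (ncol(trial) < 1L) abort("empty trial")
  if (any(!is.finite(trial))) abort("non-finite trial data")
  u <- fwd_matrix(params, t(trial))$u
  mean(u^2)
}

#' Decision rule on the trial statistic
#'
#' `y >= 0.5` is classified as the left-oriented percept (`"L"`, the
#' boundary included), `y < 0.5` as the right-oriented percept (`"R"`).
#'
#' @param y Numeric vector of decision statistics in `[0, 1]`.
#' @return Character vector of labels `"L"`/`"R"`.
#' @export
classify_y <- function(y) {
  if (any(!is.finite(y)) || any(y < 0 | y > 1)) {
    abort("decision statistic must lie in [0, 1]")
  }
  ifelse(y >= 0.5, "L", "R")
}

targets_from_labels <- function(labels) {
  if (!all(labels %in% c("L", "R"))) abort('labels must be "L" or "R"')
  as.numeric(labels == "L")
}

trial_matrices <- function(trials) {
  if (inherits(trials, "eeg_trials") || (is.data.frame(trials) && "data" %in% names(trials))) {
    trials$data
  } else if (is.list(trials) && !is.data.frame(trials)) {
    trials
  } else {
    abort("`trials` must be an eeg_trials tibble or a list of matrices")
  }
}

#' Mean-squared classification error
#'
#' The training criterion `mu = mean((d_k - y_k)^2)` over a set of trials,
#' with targets `d_k = 1` for left- and `d_k = 0` for right-oriented
#' percepts and `y_k` the trial statistic from [forward_trial()].
#'
#' @param params An `mlp_params` object.
#' @param trials Trials (tibble or list of matrices).
#' @param targets Numeric 0/1 targets, or labels `"L"`/`"R"`.
#' @return Scalar `mu` in `[0, 1]`.
#' @export
mlp_loss <- function(params, trials, targets) {
  mats <- trial_matrices(trials)
  if (!length(mats)) abort("empty training set")
  if (is.character(targets)) targets <- targets_from_labels(targets)
  if (length(targets) != length(mats)) {
    abort("`trials` and `targets` must have the same length")
  }
  y <- vapply(mats, function(m) forward_trial(params, m), numeric(1))
  mean((targets - y)^2)
}

#' Recognition-accuracy report
#'
#' Classifies each trial with `classify_y(forward_trial(...))` and reports
#' the recognition accuracy `rho = 100 * N_p / N` (percent of correctly
#' classified trials), overall and per class.
#'
#' @param params An `mlp_params` object.
#' @param trials Trials (tibble with `label` column, or list of matrices
#'   with `labels` supplied).
#' @param labels True labels; defaults to `trials$label`.
#' @return A one-row tibble: `n_total`, `n_correct`, `rho`, `n_L`, `n_R`,
#'   `rho_L`, `rho_R`.
#' @export
accuracy_report <- function(params, trials, labels = NULL) {
  mats <- trial_matrices(trials)
  if (is.null(labels) && is.data.frame(trials)) labels <- trials$label
  if (!length(mats)) abort("empty evaluation set")
  if (length(labels) != length(mats)) abort("labels/trials length mismatch")
  pred <- classify_y(vapply(mats, function(m) forward_trial(params, m),
                            numeric(1)))
  correct <- pred == labels
  is_l <- labels == "L"
  tibble(
    n_total = length(labels),
    n_correct = sum(correct),
    rho = 100 * sum(correct) / length(labels),
    n_L = sum(is_l),
    n_R = sum(!is_l),
    rho_L = if (any(is_l)) 100 * sum(correct[is_l]) / sum(is_l) else NA_real_,
    rho_R = if (any(!is_l)) 100 * sum(correct[!is_l]) / sum(!is_l) else NA_real_
  )
}

#' Cross-subject transfer accuracy matrix
#'
#' Evaluates each subject's trained network on every subject's held-out
#' trials. Entry `(h, r)` is the recognition accuracy of the network trained
#' on subject `h` applied to the held-out trials of subject `r`; the
#' diagonal reproduces within-subject accuracy.
#'
#' @param nets Named list of `mlp_params`, one per subject.
#' @param datasets Named list (same names) of held-out `eeg_trials` tibbles.
#' @return A tibble of class `xsub_matrix` with columns `h`, `r`, `rho`.
#' @export
cross_subject_matrix <- function(nets, datasets) {
  if (!length(nets)) abort("need at least one subject")
  if (is.null(names(nets)) || is.null(names(datasets)) ||
      !setequal(names(nets), names(datasets))) {
    abort("`nets` and `datasets` must be named lists over the same subjects")
  }
  out <- tidyr::expand_grid(h = names(nets), r = names(nets)) %>%
    mutate(rho = purrr::map2_dbl(.data$h, .data$r, function(h, r) {
      accuracy_report(nets[[h]], datasets[[r]])$rho
    }))
  class(out) <- c("xsub_matrix", class(out))
  out
}

#' Convert a cross-subject table to a matrix
#'
#' @param x An `xsub_matrix` tibble.
#' @param ... Unused.
#' @return A numeric matrix with trainers as rows and test subjects as
#'   columns.
#' @export
as.matrix.xsub_matrix <- function(x, ...) {
  wide <- tidyr::pivot_wider(as_tibble(x), names_from = "r",
                             values_from = "rho")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$h
  m
}

#' Serialize network parameters to JSON
#'
#' Writes layer sizes, row-major weight lists, thresholds and optional
#' metadata (training seed, loss) to a documented JSON layout.
#'
#' @param params An `mlp_params` object.
#' @param path Output path.
#' @param meta Optional named list of metadata.
#' @return `path` invisibly; `read_mlp()` returns the `mlp_params` with
#'   metadata in attribute `meta`.
#' @export
write_mlp <- function(params, path, meta = list()) {
  stopifnot(inherits(params, "mlp_params"))
  obj <- list(
    layer_sizes = c(nrow(params$W1), ncol(params$W1), ncol(params$W2), 1L),
    W1 = as.vector(t(params$W1)), theta1 = params$theta1,
    W2 = as.vector(t(params$W2)), theta2 = params$theta2,
    W3 = as.vector(t(params$W3)), theta3 = params$theta3,
    meta = meta
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_mlp
#' @export
read_mlp <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ls <- obj$layer_sizes
  p <- mlp_params(
    W1 = matrix(obj$W1, ls[1], ls[2], byrow = TRUE), theta1 = obj$theta1,
    W2 = matrix(obj$W2, ls[2], ls[3], byrow = TRUE), theta2 = obj$theta2,
    W3 = matrix(obj$W3, ls[3], 1, byrow = TRUE), theta3 = obj$theta3
  )
  attr(p, "meta") <- obj$meta
  p
}
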