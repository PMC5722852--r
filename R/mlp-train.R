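# Flattening order (fixed, documented): W1 column-major, theta1, W2, theta2,
# W3, theta3. The analytic Jacobian below emits columns in the same order.
flatten_params <- function(p) {
  c(as.vector(p$W1), p$theta1, as.vector(p$W2), p$theta2, as.vector(p$W3),
    p$theta3)
}

unflatten_params <- function(v, n_in, h1, h2) {
  i <- 0L
  take <- function(n) { out <- v[(i + 1L):(i + n)]; i <<- i + n; out }
  # slices must be materialized in order before the constructor call (lazy
  # argument evaluation would otherwise consume them out of sequence)
  W1 <- matrix(take(n_in * h1), n_in, h1); theta1 <- take(h1)
  W2 <- matrix(take(h1 * h2), h1, h2); theta2 <- take(h2)
  W3 <- matrix(take(h2), h2, 1); theta3 <- take(1L)
  mlp_params(W1 = W1, theta1 = theta1, W2 = W2, theta2 = theta2, W3 = W3,
             theta3 = theta3)
}

# Stack a list of samples-by-channels trial matrices into one matrix with
# trial bookkeeping, so the forward/backward passes run as a few large BLAS
# calls instead of many small ones.
stack_trials <- function(Xlist) {
  Ns <- vapply(Xlist, nrow, integer(1))
  ends <- cumsum(Ns)
  list(X = do.call(rbind, Xlist), Ns = Ns,
       grp = rep(seq_along(Xlist), Ns),
       starts = c(1L, head(ends, -1L) + 1L), ends = ends,
       K = length(Xlist))
}

# Decision statistics y_k and the analytic Jacobian dy_k/dparams over
# stacked trials. Derived by the chain rule through the time average
# y = mean(u_i^2) and the logistic layers: the per-sample seed is
# s3_i = (2/N) u_i^2 (1 - u_i), back-propagated with
# delta^{l} = (delta^{l+1} W^{l+1}') * A^l (1 - A^l), then aggregated per
# trial (rowsum for thresholds, per-trial crossprods for weights).
mlp_y_jac_stacked <- function(params, st, jacobian = TRUE) {
  act <- fwd_matrix(params, st$X)
  u <- act$u
  y <- drop(rowsum(u^2, st$grp, reorder = TRUE)) / st$Ns
  if (!jacobian) return(list(y = y, J = NULL))
  s3 <- (2 / st$Ns[st$grp]) * u^2 * (1 - u)
  S2 <- (s3 %*% t(params$W3)) * act$A2 * (1 - act$A2)  # Ntot x h2
  S1 <- (S2 %*% t(params$W2)) * act$A1 * (1 - act$A1)  # Ntot x h1
  gt3 <- -drop(rowsum(s3, st$grp))
  gW3 <- rowsum(act$A2 * s3, st$grp)
  gt2 <- -rowsum(S2, st$grp)
  gt1 <- -rowsum(S1, st$grp)
  J <- matrix(0, st$K, n_params(params))
  for (k in seq_len(st$K)) {
    r <- st$starts[k]:st$ends[k]
    gW1 <- crossprod(st$X[r, , drop = FALSE], S1[r, , drop = FALSE])
    gW2 <- crossprod(act$A1[r, , drop = FALSE], S2[r, , drop = FALSE])
    J[k, ] <- c(as.vector(gW1), gt1[k, ], as.vector(gW2), gt2[k, ],
                gW3[k, ], gt3[k])
  }
  list(y = y, J = J)
}

# compatibility wrapper over a plain list of trial matrices (used by tests)
mlp_y_and_jacobian <- function(params, Xlist, jacobian = TRUE) {
  mlp_y_jac_stacked(params, stack_trials(Xlist), jacobian)
}

# One Levenberg-Marquardt run from given initial parameters. Damping
# schedule: lambda starts at lambda_init, x10 on a rejected step, /10 on an
# accepted step; steps are accepted only if mu does not increase, so the
# accepted-mu trace is non-increasing by construction. Stops when an
# accepted step improves mu by less than `tol`, or after `max_iter`
# accepted iterations.
lm_fit <- function(params0, Xlist, d, max_iter, lambda_init, tol) {
  n_in <- nrow(params0$W1); h1 <- ncol(params0$W1); h2 <- ncol(params0$W2)
  st <- if (is.list(Xlist) && !is.null(Xlist$grp)) Xlist else stack_trials(Xlist)
  p <- flatten_params(params0)
  cur <- mlp_y_jac_stacked(params0, st, jacobian = FALSE)
  mu <- mean((d - cur$y)^2)
  trace <- mu
  lambda <- lambda_init
  iter <- 0L
  converged <- FALSE
  diverged <- FALSE
  while (iter < max_iter) {
    yj <- mlp_y_jac_stacked(unflatten_params(p, n_in, h1, h2), st)
    r <- d - yj$y
    J <- yj$J
    JtJ <- crossprod(J)
    g <- crossprod(J, r)
    accepted <- FALSE
    for (inner in 1:40) {
      A <- JtJ + lambda * diag(diag(JtJ) + 1e-12, nrow(JtJ))
      # A is symmetric positive definite by construction: Cholesky solve
      delta <- tryCatch({
        R <- chol(A)
        backsolve(R, forwardsolve(t(R), g))
      }, error = function(e) NULL)
      if (is.null(delta) || any(!is.finite(delta))) {
        lambda <- lambda * 10
        next
      }
      p_new <- p + drop(delta)
      y_new <- mlp_y_jac_stacked(unflatten_params(p_new, n_in, h1, h2),
                                 st, jacobian = FALSE)$y
      mu_new <- mean((d - y_new)^2)
      if (!is.finite(mu_new)) {
        diverged <- TRUE
        lambda <- lambda * 10
        next
      }
      if (mu_new <= mu) {
        dmu <- mu - mu_new
        p <- p_new
        mu <- mu_new
        lambda <- max(lambda / 10, 1e-12)
        trace <- c(trace, mu)
        accepted <- TRUE
        iter <- iter + 1L
        if (dmu < tol) converged <- TRUE
        break
      }
      lambda <- lambda * 10
    }
    if (!accepted || converged || lambda > 1e14) break
  }
  list(params = unflatten_params(p, n_in, h1, h2), mu = mu,
       iterations = iter, converged = converged, diverged = diverged,
       mu_trace = trace)
}

#' Train the perceptron by multi-restart Levenberg-Marquardt
#'
#' Minimizes the mean-squared classification error
#' `mu = mean((d_k - y_k)^2)` over all weights and thresholds, where `y_k`
#' is the mean-squared-output trial statistic and `d_k = 1` (left) or `0`
#' (right). Each restart draws an independent uniform initialization from a
#' per-restart seed and runs damped Gauss-Newton steps with the analytic
#' Jacobian of `y_k`; a step is accepted only if it does not increase `mu`,
#' so each restart's accepted-loss trace is non-increasing. The restart with
#' the smallest final `mu` is flagged as best (ties broken by the lowest
#' restart index).
#'
#' @param trials Training trials (`eeg_trials` tibble or list of matrices).
#' @param labels Trial labels `"L"`/`"R"`; defaults to `trials$label`. Both
#'   classes must be present.
#' @param h1,h2 Hidden-layer sizes.
#' @param n_restarts Number of random restarts (the reference protocol uses
#'   up to 1000; desk-scale defaults are smaller).
#' @param max_iter Maximum accepted LM iterations per restart (0 returns the
#'   initial parameters unchanged).
#' @param lambda_init Initial damping.
#' @param tol Stop when an accepted step improves `mu` by less than this.
#' @param seed Top-level training seed; restart `r` uses
#'   `seed_combine(seed, r)`.
#' @param init_range Half-width of the uniform initialization.
#' @return An object of class `mlp_training`: a list with `restarts` (a
#'   tibble with list-columns `params` and `mu_trace`) and `best_index`.
#' @export
train_mlp <- function(trials, labels = NULL, h1 = 19L, h2 = 5L,
                      n_restarts = 50L, max_iter = 100L, lambda_init = 1e-3,
                      tol = 1e-9, seed = 1L, init_range = 0.5) {
  mats <- trial_matrices(trials)
  if (is.null(labels) && is.data.frame(trials)) labels <- trials$label
  d <- targets_from_labels(labels)
  if (length(d) != length(mats)) abort("labels/trials length mismatch")
  if (length(unique(d)) < 2L) {
    abort("training set must contain both classes",
          class = "neckereeg_validation_error")
  }
  check_scalar(n_restarts, "n_restarts", lower = 1)
  check_scalar(max_iter, "max_iter", lower = 0)
  n_in <- nrow(mats[[1]])
  Xlist <- stack_trials(lapply(mats, t))

  runs <- lapply(seq_len(n_restarts), function(rix) {
    rseed <- seed_combine(seed, rix)
    params0 <- init_mlp(n_in, h1, h2, seed = rseed, init_range = init_range)
    fit <- lm_fit(params0, Xlist, d, max_iter, lambda_init, tol)
    fit$seed <- rseed
    fit
  })
  restarts <- tibble(
    restart = seq_len(n_restarts),
    params = lapply(runs, `[[`, "params"),
    mu = vapply(runs, `[[`, numeric(1), "mu"),
    iterations = vapply(runs, `[[`, integer(1), "iterations"),
    converged = vapply(runs, `[[`, logical(1), "converged"),
    diverged = vapply(runs, `[[`, logical(1), "diverged"),
    seed = vapply(runs, `[[`, integer(1), "seed"),
    mu_trace = lapply(runs, `[[`, "mu_trace")
  )
  structure(
    list(restarts = restarts,
         best_index = which.min(restarts$mu)[1],
         h1 = h1, h2 = h2, seed = seed, n_trials = length(mats)),
    class = "mlp_training")
}

#' @export
print.mlp_training <- function(x, ...) {
  cat(sprintf(
    "<mlp_training> %d restarts on %d trials (19-%d-%d-1); best mu = %.4g (restart %d)\n",
    nrow(x$restarts), x$n_trials, x$h1, x$h2,
    x$restarts$mu[x$best_index], x$best_index))
  invisible(x)
}

#' Select the best restart's parameters
#'
#' Returns the parameters of the restart with the smallest final training
#' loss `mu` (lowest restart index on ties).
#'
#' @param fit An `mlp_training` object.
#' @return The best `mlp_params`.
#' @export
select_best <- function(fit) {
  stopifnot(inherits(fit, "mlp_training"))
  if (!nrow(fit$restarts)) abort("training result has no restarts")
  fit$restarts$params[[fit$best_index]]
}

#' Balanced train/test split
#'
#' Samples `n_per_class` trials of each class (seeded, without replacement)
#' for training, mirroring the reference protocol of 70 training trials (35
#' per percept); the remainder is held out.
#'
#' @param trials An `eeg_trials` tibble with a `label` column.
#' @param n_per_class Training trials per class (default 35).
#' @param seed Integer seed for the draw.
#' @return A list with `train` and `test` trial tibbles.
#' @export
train_test_split <- function(trials, n_per_class = 35L, seed = 1L) {
  stopifnot(is.data.frame(trials), "label" %in% names(trials))
  idx_l <- which(trials$label == "L")
  idx_r <- which(trials$label == "R")
  if (length(idx_l) < n_per_class || length(idx_r) < n_per_class) {
    abort(sprintf(
      "need >= %d trials per class for the training split (have L=%d, R=%d)",
      n_per_class, length(idx_l), length(idx_r)),
      class = "neckereeg_validation_error")
  }
  tr <- local_seed(seed, c(sample(idx_l, n_per_class),
                           sample(idx_r, n_per_class)))
  keep_attrs <- function(sub) {
    attr(sub, "fs") <- attr(trials, "fs")
    attr(sub, "duration") <- attr(trials, "duration")
    class(sub) <- class(trials)
    sub
  }
  list(train = keep_attrs(trials[sort(tr), , drop = FALSE]),
       test = keep_attrs(trials[-tr, , drop = FALSE]))
}

#' Sweep network topology and trial duration
#'
#' Re-runs split/train/evaluate over a grid of hidden-layer sizes and trial
#' durations (re-epoching the recording for each duration) and reports the
#' held-out recognition accuracy per grid point and subject. Grids of
#' length one reproduce a single direct run with the same derived seeds.
#'
#' @param sessions List (one element per subject) of lists with components
#'   `recording` and `events`.
#' @param h1_grid,h2_grid,t_grid Numeric grids for the two hidden-layer
#'   sizes and the trial duration in seconds.
#' @param n_restarts,max_iter Reduced training budget per grid point.
#' @param n_per_class Training trials per class.
#' @param seed Top-level seed; the seed for grid point `(h1, h2, T)` and
#'   subject `s` is `seed_combine(seed, h1, h2, round(1000 T), s)`.
#' @return A tibble with columns `h1`, `h2`, `duration`, `subject`, `rho`.
#' @export
sweep_topology_duration <- function(sessions, h1_grid = 19L, h2_grid = 5L,
                                    t_grid = 1, n_restarts = 5L,
                                    max_iter = 40L, n_per_class = 35L,
                                    seed = 1L) {
  if (!length(h1_grid) || !length(h2_grid) || !length(t_grid)) {
    abort("all grids must be non-empty")
  }
  grid <- tidyr::expand_grid(h1 = h1_grid, h2 = h2_grid, duration = t_grid)
  out <- purrr::pmap_dfr(grid, function(h1, h2, duration) {
    purrr::imap_dfr(sessions, function(ses, six) {
      s <- seed_combine(seed, h1, h2, round(1000 * duration), six)
      trials <- scale_trials(extract_trials(ses$recording, ses$events,
                                            duration = duration))
      split <- train_test_split(trials, n_per_class, seed = s)
      fit <- train_mlp(split$train, h1 = h1, h2 = h2,
                       n_restarts = n_restarts, max_iter = max_iter,
                       seed = s)
      tibble(h1 = h1, h2 = h2, duration = duration,
             subject = as.integer(six),
             rho = accuracy_report(select_best(fit), split$test)$rho)
    })
  })
  out
}
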