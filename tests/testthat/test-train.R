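# Separable toy problem: the two channels carry opposite per-sample mean
# offsets by class, so the loss can be driven towards zero.
make_separable_trials <- function(n = 16, n_samp = 40, seed = 3,
                                  strength = 1) {
  withr::with_seed(seed, {
    labels <- rep(c("L", "R"), length.out = n)
    data <- lapply(seq_len(n), function(i) {
      s <- if (labels[i] == "L") 0.4 * strength else -0.4 * strength
      m <- rbind(s + 0.1 * rnorm(n_samp),
                 -s + 0.1 * rnorm(n_samp))
      rownames(m) <- c("ch1", "ch2")
      m
    })
    out <- tibble::tibble(trial_id = seq_len(n), subject_id = 1L,
                          label = labels, g = 0.5, onset_sample = 0L,
                          data = data)
    attr(out, "fs") <- 40
    class(out) <- c("eeg_trials", class(out))
    out
  })
}

test_that("the analytic Jacobian matches central finite differences", {
  mats <- withr::with_seed(42, lapply(1:5, function(i)
    matrix(runif(30, -1, 1), 3, 10)))
  p <- init_mlp(3, 4, 3, seed = 7, init_range = 0.8)
  yj <- neckereeg:::mlp_y_and_jacobian(p, lapply(mats, t))
  fl <- neckereeg:::flatten_params(p)
  eps <- 1e-6
  num <- vapply(seq_along(fl), function(j) {
    vp <- fl; vp[j] <- vp[j] + eps
    vm <- fl; vm[j] <- vm[j] - eps
    (vapply(mats, function(m)
      forward_trial(neckereeg:::unflatten_params(vp, 3, 4, 3), m), numeric(1)) -
     vapply(mats, function(m)
       forward_trial(neckereeg:::unflatten_params(vm, 3, 4, 3), m), numeric(1))) /
      (2 * eps)
  }, numeric(5))
  expect_lt(max(abs(yj$J - num)), 1e-7)
})

test_that("a zero iteration budget returns the initial parameters", {
  tr <- make_separable_trials()
  fit <- train_mlp(tr, n_restarts = 3, max_iter = 0, seed = 5, h1 = 3, h2 = 2)
  expect_false(any(fit$restarts$converged))
  expect_true(all(fit$restarts$iterations == 0L))
  init1 <- init_mlp(2, 3, 2, seed = fit$restarts$seed[1])
  expect_equal(fit$restarts$params[[1]], init1, tolerance = 1e-15)
  expect_equal(fit$restarts$mu[1], mlp_loss(init1, tr, tr$label),
               tolerance = 1e-12)
})

test_that("accepted-step loss traces never increase", {
  tr <- make_separable_trials()
  fit <- train_mlp(tr, n_restarts = 4, max_iter = 30, seed = 6, h1 = 4, h2 = 2)
  for (trace in fit$restarts$mu_trace) {
    expect_true(all(diff(trace) <= 1e-12))
  }
  expect_true(all(fit$restarts$mu <= fit$restarts$mu_trace[[1]][1] + 1e-12 |
                    fit$restarts$restart != 1))
})

test_that("training requires both classes", {
  tr <- make_separable_trials()
  tr$label <- rep("L", nrow(tr))
  expect_error(train_mlp(tr, n_restarts = 1, max_iter = 5),
               class = "neckereeg_validation_error")
})

test_that("LM converges on a separable problem and beats its initialization", {
  tr <- make_separable_trials(n = 24)
  fit <- train_mlp(tr, n_restarts = 4, max_iter = 60, seed = 8, h1 = 6,
                   h2 = 3)
  g <- glance(fit)
  expect_lt(g$best_mu, 0.05)
  expect_equal(accuracy_report(select_best(fit), tr)$rho, 100)
  expect_identical(fit$best_index, which.min(fit$restarts$mu)[1])
})

test_that("an independent LM implementation reaches a comparable optimum", {
  skip_if_not_installed("minpack.lm")
  # lmdif needs at least as many residuals as parameters: 30 trials, 11 params
  tr <- make_separable_trials(n = 30, n_samp = 25, seed = 13)
  d <- as.numeric(tr$label == "L")
  Xlist <- lapply(tr$data, t)
  p0 <- init_mlp(2, 2, 1, seed = 91)
  ours <- neckereeg:::lm_fit(p0, Xlist, d, max_iter = 80,
                             lambda_init = 1e-3, tol = 1e-9)
  resid_fn <- function(v) {
    pp <- neckereeg:::unflatten_params(v, 2, 2, 1)
    d - vapply(tr$data, function(m) forward_trial(pp, m), numeric(1))
  }
  ref <- minpack.lm::nls.lm(par = neckereeg:::flatten_params(p0),
                            fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, nprint = 0))
  mu_ref <- mean(resid_fn(ref$par)^2)
  expect_lt(ours$mu, mu_ref + 0.02)
  expect_lt(ours$mu, mlp_loss(p0, tr, d)) # improved on the start
})

test_that("held-out accuracy is monotone in the class effect size", {
  rhos <- vapply(c(0, 4, 8), function(amp) {
    p <- subject_profile(21, 1, class_effect_amp = amp)
    ses <- generate_session(p, 160)
    trials <- scale_trials(extract_trials(ses$recording, ses$events))
    sp <- train_test_split(trials, 35, seed = 2)
    fit <- train_mlp(sp$train, n_restarts = 8, max_iter = 60, seed = 4)
    accuracy_report(select_best(fit), sp$test)$rho
  }, numeric(1))
  expect_gte(rhos[2], rhos[1] - 2)
  expect_gte(rhos[3], rhos[2] - 2)
})

test_that("balanced splits hold out the remainder and validate sizes", {
  tr <- make_separable_trials(n = 20)
  sp <- train_test_split(tr, n_per_class = 6, seed = 1)
  expect_identical(nrow(sp$train), 12L)
  expect_identical(nrow(sp$test), 8L)
  expect_equal(sum(sp$train$label == "L"), 6)
  expect_length(intersect(sp$train$trial_id, sp$test$trial_id), 0)
  expect_error(train_test_split(tr, n_per_class = 11),
               class = "neckereeg_validation_error")
})

test_that("a single sweep grid point reproduces a direct run", {
  p <- subject_profile(31, 1, class_effect_amp = 8)
  ses <- generate_session(p, 60)
  res <- sweep_topology_duration(list(list(recording = ses$recording,
                                           events = ses$events)),
                                 h1_grid = 6, h2_grid = 3, t_grid = 0.8,
                                 n_restarts = 2, max_iter = 10,
                                 n_per_class = 15, seed = 17)
  s <- seed_combine(17, 6, 3, 800, 1)
  trials <- scale_trials(extract_trials(ses$recording, ses$events,
                                        duration = 0.8))
  sp <- train_test_split(trials, 15, seed = s)
  fit <- train_mlp(sp$train, h1 = 6, h2 = 3, n_restarts = 2, max_iter = 10,
                   seed = s)
  expect_equal(res$rho, accuracy_report(select_best(fit), sp$test)$rho)
  expect_identical(nrow(res), 1L)
})

test_that("longer trials that cover the class signature classify better", {
  p <- subject_profile(41, 1, class_effect_amp = 8)
  ses <- generate_session(p, 120)
  res <- sweep_topology_duration(list(list(recording = ses$recording,
                                           events = ses$events)),
                                 h1_grid = 19, h2_grid = 5,
                                 t_grid = c(0.12, 1.0),
                                 n_restarts = 3, max_iter = 40,
                                 n_per_class = 30, seed = 23)
  rho_short <- res$rho[res$duration == 0.12]
  rho_long <- res$rho[res$duration == 1.0]
  expect_gt(rho_long, rho_short)
})
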