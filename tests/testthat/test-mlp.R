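test_that("zero-parameter network sits at the logistic fixed point", {
  net <- zero_net()
  withr::with_seed(1, x <- runif(19, -1, 1))
  expect_identical(forward_sample(net, x), 0.5)
  tr <- matrix(runif(19 * 50, -1, 1), 19, 50)
  expect_identical(forward_trial(net, tr), 0.25)
})

test_that("output-threshold saturation follows the logistic closed form", {
  net <- zero_net()
  net$theta3 <- 20
  withr::with_seed(2, x <- runif(19, -1, 1))
  expect_equal(forward_sample(net, x), 1 / (1 + exp(20)), tolerance = 1e-15)
  # large positive output weights drive y towards 1 from below
  net2 <- zero_net()
  net2$W3[] <- 4
  net2$theta3 <- -4
  tr <- matrix(0, 19, 10)
  y <- forward_trial(net2, tr) # z3 = 4 * 5 * 0.5 + 4 = 14
  expect_lt(y, 1)
  expect_gt(y, 1 - 1e-5)
})

test_that("forward pass matches the per-neuron brute-force oracle", {
  for (k in 1:20) {
    p <- init_mlp(seed = 100 + k, init_range = 2)
    withr::with_seed(200 + k, x <- runif(19, -1, 1))
    expect_equal(forward_sample(p, x), oracle_forward(p, x),
                 tolerance = 1e-12)
  }
  # trial statistic equals the mean of squared oracle outputs
  p <- init_mlp(seed = 31, init_range = 1.5)
  withr::with_seed(32, tr <- matrix(runif(19 * 40, -1, 1), 19, 40))
  expect_equal(forward_trial(p, tr), oracle_forward_trial(p, tr),
               tolerance = 1e-12)
  expect_error(forward_sample(p, rep(NA_real_, 19)), regexp = "finite")
  expect_error(forward_sample(p, runif(5)), regexp = "length")
  expect_error(forward_trial(p, matrix(numeric(0), 19, 0)), regexp = "empty")
})

test_that("the decision rule assigns the boundary to the left percept", {
  expect_identical(classify_y(0.5), "L")
  expect_identical(classify_y(0.9), "L")
  expect_identical(classify_y(0.1), "R")
  expect_identical(classify_y(c(0.49, 0.51)), c("R", "L"))
  expect_error(classify_y(1.2), regexp = "\\[0, 1\\]")
  expect_error(classify_y(-0.1), regexp = "\\[0, 1\\]")
})

test_that("the training criterion matches direct summation", {
  net <- zero_net(4, 4, 2)
  tr <- make_random_trials(2, n_ch = 4)
  # zero net: y = 0.25 for both; d = (1, 0) -> mu = (0.75^2 + 0.25^2)/2
  expect_equal(mlp_loss(net, tr, c(1, 0)), (0.5625 + 0.0625) / 2,
               tolerance = 1e-12)
  # random case against a naive loop
  p <- init_mlp(4, 4, 2, seed = 77, init_range = 1)
  tr2 <- make_random_trials(7, n_ch = 4, seed = 5)
  d <- c(1, 0, 1, 0, 1, 0, 1)
  y <- vapply(tr2$data, function(m) oracle_forward_trial(p, m), numeric(1))
  expect_equal(mlp_loss(p, tr2, d), mean((d - y)^2), tolerance = 1e-12)
  expect_error(mlp_loss(p, tr2[0, ], numeric(0)), regexp = "empty")
})

test_that("perfect predictions give zero loss", {
  # engineer y ~= d by saturating the output unit
  net <- zero_net(4, 4, 2)
  net$theta3 <- 60
  tr <- make_random_trials(3, n_ch = 4)
  expect_equal(mlp_loss(net, tr, c(0, 0, 0)), 0, tolerance = 1e-10)
})

test_that("restart selection minimizes loss with first-index tie-breaks", {
  fake <- structure(list(
    restarts = tibble::tibble(
      restart = 1:3,
      params = list(zero_net(2, 2, 2), init_mlp(2, 2, 2, seed = 1),
                    init_mlp(2, 2, 2, seed = 2)),
      mu = c(0.3, 0.1, 0.2)),
    best_index = which.min(c(0.3, 0.1, 0.2))[1]),
    class = "mlp_training")
  expect_identical(select_best(fake), fake$restarts$params[[2]])
  fake$restarts$mu <- c(0.1, 0.3, 0.1)
  fake$best_index <- which.min(fake$restarts$mu)[1]
  expect_identical(select_best(fake), fake$restarts$params[[1]])
})

test_that("accuracy reports count correct classifications per class", {
  tr <- make_random_trials(10, n_ch = 4, seed = 9)
  p <- init_mlp(4, 4, 2, seed = 3, init_range = 1)
  y <- vapply(tr$data, function(m) forward_trial(p, m), numeric(1))
  pred <- ifelse(y >= 0.5, "L", "R")
  rep_ <- accuracy_report(p, tr)
  expect_equal(rep_$rho, 100 * mean(pred == tr$label))
  expect_identical(rep_$n_total, 10L)
  expect_equal(rep_$n_L + rep_$n_R, 10L)
  # hand confusion-count oracle for the per-class rates
  expect_equal(rep_$rho_L,
               100 * mean(pred[tr$label == "L"] == "L"))
  expect_equal(rep_$rho_R,
               100 * mean(pred[tr$label == "R"] == "R"))
  # all-correct degenerate case via matching labels
  expect_equal(accuracy_report(p, tr, labels = pred)$rho, 100)
})

test_that("cross-subject matrix is consistent with direct evaluation", {
  tr1 <- make_random_trials(8, n_ch = 4, seed = 21)
  tr2 <- make_random_trials(8, n_ch = 4, seed = 22)
  nets <- list(`1` = init_mlp(4, 3, 2, seed = 1, init_range = 1),
               `2` = init_mlp(4, 3, 2, seed = 2, init_range = 1))
  ds <- list(`1` = tr1, `2` = tr2)
  m <- cross_subject_matrix(nets, ds)
  expect_equal(m$rho[m$h == "1" & m$r == "1"],
               accuracy_report(nets[["1"]], tr1)$rho)
  expect_equal(m$rho[m$h == "2" & m$r == "1"],
               accuracy_report(nets[["2"]], tr1)$rho)
  # identical datasets: off-diagonal equals the corresponding diagonal
  m2 <- cross_subject_matrix(nets, list(`1` = tr1, `2` = tr1))
  expect_equal(m2$rho[m2$h == "1" & m2$r == "2"],
               m2$rho[m2$h == "1" & m2$r == "1"])
  mm <- as.matrix(m)
  expect_identical(dim(mm), c(2L, 2L))
  expect_error(cross_subject_matrix(nets, list(a = tr1, b = tr2)),
               regexp = "same subjects")
})

test_that("parameters round trip through the JSON layout", {
  p <- init_mlp(seed = 5)
  path <- withr::local_tempfile(fileext = ".json")
  write_mlp(p, path, meta = list(mu = 0.1, seed = 5))
  p2 <- read_mlp(path)
  expect_equal(p2$W1, p$W1, tolerance = 1e-15)
  expect_equal(p2$theta2, p$theta2, tolerance = 1e-15)
  expect_equal(p2$W3, p$W3, tolerance = 1e-15)
  expect_equal(attr(p2, "meta")$mu, 0.1)
  withr::with_seed(3, x <- runif(19, -1, 1))
  expect_equal(forward_sample(p2, x), forward_sample(p, x), tolerance = 1e-15)
})
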