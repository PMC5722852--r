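fs <- 250

test_that("reference normalization matches closed forms and quadrature", {
  # constant 2 on a 1-s window has norm 2 under the rectangle rule
  out <- normalize_reference(rep(2, fs), fs)
  expect_equal(out, rep(1, fs), tolerance = 1e-12)
  # already unit-norm input is returned unchanged
  expect_equal(normalize_reference(out, fs), out, tolerance = 1e-12)
  # 10 Hz sinusoid over 1 s: norm ~ sqrt(1/2) up to discretization
  t <- (0:(fs - 1)) / fs
  s <- sin(2 * pi * 10 * t)
  quad <- sqrt(sum(s^2) / fs) # independent rectangle quadrature
  expect_equal(quad, sqrt(1 / 2), tolerance = 1e-2)
  expect_equal(normalize_reference(s, fs), s / quad, tolerance = 1e-12)
  expect_error(normalize_reference(rep(0, fs), fs),
               class = "neckereeg_degenerate_reference")
})

test_that("orthogonalization is exact in the discrete inner product", {
  withr::with_seed(10, {
    n <- 500
    x <- rnorm(n); c_v <- rnorm(n); c_h <- rnorm(n)
    cv0 <- normalize_reference(c_v, fs)
    ch0 <- normalize_reference(c_h, fs)
    xt <- remove_eog(x, c_v, c_h, fs)
    xp <- x - cv0 * sum(cv0 * x) / fs
    expect_lt(abs(sum(xt * ch0) / fs), 1e-10)
    expect_lt(abs(sum(xp * cv0) / fs), 1e-10)
  })
})

test_that("self-projection removes everything; orthogonal input passes through", {
  t <- (0:(fs - 1)) / fs
  c_v <- sin(2 * pi * 5 * t)
  c_h <- cos(2 * pi * 5 * t) # exactly orthogonal on the full-period window
  cv0 <- normalize_reference(c_v, fs)
  expect_lt(max(abs(remove_eog(cv0, c_v, c_h, fs))), 1e-10)
  x <- sin(2 * pi * 20 * t) # orthogonal to both references
  expect_equal(remove_eog(x, c_v, c_h, fs), x, tolerance = 1e-10)
  # with orthogonal references the result is orthogonal to both
  withr::with_seed(2, x2 <- rnorm(fs))
  xt <- remove_eog(x2, c_v, c_h, fs)
  expect_lt(abs(sum(xt * cv0) / fs), 1e-10)
})

test_that("orthogonalization is linear and idempotent", {
  withr::with_seed(11, {
    n <- 400
    x <- rnorm(n); y <- rnorm(n); c_v <- rnorm(n); c_h <- rnorm(n)
    f <- function(z) remove_eog(z, c_v, c_h, fs)
    expect_equal(f(2 * x + 3 * y), 2 * f(x) + 3 * f(y), tolerance = 1e-10)
    # with correlated references the sequential projections re-applied leave
    # only a second-order residual ~ <c_v0, c_h0>^2
    expect_equal(f(f(x)), f(x), tolerance = 1e-3)
  })
  # with orthogonal references the operator is an exact projection
  t <- (0:(fs - 1)) / fs
  c_v <- sin(2 * pi * 5 * t); c_h <- cos(2 * pi * 5 * t)
  withr::with_seed(12, x <- rnorm(fs))
  g <- function(z) remove_eog(z, c_v, c_h, fs)
  expect_equal(g(g(x)), g(x), tolerance = 1e-10)
  expect_error(remove_eog(rnorm(10), rnorm(9), rnorm(10), fs),
               regexp = "same length")
})

test_that("cleaning a contaminated synthetic session decorrelates Fp1 from EOG", {
  p <- subject_profile(8, 1)
  ses <- generate_session(p, 60)
  dirty <- inject_eog(ses$recording, p)
  clean <- remove_eog(dirty)
  expect_lt(abs(cor(clean$signal["Fp1", ], dirty$eog_v)), 0.1)
  expect_lt(abs(cor(clean$signal["Fp1", ], dirty$eog_h)), 0.1)
})

test_that("band-pass and notch behave as designed on pure tones", {
  p <- subject_profile(1, 1)
  rec <- generate_session(p, 0)$recording
  n <- ncol(rec$signal)
  t <- (0:(n - 1)) / fs
  mid <- seq(as.integer(n * 0.2), as.integer(n * 0.8)) # avoid edge transients
  rms <- function(v) sqrt(mean(v^2))

  rec$signal[1, ] <- sin(2 * pi * 50 * t)
  rec$signal[2, ] <- sin(2 * pi * 10 * t)
  rec$signal[3, ] <- 0
  out <- bandlimit(rec)
  expect_lt(rms(out$signal[1, mid]) / rms(rec$signal[1, mid]), 0.05)
  expect_equal(rms(out$signal[2, mid]) / rms(rec$signal[2, mid]), 1,
               tolerance = 0.05)
  expect_equal(out$signal[3, ], rep(0, n), tolerance = 1e-9)
  expect_error(bandlimit(rec, hp = 120, lp = 100),
               class = "neckereeg_validation_error")
  expect_error(bandlimit(rec, notch = 130),
               class = "neckereeg_validation_error")
})

test_that("trial extraction is aligned, sized, and bit-exact", {
  p <- subject_profile(12, 1)
  ses <- generate_session(p, 10)
  trials <- extract_trials(ses$recording, ses$events, duration = 1)
  expect_true(all(vapply(trials$data, ncol, integer(1)) == 250L))
  expect_identical(nrow(trials), nrow(ses$events))
  k <- 4
  s0 <- ses$events$onset_sample[k]
  expect_identical(trials$data[[k]],
                   ses$recording$signal[, (s0 + 1):(s0 + 250)])
  expect_identical(trials$label[k], ses$events$label[k])

  empty <- extract_trials(ses$recording, ses$events[0, ], duration = 1)
  expect_identical(nrow(empty), 0L)

  late <- ses$events[1, ]
  late$onset_sample <- ncol(ses$recording$signal) - 100L
  expect_message(skipped <- extract_trials(ses$recording, late, duration = 1),
                 regexp = "skipped 1")
  expect_identical(nrow(skipped), 0L)
  expect_identical(attr(skipped, "n_skipped"), 1L)
})

test_that("pooled min-max scaling maps ranges to [-1, 1] and is idempotent", {
  tr <- make_random_trials(6, n_ch = 3, n_samp = 30)
  # impose a known pooled range on channel 1: min -4, max 2
  tr$data[[1]][1, 1] <- -4
  tr$data[[2]][1, 5] <- 2
  tr$data <- lapply(tr$data, function(m) { m[1, ] <- pmin(pmax(m[1, ], -4), 2); m })
  tr$data[[3]][2, ] <- 7 # constant channel
  tr$data <- lapply(tr$data, function(m) { m[2, ] <- 7; m })
  sc <- scale_trials(tr)
  pooled <- do.call(cbind, sc$data)
  expect_equal(min(pooled[1, ]), -1, tolerance = 1e-12)
  expect_equal(max(pooled[1, ]), 1, tolerance = 1e-12)
  expect_true(all(pooled[2, ] == 0))
  sc2 <- scale_trials(sc)
  expect_equal(sc2$data, sc$data, tolerance = 1e-12)
  expect_error(scale_trials(tr[0, ]), regexp = "empty")
  # per-trial mode scales each trial independently
  pt <- scale_trials(tr, mode = "per_trial")
  expect_equal(range(pt$data[[4]][1, ]), c(-1, 1), tolerance = 1e-12)
})

test_that("epoch extraction spans the peristimulus window", {
  p <- subject_profile(3, 2)
  ses <- generate_session(p, 8)
  ep <- extract_epochs(ses$recording, ses$events, pre = 1, post = 2)
  expect_true(all(vapply(ep$data, ncol, integer(1)) == 750L))
  s0 <- ses$events$onset_sample[2]
  expect_identical(ep$data[[2]],
                   ses$recording$signal[, (s0 - 250 + 1):(s0 + 500)])
})
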