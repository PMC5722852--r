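# Independent brute-force oracles used to pin down the vectorized
# implementations. These are deliberately written as plain per-neuron /
# per-point loops and share no code with the package internals.

# forward pass, one neuron at a time
oracle_forward <- function(params, x) {
  sig <- function(eta) 1 / (1 + exp(-eta))
  h1 <- ncol(params$W1); h2 <- ncol(params$W2)
  u1 <- numeric(h1)
  for (i in seq_len(h1)) {
    acc <- 0
    for (p in seq_len(nrow(params$W1))) acc <- acc + params$W1[p, i] * x[p]
    u1[i] <- sig(acc - params$theta1[i])
  }
  u2 <- numeric(h2)
  for (i in seq_len(h2)) {
    acc <- 0
    for (p in seq_len(h1)) acc <- acc + params$W2[p, i] * u1[p]
    u2[i] <- sig(acc - params$theta2[i])
  }
  acc <- 0
  for (p in seq_len(h2)) acc <- acc + params$W3[p, 1] * u2[p]
  sig(acc - params$theta3)
}

# trial statistic via the per-sample oracle
oracle_forward_trial <- function(params, trial) {
  u <- vapply(seq_len(ncol(trial)), function(i)
    oracle_forward(params, trial[, i]), numeric(1))
  mean(u^2)
}

# Morlet coefficient at one (frequency, sample) point by direct quadrature
# over the truncated support
oracle_cwt_point <- function(x, fs, f, t_idx, omega0 = 2 * pi) {
  half <- floor(4 / f * fs)
  acc <- 0 + 0i
  for (k in -half:half) {
    j <- t_idx + k
    if (j >= 1 && j <= length(x)) {
      tau <- k / fs
      acc <- acc + x[j] * exp(-1i * omega0 * f * tau) *
        exp(-(f * tau)^2 / 2)
    }
  }
  f * pi^(-1 / 4) * acc / fs
}

# 2-D trapezoid integral by explicit cell loop
oracle_trapz2d <- function(f_axis, t_axis, z) {
  acc <- 0
  for (i in seq_len(length(f_axis) - 1)) {
    for (j in seq_len(length(t_axis) - 1)) {
      cell <- (z[i, j] + z[i + 1, j] + z[i, j + 1] + z[i + 1, j + 1]) / 4
      acc <- acc + cell * (f_axis[i + 1] - f_axis[i]) *
        (t_axis[j + 1] - t_axis[j])
    }
  }
  acc
}

# small random trial set as an eeg_trials-shaped tibble
make_random_trials <- function(n, n_ch = 4, n_samp = 20, fs = 20,
                               seed = 1) {
  withr::with_seed(seed, {
    labels <- rep(c("L", "R"), length.out = n)
    data <- lapply(seq_len(n), function(i) {
      m <- matrix(runif(n_ch * n_samp, -1, 1), n_ch, n_samp)
      rownames(m) <- paste0("ch", seq_len(n_ch))
      m
    })
    out <- tibble::tibble(trial_id = seq_len(n), subject_id = 1L,
                          label = labels, g = 0.5,
                          onset_sample = 0L, data = data)
    attr(out, "fs") <- fs
    attr(out, "duration") <- n_samp / fs
    class(out) <- c("eeg_trials", class(out))
    out
  })
}

# zero-parameter network of the reference topology
zero_net <- function(n_in = 19, h1 = 19, h2 = 5) {
  mlp_params(matrix(0, n_in, h1), rep(0, h1),
             matrix(0, h1, h2), rep(0, h2),
             matrix(0, h2, 1), 0)
}

# constant-energy time-frequency map on an exactly [0, 3] s x [1, 35] Hz grid
const_tfmap <- function(value, group = "L") {
  freq <- seq(1, 35, by = 0.25)
  time <- seq(0, 3, length.out = 751)
  structure(list(energy = matrix(value, length(freq), length(time)),
                 freq = freq, time = time, coi = NULL,
                 n_averaged = 1L, group = group),
            class = "eeg_tfmap")
}
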