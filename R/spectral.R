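# Morlet kernel at analysis frequency f (Hz), sampled on tau = k/fs for
# |tau| <= 4/f (the truncation limits of the transform's integral), with
# center frequency omega0 = 2*pi so that analysis frequency equals signal
# frequency in Hz. The sqrt(f) prefactors of the transform and of the
# mother wavelet combine to a single factor f; the Gaussian envelope decays
# as exp(-(f tau)^2 / 2). The rectangle-rule dt is folded into the kernel.
morlet_kernel <- function(f, fs, omega0 = 2 * pi) {
  half <- as.integer(floor(4 / f * fs))
  tau <- (-half:half) / fs
  list(
    half = half,
    k = f * pi^(-1 / 4) * exp(-1i * omega0 * f * tau) *
      exp(-(f * tau)^2 / 2) / fs
  )
}

# centered complex correlation via FFT: out[t] = sum_k x[t+k-h-1] kern[k]
conv_center <- function(x, kern, half) {
  n <- length(x)
  L <- length(kern)
  # pad to a 2-3-5-smooth length to keep the mixed-radix FFT fast
  nf <- stats::nextn(n + L - 1L, c(2, 3, 5))
  full <- fft(fft(c(x, rep(0, nf - n))) *
                fft(c(rev(kern), rep(0, nf - L))), inverse = TRUE) / nf
  full[(half + 1L):(half + n)]
}

#' Continuous Morlet wavelet transform
#'
#' Computes complex wavelet coefficients `W(f, t)` of a single-channel
#' signal on a frequency grid, by discrete convolution with the truncated
#' Morlet kernel (support `|t' - t| <= 4/f`), zero-padded at the edges.
#' Samples closer than `4/f` to either edge are inside the cone of
#' influence and flagged.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate, Hz.
#' @param freqs Analysis frequencies in Hz, strictly inside `(0, fs/2)`
#'   (default 1-35 Hz in 0.25 Hz steps).
#' @param omega0 Center frequency parameter (default `2*pi`, making the
#'   analysis frequency equal the oscillation frequency in Hz).
#' @return An object of class `eeg_cwt`: list with `coef`
#'   (frequencies-by-time complex matrix), `freq`, `time` (seconds), `coi`
#'   (logical matrix, `TRUE` where edge effects corrupt the coefficient),
#'   `fs`.
#' @export
morlet_cwt <- function(x, fs, freqs = seq(1, 35, by = 0.25),
                       omega0 = 2 * pi) {
  check_scalar(fs, "fs", lower = 1e-9)
  if (!length(freqs) || any(freqs <= 0) || any(freqs >= fs / 2)) {
    abort("analysis frequencies must lie strictly inside (0, fs/2)",
          class = "neckereeg_validation_error")
  }
  n <- length(x)
  coef <- matrix(0i, nrow = length(freqs), ncol = n)
  coi <- matrix(FALSE, nrow = length(freqs), ncol = n)
  for (i in seq_along(freqs)) {
    kk <- morlet_kernel(freqs[i], fs, omega0)
    coef[i, ] <- conv_center(x, kk$k, kk$half)
    if (kk$half > 0) {
      edge <- seq_len(min(kk$half, n))
      coi[i, edge] <- TRUE
      coi[i, n + 1L - edge] <- TRUE
    }
  }
  structure(list(coef = coef, freq = freqs, time = (seq_len(n) - 1) / fs,
                 coi = coi, fs = fs),
            class = "eeg_cwt")
}

new_tfmap <- function(energy, freq, time, coi, n_averaged, group) {
  if (any(energy < 0)) abort("wavelet energy must be non-negative")
  structure(list(energy = energy, freq = freq, time = time, coi = coi,
                 n_averaged = n_averaged, group = group),
            class = "eeg_tfmap")
}

#' Wavelet energy spectrum
#'
#' The energy is the squared modulus of the wavelet coefficients,
#' `E(f, t) = |W(f, t)|^2`.
#'
#' @param W An `eeg_cwt` object (or bare complex matrix).
#' @return An `eeg_tfmap`: `energy`, `freq`, `time`, `coi`, `n_averaged`,
#'   `group`.
#' @export
energy_spectrum <- function(W) {
  if (inherits(W, "eeg_cwt")) {
    new_tfmap(Mod(W$coef)^2, W$freq, W$time, W$coi, 1L, "single")
  } else {
    new_tfmap(Mod(as.matrix(W))^2, seq_len(nrow(as.matrix(W))),
              seq_len(ncol(as.matrix(W))), NULL, 1L, "single")
  }
}

#' @export
print.eeg_tfmap <- function(x, ...) {
  cat(sprintf(
    "<eeg_tfmap> %s: %d freqs [%g, %g] Hz x %d times [%g, %g] s, averaged over %d\n",
    x$group, length(x$freq), min(x$freq), max(x$freq), length(x$time),
    min(x$time), max(x$time), x$n_averaged))
  invisible(x)
}

#' Class-averaged wavelet energy spectrum
#'
#' Computes the wavelet energy of each epoch on the selected (occipital)
#' channels and averages over channels and over the epochs of one percept
#' class, yielding the class-conditional time-frequency map `<A_L>` or
#' `<A_R>`.
#'
#' @param epochs Epoch tibble from [extract_epochs()] (list-column `data`,
#'   `label`); epoch time is taken relative to stimulus onset using the
#'   `pre` attribute.
#' @param group `"L"` or `"R"` to select a percept class, or `"all"` to
#'   average every epoch.
#' @param channels Channel subset to average over; default `c("O1", "O2")`,
#'   with `c("O1", "O2", "P3", "P4", "Cz", "Pz")` as the common six-channel
#'   occipito-parietal alternative.
#' @param freqs Analysis frequency grid, Hz.
#' @param fs Sampling rate; defaults to the epochs' `fs` attribute.
#' @return An `eeg_tfmap` with `n_averaged` epochs and the group label.
#' @export
averaged_spectrum <- function(epochs, group = c("L", "R", "all"),
                              channels = c("O1", "O2"),
                              freqs = seq(1, 35, by = 0.25), fs = NULL) {
  group <- match.arg(group)
  if (!nrow(epochs)) abort("empty epoch list")
  if (!length(channels)) abort("channel subset must be non-empty")
  fs <- fs %||% attr(epochs, "fs")
  if (is.null(fs)) abort("sampling rate not supplied and not attached to epochs")
  sel <- if (group == "all") rep(TRUE, nrow(epochs)) else epochs$label == group
  if (!any(sel)) abort(sprintf("no epochs with label %s", group))
  mats <- epochs$data[sel]
  missing_ch <- setdiff(channels, rownames(mats[[1]]))
  if (length(missing_ch)) {
    abort(sprintf("channel(s) not present: %s", paste(missing_ch, collapse = ", ")))
  }
  acc <- NULL
  coi <- NULL
  for (m in mats) {
    for (ch in channels) {
      w <- morlet_cwt(m[ch, ], fs, freqs)
      e <- Mod(w$coef)^2
      acc <- if (is.null(acc)) e else acc + e
      coi <- coi %||% w$coi
    }
  }
  energy <- acc / (length(mats) * length(channels))
  pre <- attr(epochs, "pre") %||% 0
  time <- (seq_len(ncol(energy)) - 1) / fs - pre
  new_tfmap(energy, freqs, time, coi, length(mats),
            if (group == "all") "single" else group)
}

#' Integrated spectral contrast between percept classes
#'
#' The contrast coefficient is the 2-D quadrature of
#' `<A_L>(f, t) - <A_R>(f, t)` over a frequency band and a peristimulus
#' time window (trapezoidal rule on the common grid). With
#' `normalize = TRUE` the integral is divided by the same quadrature of the
#' grand-mean spectrum `(<A_L> + <A_R>)/2`, giving a dimensionless
#' normalized comparison coefficient.
#'
#' @param a_l,a_r Class-averaged `eeg_tfmap`s on identical grids.
#' @param f_band Frequency band `c(f1, f2)` in Hz (default: full grid).
#' @param t_window Time window `c(t1, t2)` in seconds (default: full grid).
#' @param normalize Divide by the integrated grand-mean spectrum?
#' @return Scalar contrast `<Delta A>` (antisymmetric under swapping the
#'   class arguments).
#' @export
delta_a <- function(a_l, a_r, f_band = NULL, t_window = NULL,
                    normalize = FALSE) {
  stopifnot(inherits(a_l, "eeg_tfmap"), inherits(a_r, "eeg_tfmap"))
  if (!isTRUE(all.equal(a_l$freq, a_r$freq)) ||
      !isTRUE(all.equal(a_l$time, a_r$time))) {
    abort("the two spectra must share the same frequency/time grid")
  }
  f_band <- f_band %||% range(a_l$freq)
  t_window <- t_window %||% range(a_l$time)
  fi <- which(a_l$freq >= f_band[1] - 1e-9 & a_l$freq <= f_band[2] + 1e-9)
  ti <- which(a_l$time >= t_window[1] - 1e-9 & a_l$time <= t_window[2] + 1e-9)
  if (length(fi) < 2L || length(ti) < 2L) {
    abort("band/window must cover at least two grid points in each axis")
  }
  num <- trapz2d(a_l$freq[fi], a_l$time[ti],
                 (a_l$energy - a_r$energy)[fi, ti, drop = FALSE])
  if (!normalize) return(num)
  den <- trapz2d(a_l$freq[fi], a_l$time[ti],
                 ((a_l$energy + a_r$energy) / 2)[fi, ti, drop = FALSE])
  num / den
}

#' Mean band energy of a time-frequency map
#'
#' Average energy over a frequency band and time window; a convenience for
#' quantifying alpha desynchronization (for example, 8-12 Hz during the
#' presentation vs before onset).
#'
#' @param tfmap An `eeg_tfmap`.
#' @param f_band Frequency band `c(f1, f2)`, Hz.
#' @param t_window Time window `c(t1, t2)`, seconds.
#' @return Scalar mean energy.
#' @export
band_energy <- function(tfmap, f_band, t_window) {
  stopifnot(inherits(tfmap, "eeg_tfmap"))
  fi <- which(tfmap$freq >= f_band[1] - 1e-9 & tfmap$freq <= f_band[2] + 1e-9)
  ti <- which(tfmap$time >= t_window[1] - 1e-9 & tfmap$time <= t_window[2] + 1e-9)
  if (!length(fi) || !length(ti)) abort("band/window outside the grid")
  mean(tfmap$energy[fi, ti])
}

#' Write a time-frequency map as delimited text
#'
#' The matrix is written with a frequency column and one column per time
#' point (header row holds the time axis).
#'
#' @param tfmap An `eeg_tfmap`.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_tfmap <- function(tfmap, path) {
  df <- as_tibble(tfmap$energy, .name_repair = function(x)
    sprintf("t_%.6g", tfmap$time))
  df <- dplyr::bind_cols(tibble(freq_hz = tfmap$freq), df)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
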