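#' Contrast levels of the ambiguous-cube stimulus
#'
#' The seven wireframe-contrast values `g` used in the emulated experimental
#' design. `g` biases the percept towards the left-oriented interpretation.
#'
#' @return Numeric vector of length 7.
#' @export
necker_g_values <- function() c(0.15, 0.3, 0.4, 0.5, 0.6, 0.7, 0.85)

#' Create a deterministic synthetic-subject profile
#'
#' A subject profile collects every parameter of the per-subject EEG signal
#' model: background spectrum, alpha rhythm, stimulus-locked
#' desynchronization, the class-dependent effect size, and ocular-artifact
#' rates and mixing gains. Identical `(seed, subject_id)` always yield an
#' identical profile; `...` overrides any documented field.
#'
#' The class effect has two tied parts, both scaled by `class_effect_amp`
#' (microvolts): a biphasic evoked component whose per-lobe *window mean* is
#' `class_effect_amp` at O1/O2 (positive over 0.2-0.4 s and negative over
#' 0.6-0.8 s for a left percept, negated for a right percept), and an
#' occipital alpha-power lateralization of fraction
#' `class_alpha_coef * class_effect_amp` (left percepts carry the O1 alpha
#' surplus). The second part gives the percepts a time-average-visible
#' signature, which is what a sample-wise classifier with a mean-squared
#' output statistic can exploit.
#'
#' @param seed Non-negative integer cohort seed.
#' @param subject_id Positive integer identifying the subject.
#' @param ... Named overrides for profile fields, e.g. `class_effect_amp = 0`.
#' @return An object of class `eeg_profile` (a named list).
#' @examples
#' p <- subject_profile(1, 1)
#' p$alpha_freq
#' @export
subject_profile <- function(seed, subject_id = 1L, ...) {
  check_scalar(seed, "seed", lower = 0)
  check_scalar(subject_id, "subject_id", lower = 1)
  drawn <- local_seed(seed_combine(seed, subject_id, 1), {
    list(
      alpha_freq = runif(1, 8, 12),
      alpha_amp  = runif(1, 15, 25) # posterior-dominant resting alpha, uV
    )
  })
  prof <- list(
    subject_id       = as.integer(subject_id),
    alpha_freq       = drawn$alpha_freq,   # Hz
    alpha_amp        = drawn$alpha_amp,    # microvolts (sinusoid amplitude)
    noise_amp        = 6,                  # microvolts (background SD)
    noise_slope      = 1,                  # 1/f^slope spectral exponent
    class_effect_amp = 3,                  # microvolts (lobe window mean)
    class_alpha_coef = 0.08,               # lateralization fraction per microvolt
    desync_factor    = 0.5,                # alpha amplitude during presentation
    blink_rate       = 10,                 # events/min
    saccade_rate     = 15,                 # events/min
    eog_mix_gains    = default_eog_gains(),
    rng_seed         = seed_combine(seed, subject_id, 2)
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(prof))
    if (length(bad)) {
      abort(sprintf("unknown profile field(s): %s", paste(bad, collapse = ", ")),
            class = "neckereeg_validation_error")
    }
    prof <- modifyList(prof, overrides)
  }
  validate_profile(prof)
  structure(prof, class = "eeg_profile")
}

validate_profile <- function(p) {
  check_scalar(p$alpha_freq, "alpha_freq", 8, 12)
  check_scalar(p$alpha_amp, "alpha_amp", 0, Inf)
  check_scalar(p$noise_amp, "noise_amp", 0, Inf)
  check_scalar(p$noise_slope, "noise_slope", 0, 3)
  check_scalar(p$class_effect_amp, "class_effect_amp", 0, Inf)
  check_scalar(p$class_alpha_coef, "class_alpha_coef", 0, Inf)
  check_scalar(p$desync_factor, "desync_factor", 0, 1)
  check_scalar(p$blink_rate, "blink_rate", 0, Inf)
  check_scalar(p$saccade_rate, "saccade_rate", 0, Inf)
  if (!is.numeric(p$eog_mix_gains) || length(p$eog_mix_gains) != 19L) {
    abort("`eog_mix_gains` must be a numeric vector of length 19")
  }
  if (is.null(names(p$eog_mix_gains))) {
    abort("`eog_mix_gains` must be named by channel")
  }
  if (p$eog_mix_gains[["Fp1"]] <= p$eog_mix_gains[["O1"]]) {
    abort("`eog_mix_gains` must be frontal-dominant (Fp1 > O1)",
          class = "neckereeg_validation_error")
  }
  invisible(p)
}

#' @export
print.eeg_profile <- function(x, ...) {
  cat(sprintf(
    "<eeg_profile> subject %d: alpha %.2f Hz x %.1f uV, noise %.1f uV (1/f^%.1f),\n",
    x$subject_id, x$alpha_freq, x$alpha_amp, x$noise_amp, x$noise_slope))
  cat(sprintf(
    "  class effect %.1f uV (alpha lateralization %.2f), desync %.2f, blinks %.0f/min, saccades %.0f/min\n",
    x$class_effect_amp, x$class_alpha_coef * x$class_effect_amp,
    x$desync_factor, x$blink_rate, x$saccade_rate))
  invisible(x)
}

# Spectrally shaped Gaussian noise with amplitude spectrum f^(-slope/2),
# flat below 1 Hz, normalized to unit SD.
pink_noise <- function(n, slope, fs) {
  if (n < 4) return(rnorm(n))
  # pad to a 2-3-5-smooth length: R's mixed-radix FFT degrades to O(n^2)
  # on lengths with large prime factors
  m <- stats::nextn(n, c(2, 3, 5))
  w <- rnorm(m)
  f <- c(0, seq_len(m - 1)) / m * fs
  f <- pmin(f, fs - f)             # two-sided frequency axis
  shape <- pmax(f, 1)^(-slope / 2) # flat at/below 1 Hz avoids DC blowup
  x <- Re(fft(fft(w) * shape, inverse = TRUE))[seq_len(n)] / m
  x / sd(x)
}

# Raised-cosine lobe over [t1, t2] whose mean over the window equals `amp`.
raised_cosine_lobe <- function(t, t1, t2, amp) {
  inside <- t >= t1 & t < t2
  out <- numeric(length(t))
  out[inside] <- amp * (1 - cos(2 * pi * (t[inside] - t1) / (t2 - t1)))
  out
}

# Evoked class component on the trial-relative time axis (seconds): window
# mean +amp over [0.2, 0.4) and -amp over [0.6, 0.8) for label "L".
class_component <- function(t_rel, amp, label) {
  sgn <- if (label == "L") 1 else -1
  sgn * (raised_cosine_lobe(t_rel, 0.2, 0.4, amp) -
           raised_cosine_lobe(t_rel, 0.6, 0.8, amp))
}

new_recording <- function(signal, fs, channel_labels, eog_v, eog_h, subject_id) {
  rownames(signal) <- channel_labels
  structure(
    list(signal = signal, fs = fs, channel_labels = channel_labels,
         eog_v = eog_v, eog_h = eog_h, subject_id = as.integer(subject_id)),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject %d: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, nrow(x$signal), ncol(x$signal), x$fs,
              ncol(x$signal) / x$fs))
  invisible(x)
}

#' Generate one synthetic stimulus session
#'
#' Simulates a full recording session for one subject: 1/f background noise
#' plus an occipital-dominant alpha rhythm on all 19 channels, a randomized
#' trial sequence (presentation durations 0.8-1.3 s; inter-stimulus
#' intervals 2-3 s for the button design or 5-7 s for the voice design;
#' contrast `g` drawn from the seven standard values; percept labels drawn
#' with `P(L) = g`), stimulus-locked alpha desynchronization by
#' `desync_factor` during each presentation, and the class-dependent evoked
#' and induced components described in [subject_profile()]. EOG reference
#' channels are returned silent; add ocular artifacts with [inject_eog()].
#'
#' The session is a pure function of the profile and the arguments: the
#' random stream is seeded from `profile$rng_seed` and draws occur in a
#' fixed documented order (durations, ISIs, contrasts, labels, alpha phases,
#' then per-channel background noise).
#'
#' @param profile An `eeg_profile`.
#' @param n_trials Number of stimulus presentations (may be 0).
#' @param fs Sampling rate in Hz (>= 100).
#' @param design `"button"` (ISI 2-3 s) or `"voice"` (ISI 5-7 s).
#' @param max_duration Maximum session length in seconds; exceeding it is an
#'   error.
#' @return A list with elements `recording` (an `eeg_recording`, microvolts)
#'   and `events` (a tibble with columns `onset_sample` (0-based), `g`,
#'   `label`, `presentation_samples`).
#' @examples
#' ses <- generate_session(subject_profile(1), n_trials = 3)
#' ses$events
#' @export
generate_session <- function(profile, n_trials, fs = 250,
                             design = c("button", "voice"),
                             max_duration = 7200) {
  stopifnot(inherits(profile, "eeg_profile"))
  design <- match.arg(design)
  check_scalar(n_trials, "n_trials", lower = 0)
  check_scalar(fs, "fs", lower = 100)
  n_trials <- as.integer(n_trials)
  isi_range <- if (design == "button") c(2, 3) else c(5, 7)
  lead_in <- 2; lead_out <- 2

  local_seed(profile$rng_seed, {
    tau <- if (n_trials) runif(n_trials, 0.8, 1.3) else numeric(0)
    isi <- if (n_trials) runif(n_trials, isi_range[1], isi_range[2]) else numeric(0)
    g <- if (n_trials) sample(necker_g_values(), n_trials, replace = TRUE) else numeric(0)
    label <- if (n_trials) ifelse(rbinom(n_trials, 1, g) == 1, "L", "R") else character(0)

    total <- lead_in + sum(tau + isi) + lead_out
    if (total > max_duration) {
      abort(sprintf("session duration %.0f s exceeds max_duration %.0f s",
                    total, max_duration),
            class = "neckereeg_validation_error")
    }
    n_samp <- as.integer(ceiling(total * fs))
    t_axis <- (seq_len(n_samp) - 1) / fs
    onset_time <- lead_in + c(0, cumsum(tau + isi))[seq_len(n_trials)]
    onset_sample <- as.integer(round(onset_time * fs)) # 0-based
    pres_samples <- as.integer(round(tau * fs))

    chans <- eeg_channels()
    a_gain <- alpha_gain_map()
    e_gain <- evoked_gain_map()
    kappa <- min(0.9, profile$class_alpha_coef * profile$class_effect_amp)

    phases <- runif(19, 0, 2 * pi)

    # alpha amplitude envelope: 1 at rest, desync_factor during presentations
    env <- rep(1, n_samp)
    # per-channel lateralization multiplier (only O1/O2 and P3/P4 deviate)
    lat <- matrix(1, nrow = 19, ncol = n_samp, dimnames = list(chans, NULL))
    evoked <- matrix(0, nrow = 19, ncol = n_samp)
    for (k in seq_len(n_trials)) {
      i0 <- onset_sample[k] + 1L
      i1 <- min(onset_sample[k] + pres_samples[k], n_samp)
      env[i0:i1] <- profile$desync_factor
      s <- if (label[k] == "L") 1 else -1
      lat["O1", i0:i1] <- 1 + s * kappa
      lat["O2", i0:i1] <- 1 - s * kappa
      lat["P3", i0:i1] <- 1 + s * kappa / 2
      lat["P4", i0:i1] <- 1 - s * kappa / 2
      # evoked component over one trial-second after onset
      j1 <- min(onset_sample[k] + as.integer(round(fs)), n_samp)
      t_rel <- (seq(i0, j1) - i0) / fs
      comp <- class_component(t_rel, profile$class_effect_amp, label[k])
      evoked[, i0:j1] <- evoked[, i0:j1] + outer(e_gain, comp)
    }

    alpha <- (profile$alpha_amp * a_gain) * lat *
      matrix(env, nrow = 19, ncol = n_samp, byrow = TRUE) *
      sin(matrix(2 * pi * profile$alpha_freq * t_axis,
                 nrow = 19, ncol = n_samp, byrow = TRUE) + phases)

    bg <- matrix(0, nrow = 19, ncol = n_samp)
    for (ch in seq_len(19)) {
      bg[ch, ] <- profile$noise_amp * pink_noise(n_samp, profile$noise_slope, fs)
    }

    signal <- bg + alpha + evoked
    rec <- new_recording(signal, fs, chans,
                         eog_v = numeric(n_samp), eog_h = numeric(n_samp),
                         subject_id = profile$subject_id)
    events <- tibble(
      onset_sample = onset_sample,
      g = g,
      label = label,
      presentation_samples = pres_samples
    )
    class(events) <- c("eeg_events", class(events))
    list(recording = rec, events = events)
  })
}

#' Add ocular artifacts to a recording
#'
#' Generates blink and saccade waveforms as seeded Poisson point processes at
#' the profile's rates, writes them to the vertical/horizontal EOG reference
#' channels, and adds them to every scalp channel scaled by the profile's
#' frontal-dominant mixing gains. Mixing is purely additive and linear, so
#' the Gram-Schmidt cleaning step can in principle remove the contamination
#' exactly.
#'
#' @param recording An `eeg_recording`.
#' @param profile The `eeg_profile` supplying rates, gains and the seed.
#' @return The recording with contaminated scalp channels and populated
#'   `eog_v`/`eog_h` references.
#' @export
inject_eog <- function(recording, profile) {
  stopifnot(inherits(recording, "eeg_recording"), inherits(profile, "eeg_profile"))
  n <- ncol(recording$signal)
  fs <- recording$fs
  dur_min <- n / fs / 60

  local_seed(seed_combine(profile$rng_seed, 77), {
    eog_v <- numeric(n)
    eog_h <- numeric(n)
    n_blink <- rpois(1, profile$blink_rate * dur_min)
    if (n_blink > 0) {
      b_time <- runif(n_blink, 0, n / fs)
      b_amp <- runif(n_blink, 120, 180)
      for (b in seq_len(n_blink)) {
        i0 <- as.integer(round(b_time[b] * fs))
        len <- as.integer(round(0.3 * fs))
        idx <- (i0 + 1):min(i0 + len, n)
        if (length(idx) < 2) next
        ph <- (seq_along(idx) - 1) / len
        eog_v[idx] <- eog_v[idx] + b_amp[b] * 0.5 * (1 - cos(2 * pi * ph))
      }
    }
    n_sac <- rpois(1, profile$saccade_rate * dur_min)
    if (n_sac > 0) {
      s_time <- runif(n_sac, 0, n / fs)
      s_dur <- runif(n_sac, 0.2, 0.6)
      s_amp <- runif(n_sac, 60, 100) * sample(c(-1, 1), n_sac, replace = TRUE)
      ramp_len <- as.integer(round(0.04 * fs))
      for (s in seq_len(n_sac)) {
        i0 <- as.integer(round(s_time[s] * fs))
        len <- as.integer(round(s_dur[s] * fs))
        idx <- (i0 + 1):min(i0 + len, n)
        if (length(idx) < 2) next
        box <- rep(1, length(idx))
        r <- min(ramp_len, floor(length(idx) / 2))
        if (r > 0) {
          box[seq_len(r)] <- seq_len(r) / r
          box[(length(idx) - r + 1):length(idx)] <- rev(seq_len(r) / r)
        }
        eog_h[idx] <- eog_h[idx] + s_amp[s] * box
      }
    }
    recording$signal <- recording$signal +
      outer(profile$eog_mix_gains, eog_v + eog_h)
    recording$eog_v <- recording$eog_v + eog_v
    recording$eog_h <- recording$eog_h + eog_h
    recording
  })
}
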