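# Discrete inner product implementing the continuous-time quadrature with
# the rectangle rule, dt = 1/fs. With this convention the orthogonalization
# below is *exact* in the discrete inner product.
ip <- function(a, b, fs) sum(a * b) / fs

resolve_window <- function(n, fs, t1, duration) {
  check_scalar(t1, "t1", lower = 0)
  if (is.null(duration)) duration <- n / fs - t1
  check_scalar(duration, "duration", lower = 0)
  i0 <- as.integer(round(t1 * fs)) + 1L
  i1 <- as.integer(round((t1 + duration) * fs))
  if (i0 < 1L || i1 > n || i1 < i0) {
    abort(sprintf("window [%g, %g] s does not fit a %d-sample signal", t1,
                  t1 + duration, n))
  }
  i0:i1
}

#' Normalize an EOG reference signal to unit energy
#'
#' Divides the reference by its L2 norm over the analysis window, the norm
#' being the discrete rectangle-rule quadrature of the squared signal with
#' `dt = 1/fs`. The returned window has exactly unit norm under the same
#' rule.
#'
#' @param x Reference signal (numeric vector, e.g. microvolts).
#' @param fs Sampling rate in Hz.
#' @param t1 Window start in seconds (default 0).
#' @param duration Window length in seconds (default: the rest of the
#'   signal).
#' @param tol Degenerate-reference tolerance: norms below `tol` raise an
#'   error rather than dividing by (near) zero.
#' @return The normalized reference on the window.
#' @examples
#' normalize_reference(rep(2, 250), fs = 250)[1] # constant 2 -> constant 1
#' @export
normalize_reference <- function(x, fs, t1 = 0, duration = NULL, tol = 1e-12) {
  check_scalar(fs, "fs", lower = 1e-9)
  idx <- resolve_window(length(x), fs, t1, duration)
  w <- x[idx]
  nrm <- sqrt(ip(w, w, fs))
  if (!is.finite(nrm) || nrm < tol) {
    abort("degenerate (near-zero-norm) reference signal",
          class = "neckereeg_degenerate_reference")
  }
  w / nrm
}

#' Remove ocular artifacts by sequential orthogonalization
#'
#' Projects the EEG signal against the normalized vertical EOG reference and
#' then against the normalized horizontal reference:
#' `x' = x - c_v0 <c_v0, x>`, `x~ = x' - c_h0 <c_h0, x'>`, with inner
#' products under the discrete rectangle rule. The result is exactly
#' orthogonal to the horizontal reference, and the intermediate signal
#' exactly orthogonal to the vertical one; when the two references are
#' themselves orthogonal, the result is orthogonal to both.
#'
#' The default numeric method cleans one channel; the `eeg_recording` method
#' cleans all 19 scalp channels against the recording's own EOG references.
#'
#' @param x A numeric signal or an `eeg_recording`.
#' @param ... Passed between methods.
#' @return Cleaned signal of the same shape (the window for the numeric
#'   method; the full recording for the recording method).
#' @export
remove_eog <- function(x, ...) UseMethod("remove_eog")

#' @rdname remove_eog
#' @param c_v,c_h Vertical and horizontal EOG reference signals, same length
#'   as `x`.
#' @inheritParams normalize_reference
#' @export
remove_eog.default <- function(x, c_v, c_h, fs, t1 = 0, duration = NULL,
                               tol = 1e-12, ...) {
  if (length(c_v) != length(x) || length(c_h) != length(x)) {
    abort("`x`, `c_v` and `c_h` must have the same length")
  }
  idx <- resolve_window(length(x), fs, t1, duration)
  cv0 <- normalize_reference(c_v, fs, t1, duration, tol)
  ch0 <- normalize_reference(c_h, fs, t1, duration, tol)
  xw <- x[idx]
  xp <- xw - cv0 * ip(cv0, xw, fs)
  xp - ch0 * ip(ch0, xp, fs)
}

#' @rdname remove_eog
#' @export
remove_eog.eeg_recording <- function(x, t1 = 0, duration = NULL,
                                     tol = 1e-12, ...) {
  idx <- resolve_window(ncol(x$signal), x$fs, t1, duration)
  cleaned <- t(apply(x$signal, 1L, function(ch)
    remove_eog.default(ch, x$eog_v, x$eog_h, x$fs, t1, duration, tol)))
  out <- x
  out$signal[, idx] <- cleaned
  rownames(out$signal) <- x$channel_labels
  out
}

#' Band-limit a recording
#'
#' Applies a zero-phase 4th-order Butterworth band-pass (two second-order
#' sections via forward-backward filtering) and an optional 2nd-order notch
#' to every scalp and EOG channel, mirroring standard acquisition filters
#' (1-100 Hz band-pass with a 50 Hz mains notch).
#'
#' @param recording An `eeg_recording`.
#' @param hp,lp High-pass and low-pass corner frequencies in Hz
#'   (`hp < lp < fs/2`).
#' @param notch Notch center frequency in Hz (+-1 Hz stop band), or `NULL`
#'   to skip.
#' @return The filtered recording.
#' @export
bandlimit <- function(recording, hp = 1, lp = 100, notch = 50) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$fs
  nyq <- fs / 2
  if (!(hp > 0 && hp < lp && lp < nyq)) {
    abort(sprintf("need 0 < hp < lp < fs/2; got hp=%g, lp=%g, fs/2=%g",
                  hp, lp, nyq), class = "neckereeg_validation_error")
  }
  if (!is.null(notch) && (notch - 1 <= 0 || notch + 1 >= nyq)) {
    abort(sprintf("notch band [%g, %g] Hz must lie inside (0, fs/2)",
                  notch - 1, notch + 1), class = "neckereeg_validation_error")
  }
  bp <- signal::butter(2, c(hp, lp) / nyq, type = "pass")
  nt <- if (!is.null(notch)) {
    signal::butter(1, c(notch - 1, notch + 1) / nyq, type = "stop")
  }
  apply_filt <- function(v) {
    v <- signal::filtfilt(bp, v)
    if (!is.null(nt)) v <- signal::filtfilt(nt, v)
    v
  }
  out <- recording
  out$signal <- t(apply(recording$signal, 1L, apply_filt))
  rownames(out$signal) <- recording$channel_labels
  out$eog_v <- apply_filt(recording$eog_v)
  out$eog_h <- apply_filt(recording$eog_h)
  out
}

#' Cut a recording into stimulus-locked trials
#'
#' Extracts one trial per event, aligned at the stimulus onset and
#' `round(fs * duration)` samples long (half-open window
#' `[onset, onset + N)`, onsets 0-based). Sample values are copied
#' bit-exactly. Events whose window does not fit inside the recording are
#' skipped with a message.
#'
#' @param recording An `eeg_recording`.
#' @param events Event tibble with 0-based `onset_sample`, `g`, `label`.
#' @param duration Trial length in seconds (default 1, i.e. 250 samples at
#'   250 Hz).
#' @return An `eeg_trials` tibble with one row per kept trial: `trial_id`,
#'   `subject_id`, `label`, `g`, `onset_sample`, and a `data` list-column of
#'   channels-by-samples matrices. The sampling rate and duration are
#'   carried in attributes `fs` and `duration`.
#' @export
extract_trials <- function(recording, events, duration = 1) {
  stopifnot(inherits(recording, "eeg_recording"))
  check_scalar(duration, "duration", lower = 1e-9)
  fs <- recording$fs
  n_samp <- as.integer(round(fs * duration))
  total <- ncol(recording$signal)
  keep <- events$onset_sample + n_samp <= total & events$onset_sample >= 0
  if (any(!keep)) {
    message(sprintf("extract_trials: skipped %d event(s) with incomplete windows",
                    sum(!keep)))
  }
  ev <- events[keep, , drop = FALSE]
  data <- lapply(ev$onset_sample, function(s0) {
    recording$signal[, (s0 + 1L):(s0 + n_samp), drop = FALSE]
  })
  out <- tibble(
    trial_id = seq_len(nrow(ev)),
    subject_id = recording$subject_id,
    label = ev$label,
    g = ev$g,
    onset_sample = ev$onset_sample,
    data = data
  )
  attr(out, "fs") <- fs
  attr(out, "duration") <- duration
  attr(out, "n_skipped") <- sum(!keep)
  class(out) <- c("eeg_trials", class(out))
  out
}

trials_fs <- function(trials) {
  fs <- attr(trials, "fs")
  if (is.null(fs)) abort("trials object lacks an `fs` attribute")
  fs
}

#' Scale trials to the interval [-1, 1]
#'
#' Per electrode, an affine min-max map computed over that electrode's
#' samples pooled across all of the subject's trials sends the pooled
#' minimum to -1 and the pooled maximum to +1 (mode `"pooled"`, the
#' default). Mode `"per_trial"` computes the map within each trial instead.
#' Channels that are constant over the pooling set map to 0. Applying the
#' pooled scaling twice is the identity.
#'
#' @param trials An `eeg_trials` tibble.
#' @param mode `"pooled"` or `"per_trial"`.
#' @return The trials tibble with scaled `data`; the pooled channel ranges
#'   are attached as attribute `scaling` (a tibble).
#' @export
scale_trials <- function(trials, mode = c("pooled", "per_trial")) {
  mode <- match.arg(mode)
  if (!nrow(trials)) abort("cannot scale an empty trial set")
  scale_mat <- function(m, mn, mx) {
    rng <- mx - mn
    flat <- rng < 1e-12
    out <- 2 * (m - mn) / ifelse(flat, 1, rng) - 1
    out[flat, ] <- 0
    out
  }
  if (mode == "pooled") {
    pooled <- do.call(cbind, trials$data)
    mn <- apply(pooled, 1L, min)
    mx <- apply(pooled, 1L, max)
    trials$data <- lapply(trials$data, scale_mat, mn = mn, mx = mx)
    attr(trials, "scaling") <- tibble(channel = rownames(trials$data[[1]]),
                                      min = mn, max = mx)
  } else {
    trials$data <- lapply(trials$data, function(m)
      scale_mat(m, apply(m, 1L, min), apply(m, 1L, max)))
  }
  trials
}

#' Cut peristimulus epochs for time-frequency analysis
#'
#' Like [extract_trials()] but with a window extending `pre` seconds before
#' and `post` seconds after the stimulus onset, for wavelet analysis of the
#' peristimulus interval (the conventional window is 1 s before to 2 s
#' after onset, spanning about 3 s).
#'
#' @inheritParams extract_trials
#' @param pre,post Window extent before/after onset, seconds.
#' @return An `eeg_trials`-like tibble of epochs with attributes `fs` and
#'   `pre`; epoch time runs from `-pre` to `post`.
#' @export
extract_epochs <- function(recording, events, pre = 1, post = 2) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$fs
  n_pre <- as.integer(round(fs * pre))
  n_post <- as.integer(round(fs * post))
  total <- ncol(recording$signal)
  keep <- events$onset_sample - n_pre >= 0 &
    events$onset_sample + n_post <= total
  if (any(!keep)) {
    message(sprintf("extract_epochs: skipped %d event(s) with incomplete windows",
                    sum(!keep)))
  }
  ev <- events[keep, , drop = FALSE]
  data <- lapply(ev$onset_sample, function(s0) {
    recording$signal[, (s0 - n_pre + 1L):(s0 + n_post), drop = FALSE]
  })
  out <- tibble(
    trial_id = seq_len(nrow(ev)),
    subject_id = recording$subject_id,
    label = ev$label,
    g = ev$g,
    onset_sample = ev$onset_sample,
    data = data
  )
  attr(out, "fs") <- fs
  attr(out, "pre") <- pre
  attr(out, "post") <- post
  class(out) <- c("eeg_trials", class(out))
  out
}

#' Write / read extracted trials as delimited text
#'
#' Trials are stored as one wide CSV per subject (rows: trial x channel,
#' columns: samples) plus a tab-delimited manifest (`trial_id`, `label`,
#' `g`, `onset_sample`).
#'
#' @param trials An `eeg_trials` tibble.
#' @param path Base path; `<path>.csv` and `<path>_manifest.tsv` are
#'   written.
#' @return `write_trials()` returns `path` invisibly; `read_trials()`
#'   returns the trials tibble.
#' @export
write_trials <- function(trials, path) {
  chans <- rownames(trials$data[[1]])
  mat <- do.call(rbind, trials$data)
  wide <- tibble(
    trial_id = rep(trials$trial_id, each = length(chans)),
    channel = rep(chans, times = nrow(trials))
  )
  wide <- dplyr::bind_cols(wide, as_tibble(mat, .name_repair = function(x)
    paste0("s", seq_along(x))))
  readr::write_csv(wide, paste0(path, ".csv"), progress = FALSE)
  manifest <- tibble(trial_id = trials$trial_id, subject_id = trials$subject_id,
                     label = trials$label, g = trials$g,
                     onset_sample = trials$onset_sample,
                     fs = trials_fs(trials))
  readr::write_tsv(manifest, paste0(path, "_manifest.tsv"), progress = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  wide <- readr::read_csv(paste0(path, ".csv"), show_col_types = FALSE,
                          progress = FALSE)
  manifest <- readr::read_tsv(paste0(path, "_manifest.tsv"),
                              show_col_types = FALSE, progress = FALSE)
  ids <- unique(wide$trial_id)
  data <- lapply(ids, function(id) {
    block <- wide[wide$trial_id == id, , drop = FALSE]
    m <- as.matrix(block[, -(1:2)])
    dimnames(m) <- list(block$channel, NULL)
    m
  })
  out <- tibble(
    trial_id = manifest$trial_id,
    subject_id = manifest$subject_id,
    label = manifest$label,
    g = manifest$g,
    onset_sample = manifest$onset_sample,
    data = data
  )
  attr(out, "fs") <- manifest$fs[1]
  attr(out, "duration") <- ncol(data[[1]]) / manifest$fs[1]
  class(out) <- c("eeg_trials", class(out))
  out
}
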