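#' Class-conditional trial average (event-related potential)
#'
#' Per-channel arithmetic mean across all trials of one percept class: the
#' averaged trace `x_bar_p(t)` for channel `p`, the sum over the class's
#' trials divided by the class trial count.
#'
#' @param trials An `eeg_trials` tibble with `label` and `data` columns (any
#'   units; use unscaled microvolt trials to compare against generator
#'   amplitudes).
#' @param class `"L"` or `"R"`.
#' @return An object of class `erp_trace`: list with `mean`
#'   (channels-by-samples matrix), `n`, `class`, `fs`, `channels`.
#' @export
average_trials <- function(trials, class = c("L", "R")) {
  class <- match.arg(class)
  stopifnot(is.data.frame(trials), all(c("label", "data") %in% names(trials)))
  mats <- trials$data[trials$label == class]
  if (!length(mats)) {
    abort(sprintf("no trials with label %s", class),
          class = "neckereeg_validation_error")
  }
  m <- Reduce(`+`, mats) / length(mats)
  structure(list(mean = m, n = length(mats), class = class,
                 fs = attr(trials, "fs"), channels = rownames(m)),
            class = "erp_trace")
}

#' @export
print.erp_trace <- function(x, ...) {
  cat(sprintf("<erp_trace> class %s: %d channels x %d samples, mean of %d trials\n",
              x$class, nrow(x$mean), ncol(x$mean), x$n))
  invisible(x)
}

#' Averaged difference trace between percept classes
#'
#' The per-channel difference `Delta_p(t) = x_bar_p^L(t) - x_bar_p^R(t)`
#' between the class-conditional averages; antisymmetric under exchanging
#' the class arguments.
#'
#' @param erp_l,erp_r `erp_trace` objects for the left and right percept
#'   classes, on the same channels and sample grid.
#' @return An object of class `erp_diff`: list with `delta`
#'   (channels-by-samples), `fs`, `channels`, `n_l`, `n_r`.
#' @export
difference_trace <- function(erp_l, erp_r) {
  stopifnot(inherits(erp_l, "erp_trace"), inherits(erp_r, "erp_trace"))
  if (!identical(dim(erp_l$mean), dim(erp_r$mean)) ||
      !identical(erp_l$channels, erp_r$channels)) {
    abort("the two averages must share channels and sample count")
  }
  structure(list(delta = erp_l$mean - erp_r$mean, fs = erp_l$fs,
                 channels = erp_l$channels, n_l = erp_l$n, n_r = erp_r$n),
            class = "erp_diff")
}

#' Window means of a difference trace
#'
#' Mean of `Delta_p(t)` over one or more time windows per channel, for
#' summarizing evoked components (for example the early positive 0.2-0.4 s
#' and late negative 0.6-0.8 s occipital deflections). Windows are
#' half-open `[start, end)` in trial-relative seconds, mapped to samples
#' `round(start * fs) .. round(end * fs) - 1` (0-based).
#'
#' @param delta An `erp_diff` (or a channels-by-samples matrix with `fs`
#'   supplied).
#' @param windows List of `c(start, end)` pairs in seconds.
#' @param fs Sampling rate; defaults to the object's.
#' @return A tibble with columns `channel`, `window_start`, `window_end`,
#'   `mean`.
#' @export
component_windows <- function(delta,
                              windows = list(c(0.2, 0.4), c(0.6, 0.8)),
                              fs = NULL) {
  if (inherits(delta, "erp_diff")) {
    fs <- fs %||% delta$fs
    m <- delta$delta
  } else {
    m <- as.matrix(delta)
    if (is.null(fs)) abort("`fs` must be supplied for a bare matrix")
  }
  n <- ncol(m)
  total_t <- n / fs
  purrr::map_dfr(windows, function(w) {
    if (length(w) != 2L || w[1] < 0 || w[2] > total_t + 1e-9 || w[2] <= w[1]) {
      abort(sprintf("window [%g, %g] s lies outside the trial [0, %g] s",
                    w[1], w[2], total_t), class = "neckereeg_validation_error")
    }
    idx <- (as.integer(round(w[1] * fs)) + 1L):as.integer(round(w[2] * fs))
    tibble(channel = rownames(m) %||% as.character(seq_len(nrow(m))),
           window_start = w[1], window_end = w[2],
           mean = rowMeans(m[, idx, drop = FALSE]))
  })
}

#' Write ERP traces or window tables as delimited text
#'
#' @param erp An `erp_trace` or `erp_diff`.
#' @param path Output path (TSV; one row per channel, one column per
#'   sample).
#' @return `path` invisibly.
#' @export
write_erp <- function(erp, path) {
  m <- if (inherits(erp, "erp_diff")) erp$delta else erp$mean
  df <- dplyr::bind_cols(tibble(channel = rownames(m)),
                         as_tibble(m, .name_repair = function(x)
                           paste0("s", seq_along(x))))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
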