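#' Declarative experiment configuration
#'
#' Collects every parameter of an end-to-end run in one validated object.
#' Defaults mirror the reference protocol where tractable at a desk
#' (19-channel montage at 250 Hz, 1-s trials, 19/5 hidden units, balanced
#' 35+35 training split) and a reduced restart budget where the full
#' protocol is expensive (the reference uses up to 1000 restarts).
#'
#' @param n_subjects Number of synthetic subjects.
#' @param seed Top-level seed; all stage seeds derive from it.
#' @param n_trials Stimulus presentations per subject.
#' @param fs Sampling rate, Hz.
#' @param design `"button"` or `"voice"` (sets the inter-stimulus range).
#' @param duration Trial length in seconds.
#' @param eog Inject and remove ocular artifacts?
#' @param filter `NULL`, or `list(hp=, lp=, notch=)` corner frequencies for
#'   [bandlimit()].
#' @param scaling `"pooled"` or `"per_trial"` channel scaling.
#' @param h1,h2 Hidden-layer sizes.
#' @param n_restarts,max_iter Training budget.
#' @param n_train_per_class Training trials per class.
#' @param cross_subject Evaluate the transfer matrix?
#' @param spectral List of wavelet-stage settings: `f_band`, `freqs`, `pre`,
#'   `post`, `channels`, `normalize`.
#' @param erp_windows List of `c(start, end)` windows for the ERP summary.
#' @param profile_overrides Named list forwarded to [subject_profile()] for
#'   every subject (e.g. `list(class_effect_amp = 8)`).
#' @return A validated list of class `experiment_config`.
#' @export
experiment_config <- function(n_subjects = 2, seed = 1, n_trials = 200,
                              fs = 250, design = "button", duration = 1,
                              eog = TRUE,
                              filter = list(hp = 1, lp = 100, notch = 50),
                              scaling = "pooled", h1 = 19, h2 = 5,
                              n_restarts = 20, max_iter = 80,
                              n_train_per_class = 35, cross_subject = TRUE,
                              spectral = list(), erp_windows = list(
                                c(0.2, 0.4), c(0.6, 0.8)),
                              profile_overrides = list()) {
  cfg <- list(
    n_subjects = n_subjects, seed = seed, n_trials = n_trials, fs = fs,
    design = design, duration = duration, eog = eog, filter = filter,
    scaling = scaling, h1 = h1, h2 = h2, n_restarts = n_restarts,
    max_iter = max_iter, n_train_per_class = n_train_per_class,
    cross_subject = cross_subject,
    spectral = modifyList(list(f_band = c(8, 12),
                               freqs = seq(1, 35, by = 0.5),
                               pre = 1, post = 2,
                               channels = c("O1", "O2"),
                               normalize = FALSE), spectral),
    erp_windows = erp_windows, profile_overrides = profile_overrides
  )
  validate_config(cfg)
  structure(cfg, class = "experiment_config")
}

validate_config <- function(cfg) {
  required <- c("n_subjects", "seed", "n_trials", "fs", "design", "duration",
                "scaling", "h1", "h2", "n_restarts", "max_iter",
                "n_train_per_class")
  for (f in required) {
    if (is.null(cfg[[f]])) {
      abort(sprintf("config field `%s` is missing", f),
            class = "neckereeg_config_error")
    }
  }
  check_scalar(cfg$n_subjects, "n_subjects", 1, 1000)
  check_scalar(cfg$fs, "fs", 100, Inf)
  check_scalar(cfg$n_trials, "n_trials", 0, Inf)
  check_scalar(cfg$duration, "duration", 1e-3, Inf)
  if (!cfg$design %in% c("button", "voice")) {
    abort('config field `design` must be "button" or "voice"',
          class = "neckereeg_config_error")
  }
  if (!cfg$scaling %in% c("pooled", "per_trial")) {
    abort('config field `scaling` must be "pooled" or "per_trial"',
          class = "neckereeg_config_error")
  }
  invisible(cfg)
}

log_stage <- function(log_path, stage, msg) {
  line <- sprintf("[%s] stage=%s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, msg)
  message(line)
  if (!is.null(log_path)) cat(line, "\n", file = log_path, append = TRUE)
}

pipeline_stages <- function() {
  c("simulate", "preprocess", "train", "evaluate", "cross_subject",
    "wavelet", "erp")
}

#' Run the experiment pipeline
#'
#' Executes the requested stages in dependency order, reading earlier
#' stages' artifacts from `outdir` when they are not being rerun, and
#' writes every stage's documented outputs plus `manifest.json` (config,
#' seeds, per-file checksums; no timestamps, so identical configurations
#' reproduce byte-identical result tables). Timestamped progress lines go
#' to `run.log`.
#'
#' Stage outputs, per subject `s`:
#' \describe{
#'   \item{simulate}{`sub-<s>.edf`, `sub-<s>_events.tsv`}
#'   \item{preprocess}{`sub-<s>_trials.csv` + manifest}
#'   \item{train}{`sub-<s>_model.json`, `training.tsv`}
#'   \item{evaluate}{`accuracy.tsv`}
#'   \item{cross_subject}{`cross_subject.tsv`}
#'   \item{wavelet}{`delta_a.tsv`, `sub-<s>_tf_<L|R>.tsv`}
#'   \item{erp}{`erp_windows.tsv`, `sub-<s>_erp_diff.tsv`}
#' }
#'
#' @param config An `experiment_config`.
#' @param outdir Output directory (created if needed).
#' @param stages `"all"` or a subset of
#'   `simulate, preprocess, train, evaluate, cross_subject, wavelet, erp`.
#' @param seed Optional override of `config$seed`.
#' @return Invisibly, the manifest list.
#' @export
run_experiment <- function(config, outdir, stages = "all", seed = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  validate_config(config)
  if (!is.null(seed)) config$seed <- seed
  if (identical(stages, "all")) stages <- pipeline_stages()
  bad <- setdiff(stages, pipeline_stages())
  if (length(bad)) {
    abort(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")),
          class = "neckereeg_config_error")
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(outdir, "run.log")
  subjects <- seq_len(config$n_subjects)
  sp <- function(s, suffix) file.path(outdir, sprintf("sub-%d%s", s, suffix))

  need <- function(path, producer) {
    if (!file.exists(path)) {
      abort(sprintf("missing artifact `%s`; run stage `%s` first",
                    basename(path), producer),
            class = "neckereeg_dependency_error")
    }
    path
  }

  if ("simulate" %in% stages) {
    for (s in subjects) {
      prof <- do.call(subject_profile,
                      c(list(seed = config$seed, subject_id = s),
                        config$profile_overrides))
      ses <- generate_session(prof, config$n_trials, config$fs, config$design)
      rec <- ses$recording
      if (isTRUE(config$eog)) rec <- inject_eog(rec, prof)
      write_edf(rec, sp(s, ".edf"))
      write_events(ses$events, sp(s, "_events.tsv"))
      log_stage(log_path, "simulate",
                sprintf("subject=%d trials=%d seed=%d", s,
                        nrow(ses$events), config$seed))
    }
  }

  if ("preprocess" %in% stages) {
    for (s in subjects) {
      rec <- read_edf(need(sp(s, ".edf"), "simulate"))
      ev <- read_events(need(sp(s, "_events.tsv"), "simulate"))
      if (!is.null(config$filter)) {
        rec <- bandlimit(rec, config$filter$hp, config$filter$lp,
                         config$filter$notch)
      }
      if (isTRUE(config$eog)) rec <- remove_eog(rec)
      trials <- scale_trials(extract_trials(rec, ev, config$duration),
                             mode = config$scaling)
      write_trials(trials, sp(s, "_trials"))
      log_stage(log_path, "preprocess",
                sprintf("subject=%d kept=%d", s, nrow(trials)))
    }
  }

  load_split <- function(s) {
    need(paste0(sp(s, "_trials"), ".csv"), "preprocess")
    trials <- read_trials(sp(s, "_trials"))
    train_test_split(trials, config$n_train_per_class,
                     seed = seed_combine(config$seed, s, 11))
  }

  if ("train" %in% stages) {
    train_rows <- list()
    for (s in subjects) {
      split <- load_split(s)
      fit <- train_mlp(split$train, h1 = config$h1, h2 = config$h2,
                       n_restarts = config$n_restarts,
                       max_iter = config$max_iter,
                       seed = seed_combine(config$seed, s, 12))
      write_mlp(select_best(fit), sp(s, "_model.json"),
                meta = list(subject = s,
                            mu = fit$restarts$mu[fit$best_index],
                            seed = fit$seed))
      train_rows[[s]] <- mutate(tidy(fit), subject = s)
      log_stage(log_path, "train",
                sprintf("subject=%d best_mu=%.5f", s,
                        fit$restarts$mu[fit$best_index]))
    }
    readr::write_tsv(bind_rows(train_rows),
                     file.path(outdir, "training.tsv"), progress = FALSE)
  }

  if ("evaluate" %in% stages) {
    rows <- purrr::map_dfr(subjects, function(s) {
      net <- read_mlp(need(sp(s, "_model.json"), "train"))
      split <- load_split(s)
      mutate(accuracy_report(net, split$test), subject = s, .before = 1)
    })
    readr::write_tsv(rows, file.path(outdir, "accuracy.tsv"),
                     progress = FALSE)
    log_stage(log_path, "evaluate",
              sprintf("mean_rho=%.1f", mean(rows$rho)))
  }

  if ("cross_subject" %in% stages && isTRUE(config$cross_subject)) {
    nets <- lapply(subjects, function(s)
      read_mlp(need(sp(s, "_model.json"), "train")))
    helds <- lapply(subjects, function(s) load_split(s)$test)
    names(nets) <- names(helds) <- as.character(subjects)
    xmat <- cross_subject_matrix(nets, helds)
    readr::write_tsv(as_tibble(xmat), file.path(outdir, "cross_subject.tsv"),
                     progress = FALSE)
    off <- xmat$rho[xmat$h != xmat$r]
    log_stage(log_path, "cross_subject",
              sprintf("mean_offdiag=%.1f", if (length(off)) mean(off) else NA))
  }

  if ("wavelet" %in% stages) {
    sc <- config$spectral
    rows <- purrr::map_dfr(subjects, function(s) {
      rec <- read_edf(need(sp(s, ".edf"), "simulate"))
      ev <- read_events(need(sp(s, "_events.tsv"), "simulate"))
      if (isTRUE(config$eog)) rec <- remove_eog(rec)
      epochs <- extract_epochs(rec, ev, pre = sc$pre, post = sc$post)
      a_l <- averaged_spectrum(epochs, "L", sc$channels, sc$freqs)
      a_r <- averaged_spectrum(epochs, "R", sc$channels, sc$freqs)
      write_tfmap(a_l, sp(s, "_tf_L.tsv"))
      write_tfmap(a_r, sp(s, "_tf_R.tsv"))
      tibble(subject = s,
             delta_a = delta_a(a_l, a_r, normalize = sc$normalize),
             f1 = min(sc$freqs), f2 = max(sc$freqs),
             normalized = isTRUE(sc$normalize),
             n_l = a_l$n_averaged, n_r = a_r$n_averaged)
    })
    readr::write_tsv(rows, file.path(outdir, "delta_a.tsv"), progress = FALSE)
    log_stage(log_path, "wavelet", sprintf("subjects=%d", length(subjects)))
  }

  if ("erp" %in% stages) {
    rows <- purrr::map_dfr(subjects, function(s) {
      rec <- read_edf(need(sp(s, ".edf"), "simulate"))
      ev <- read_events(need(sp(s, "_events.tsv"), "simulate"))
      if (isTRUE(config$eog)) rec <- remove_eog(rec)
      trials <- extract_trials(rec, ev, config$duration)
      dd <- difference_trace(average_trials(trials, "L"),
                             average_trials(trials, "R"))
      write_erp(dd, sp(s, "_erp_diff.tsv"))
      mutate(component_windows(dd, config$erp_windows), subject = s,
             .before = 1)
    })
    readr::write_tsv(rows, file.path(outdir, "erp_windows.tsv"),
                     progress = FALSE)
    log_stage(log_path, "erp", sprintf("subjects=%d", length(subjects)))
  }

  files <- setdiff(list.files(outdir), c("run.log", "manifest.json"))
  manifest <- list(
    package = "neckereeg",
    version = as.character(utils::packageVersion("neckereeg")),
    seed = config$seed,
    stages = stages,
    config = unclass(config),
    files = lapply(stats::setNames(files, files), function(f)
      unname(tools::md5sum(file.path(outdir, f))))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
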