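#' Binary confusion matrix with delirium as the positive class
#'
#' @param true_labels,predicted_labels Equal-length vectors, either
#'   character (`"delirium"`/`"control"`) or 0/1 integers (1 = delirium).
#' @return Named integer vector `c(TP, FP, TN, FN)`.
#' @export
confusion_matrix <- function(true_labels, predicted_labels) {
  if (length(true_labels) != length(predicted_labels)) {
    stopf("label vectors differ in length (%d vs %d)",
          length(true_labels), length(predicted_labels))
  }
  y <- labels_to_int(true_labels)
  p <- labels_to_int(predicted_labels)
  if (!all(c(y, p) %in% c(0L, 1L))) stopf("labels must be binary (0/1)")
  c(TP = sum(y == 1 & p == 1), FP = sum(y == 0 & p == 1),
    TN = sum(y == 0 & p == 0), FN = sum(y == 1 & p == 0))
}

#' Experiment configuration
#'
#' Bundles every knob of an end-to-end run: cohort source, preprocessing,
#' the sweep axes (slice length, overlap, image domain, cleaning arm),
#' the model configuration and the split. Defaults mirror the reference
#' protocol: slice lengths {0.1, 0.5, 1, 1.6, 5} s, overlaps
#' {0.75, 0.9, 0.95} with 0.9 the reporting default, test fraction 0.25
#' of subjects, fixed 5 training epochs.
#'
#' @param cohort Either a list describing a synthetic cohort (fields
#'   `n_subjects`, `fraction_delirium`, `duration`, `seed`, optional
#'   `effect` multipliers for the delirium template, `gain_sdlog`,
#'   `noise_sd`) or `list(manifest = <path>)` for external data.
#' @param preprocess A [preprocess_config()].
#' @param slice_seconds Numeric vector of slice lengths (s).
#' @param overlap Numeric vector of overlap ratios.
#' @param domain Subset of `c("time", "frequency")`.
#' @param arm `"cleaned"`, `"uncleaned"` or `"both"`.
#' @param model A [vit_config()].
#' @param split_seed Seed of the subject-grouped split and balancing.
#' @param test_fraction Fraction of subjects held out.
#' @param max_slices_per_recording Per-recording cap; when a condition
#'   yields more windows they are thinned to an evenly spaced subset so
#'   every condition trains on a comparable number of examples.
#' @param outdir Optional output directory for reports and manifests.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(cohort = list(n_subjects = 12,
                                            fraction_delirium = 0.5,
                                            duration = 60, seed = 1),
                              preprocess = preprocess_config(),
                              slice_seconds = c(0.1, 0.5, 1, 1.6, 5),
                              overlap = c(0.75, 0.9, 0.95),
                              domain = "time",
                              arm = c("cleaned", "uncleaned", "both"),
                              model = vit_config_desk(),
                              split_seed = 1, test_fraction = 0.25,
                              max_slices_per_recording = 40,
                              outdir = NULL) {
  arm <- match.arg(arm)
  domain <- match.arg(domain, c("time", "frequency"), several.ok = TRUE)
  if (!length(slice_seconds) || !length(overlap)) {
    stopf("each sweep axis needs at least one value")
  }
  structure(list(cohort = cohort, preprocess = preprocess,
                 slice_seconds = slice_seconds, overlap = overlap,
                 domain = domain, arm = arm, model = model,
                 split_seed = split_seed, test_fraction = test_fraction,
                 max_slices_per_recording = max_slices_per_recording,
                 outdir = outdir),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML
#'
#' Top-level keys mirror the arguments of [experiment_config()]; the
#' `preprocess` and `model` sections map onto [preprocess_config()] and
#' [vit_config()] arguments.
#'
#' @param path YAML file.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y
  if (!is.null(y$preprocess)) args$preprocess <- do.call(preprocess_config, y$preprocess)
  if (!is.null(y$model)) args$model <- do.call(vit_config, y$model)
  if (!is.null(args$cohort$effect)) args$cohort$effect <- unlist(args$cohort$effect)
  do.call(experiment_config, args)
}

#' Materialise the cohort named by an experiment configuration
#'
#' @param cfg An [experiment_config()].
#' @return List of `eeg_recording`s.
#' @export
build_cohort <- function(cfg) {
  co <- cfg$cohort
  if (!is.null(co$manifest)) return(read_cohort(co$manifest))
  effect <- co$effect %||% c(delta = 2, theta = 2, alpha = 0.5)
  noise_sd <- co$noise_sd %||% 0.3
  background_sd <- co$background_sd %||% 1
  generate_cohort(
    n_subjects = co$n_subjects %||% 12,
    fraction_delirium = co$fraction_delirium %||% 0.5,
    templates = list(delirium = delirium_profile(effect, noise_sd = noise_sd,
                                                 background_sd = background_sd),
                     control = control_profile(noise_sd = noise_sd,
                                               background_sd = background_sd)),
    duration = co$duration %||% 60,
    seed = co$seed %||% 1,
    gain_sdlog = co$gain_sdlog %||% 0.2,
    mode = co$mode %||% "sinusoid",
    freq_jitter = co$freq_jitter %||% 0.2,
    env_sd = co$env_sd %||% 0,
    env_hz = co$env_hz %||% 1)
}

preprocess_cohort <- function(cohort, pre_cfg, arm, seed = 1) {
  lapply(cohort, preprocess_recording, cfg = pre_cfg, seed = seed, arm = arm)
}

thin_slices <- function(slices, cap) {
  if (is.null(cap) || length(slices) <= cap) return(slices)
  slices[unique(round(seq(1, length(slices), length.out = cap)))]
}

render_images <- function(slices, domain, side) {
  if (domain == "time") lapply(slices, slice_to_image, side = side)
  else lapply(slices, slice_to_spectral_image, side = side)
}

#' Run one experimental condition end-to-end
#'
#' Pipeline: slice every (already preprocessed) recording with the given
#' window length and overlap, thin to the per-recording cap, split by
#' subject, balance each side independently, render wave images in the
#' requested domain, train the transformer, and score the held-out
#' subjects.
#'
#' @param cohort List of preprocessed `eeg_recording`s.
#' @param cfg An [experiment_config()] (supplies model, split and cap).
#' @param slice_seconds,overlap,domain,arm The condition coordinates.
#' @return An `eval_report`: condition, confusion matrix (TP/FP/TN/FN),
#'   training and testing accuracy (slice-level), subject-level
#'   majority-vote accuracy (an extension, labelled as such), the
#'   per-epoch trace, seeds and split manifests.
#' @export
run_condition <- function(cohort, cfg, slice_seconds, overlap,
                          domain = "time", arm = "cleaned") {
  si <- cohort[[1]]$sampling_interval
  n_rows <- rows_for_duration(slice_seconds, si)
  slices <- unlist(lapply(cohort, function(rec) {
    thin_slices(make_slices(rec, n_rows, overlap),
                cfg$max_slices_per_recording)
  }), recursive = FALSE)
  split <- split_by_subject(slices, cfg$test_fraction, seed = cfg$split_seed)
  train_sl <- balance_classes(split$train_slices, seed = cfg$split_seed + 1L)
  test_sl <- balance_classes(split$test_slices, seed = cfg$split_seed + 2L)

  side <- cfg$model$image_side
  fit <- vit_train(render_images(train_sl, domain, side), cfg$model)
  pred <- vit_predict(fit, render_images(test_sl, domain, side))

  y_true <- labels_to_int(slice_labels(test_sl))
  cm <- confusion_matrix(y_true, pred$labels)
  test_acc <- (cm[["TP"]] + cm[["TN"]]) / sum(cm)

  subj <- slice_subjects(test_sl)
  subj_vote <- tapply(pred$labels, subj, function(v) as.integer(mean(v) > 0.5))
  subj_true <- tapply(y_true, subj, function(v) v[1])
  subj_acc <- mean(subj_vote == subj_true[names(subj_vote)])

  report <- list(
    condition = list(slice_seconds = slice_seconds, n_rows = n_rows,
                     overlap = overlap, domain = domain, arm = arm,
                     min_detectable_hz = min_detectable_frequency(slice_seconds)),
    confusion = cm,
    train_accuracy = utils::tail(fit$trace$train_accuracy, 1),
    test_accuracy = test_acc,
    subject_majority_accuracy = subj_acc,   # extension beyond slice level
    trace = fit$trace,
    n_train_slices = length(train_sl), n_test_slices = length(test_sl),
    seeds = list(split = cfg$split_seed, model = cfg$model$seed,
                 cohort = cfg$cohort$seed %||% NA),
    manifests = list(train = slice_manifest(train_sl, "train"),
                     test = slice_manifest(test_sl, "test")))
  class(report) <- "eval_report"
  report
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> %gs x %d rows, overlap %.0f%%, %s domain, %s arm\n",
    x$condition$slice_seconds, x$condition$n_rows, 100 * x$condition$overlap,
    x$condition$domain, x$condition$arm))
  cat(sprintf("  train %.2f%%  test %.2f%%  (TP %d FP %d TN %d FN %d)\n",
              100 * x$train_accuracy, 100 * x$test_accuracy,
              x$confusion[["TP"]], x$confusion[["FP"]],
              x$confusion[["TN"]], x$confusion[["FN"]]))
  invisible(x)
}

default_study_cohort <- function(seed, n_subjects = 12, duration = 60,
                                 effect = c(delta = 2)) {
  list(n_subjects = n_subjects, fraction_delirium = 0.5, duration = duration,
       seed = seed, effect = effect)
}

#' Frequency-coverage study: accuracy versus slice length
#'
#' The headline experiment: a synthetic cohort whose classes differ only in
#' delta-band amplitude is classified from time-domain wave images at
#' several slice lengths. Windows shorter than a delta cycle (f = 1/T)
#' cannot contain the discriminative rhythm, so accuracy should sit at
#' chance for 0.1 s slices and rise towards 1 as the slice grows past one
#' delta period. Each seed generates a fresh cohort and split.
#'
#' @param seeds Integer vector; one replicate per seed.
#' @param slice_seconds Slice lengths to profile (default 0.1/0.5/1/5 s).
#' @param overlap Overlap ratio (default 0.9, the reporting default).
#' @param n_subjects,duration Cohort shape per replicate.
#' @param effect Delirium-template band multipliers (default delta-only x2).
#' @param model [vit_config()] template; its seed is replaced per replicate.
#' @param max_slices_per_recording Per-recording window cap.
#' @return data.frame with one row per (seed, slice length): accuracies,
#'   test-set size, and the minimum detectable frequency of the window.
#' @export
frequency_coverage_experiment <- function(seeds = 1:5,
                                          slice_seconds = c(0.1, 0.5, 1, 5),
                                          overlap = 0.9, n_subjects = 12,
                                          duration = 60,
                                          effect = c(delta = 2),
                                          model = vit_config_desk(),
                                          max_slices_per_recording = 40) {
  rows <- list()
  for (sd_i in seeds) {
    cfg <- experiment_config(
      cohort = default_study_cohort(sd_i, n_subjects, duration, effect),
      preprocess = preprocess_config(ica_enabled = FALSE),
      model = utils::modifyList(model, list(seed = sd_i)),
      split_seed = sd_i,
      max_slices_per_recording = max_slices_per_recording)
    class(cfg$model) <- "vit_config"
    cohort <- build_cohort(cfg)
    pre <- preprocess_cohort(cohort, cfg$preprocess, arm = "uncleaned",
                             seed = sd_i)
    for (ss in slice_seconds) {
      rep <- run_condition(pre, cfg, ss, overlap, "time", "uncleaned")
      rows[[length(rows) + 1L]] <- data.frame(
        seed = sd_i, slice_seconds = ss, n_rows = rep$condition$n_rows,
        min_detectable_hz = rep$condition$min_detectable_hz,
        train_accuracy = rep$train_accuracy,
        test_accuracy = rep$test_accuracy,
        n_test_slices = rep$n_test_slices)
    }
  }
  do.call(rbind, rows)
}

#' Time- versus frequency-domain contrast
#'
#' Trains the same transformer on time-domain and on spectral wave images
#' of identical shape at 5 s slices with 50% overlap for 4 epochs, one
#' paired comparison per seed.
#'
#' @inheritParams frequency_coverage_experiment
#' @param slice_seconds Slice length (default 5 s).
#' @param overlap Overlap ratio (default 0.5).
#' @param epochs Training epochs (default 4).
#' @return data.frame with per-seed time/frequency test accuracies and
#'   their difference.
#' @export
domain_contrast_experiment <- function(seeds = 1:5, slice_seconds = 5,
                                       overlap = 0.5, epochs = 4,
                                       n_subjects = 12, duration = 60,
                                       effect = c(delta = 2),
                                       model = vit_config_desk(),
                                       max_slices_per_recording = 40) {
  rows <- list()
  for (sd_i in seeds) {
    cfg <- experiment_config(
      cohort = default_study_cohort(sd_i, n_subjects, duration, effect),
      preprocess = preprocess_config(ica_enabled = FALSE),
      model = utils::modifyList(model, list(seed = sd_i, epochs = epochs)),
      split_seed = sd_i,
      max_slices_per_recording = max_slices_per_recording)
    class(cfg$model) <- "vit_config"
    cohort <- build_cohort(cfg)
    pre <- preprocess_cohort(cohort, cfg$preprocess, arm = "uncleaned",
                             seed = sd_i)
    acc <- vapply(c("time", "frequency"), function(dm) {
      run_condition(pre, cfg, slice_seconds, overlap, dm,
                    "uncleaned")$test_accuracy
    }, 0)
    rows[[length(rows) + 1L]] <- data.frame(
      seed = sd_i, time_accuracy = acc[["time"]],
      frequency_accuracy = acc[["frequency"]],
      time_minus_frequency = acc[["time"]] - acc[["frequency"]])
  }
  do.call(rbind, rows)
}

#' Run the full sweep over slice lengths, overlaps, domains and arms
#'
#' Builds the cohort once, preprocesses it once per cleaning arm, then
#' executes every combination of the configured axes. Failures in one
#' condition are caught and reported; the sweep continues. When both
#' image domains are configured, a paired time-versus-frequency
#' comparison table is attached.
#'
#' @param cfg An [experiment_config()].
#' @return List with `reports` (list of `eval_report` or condition-tagged
#'   errors), `summary` (one row per condition, accuracies in percent)
#'   and, when applicable, `domain_contrast`. Written to `cfg$outdir` as
#'   CSV/JSON when set.
#' @export
run_sweep <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  cohort <- build_cohort(cfg)
  arms <- if (cfg$arm == "both") c("cleaned", "uncleaned") else cfg$arm
  pre <- lapply(stats::setNames(arms, arms), function(a) {
    preprocess_cohort(cohort, cfg$preprocess, arm = a, seed = cfg$split_seed)
  })
  grid <- expand.grid(slice_seconds = cfg$slice_seconds, overlap = cfg$overlap,
                      domain = cfg$domain, arm = arms,
                      stringsAsFactors = FALSE)
  reports <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    reports[[i]] <- tryCatch(
      run_condition(pre[[g$arm]], cfg, g$slice_seconds, g$overlap,
                    g$domain, g$arm),
      error = function(e) {
        structure(list(condition = as.list(g), error = conditionMessage(e)),
                  class = "eval_error")
      })
    r <- reports[[i]]
    rows[[i]] <- if (inherits(r, "eval_error")) {
      data.frame(g, n_rows = NA, train_accuracy_pct = NA,
                 test_accuracy_pct = NA, error = r$error)
    } else {
      data.frame(g, n_rows = r$condition$n_rows,
                 train_accuracy_pct = 100 * r$train_accuracy,
                 test_accuracy_pct = 100 * r$test_accuracy,
                 error = NA_character_)
    }
  }
  summary <- do.call(rbind, rows)
  out <- list(reports = reports, summary = summary)

  if (all(c("time", "frequency") %in% cfg$domain)) {
    ok <- !vapply(reports, inherits, TRUE, "eval_error")
    tab <- summary[ok, ]
    wide <- merge(
      tab[tab$domain == "time",
          c("slice_seconds", "overlap", "arm", "test_accuracy_pct")],
      tab[tab$domain == "frequency",
          c("slice_seconds", "overlap", "arm", "test_accuracy_pct")],
      by = c("slice_seconds", "overlap", "arm"),
      suffixes = c("_time", "_frequency"))
    wide$time_minus_frequency <- wide$test_accuracy_pct_time -
      wide$test_accuracy_pct_frequency
    out$domain_contrast <- wide
  }

  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(summary, file.path(cfg$outdir, "sweep_summary.csv"),
                     row.names = FALSE)
    for (i in seq_along(reports)) {
      r <- reports[[i]]
      if (inherits(r, "eval_error")) next
      base <- sprintf("condition_%02d", i)
      jsonlite::write_json(
        list(condition = r$condition, confusion = as.list(r$confusion),
             train_accuracy = r$train_accuracy,
             test_accuracy = r$test_accuracy,
             subject_majority_accuracy = r$subject_majority_accuracy,
             trace = r$trace, seeds = r$seeds),
        file.path(cfg$outdir, paste0(base, ".json")),
        auto_unbox = TRUE, digits = NA)
      utils::write.csv(rbind(r$manifests$train, r$manifests$test),
                       file.path(cfg$outdir, paste0(base, "_manifest.csv")),
                       row.names = FALSE)
    }
    if (!is.null(out$domain_contrast)) {
      utils::write.csv(out$domain_contrast,
                       file.path(cfg$outdir, "domain_contrast.csv"),
                       row.names = FALSE)
    }
  }
  out
}
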