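#' Detect and describe candidate events in one wave
#'
#' Runs the full candidate stage on a single trace: deconvolution against
#' the template, detector noise estimation, thresholding, window
#' extraction, Pearson correlation, and the ten-feature description.
#'
#' @inheritParams trace_duration
#' @param template A [build_kernel()] template.
#' @param mode,k Detection threshold (see [find_candidates()]); default
#'   3 standard deviations of the detector noise.
#' @param band Detector band in Hz (see [deconvolve()]).
#' @return List: `candidates` (data frame), `events` (list of `psc_event`
#'   with features), `features` (data frame), `detector` (with `sigma`).
#' @export
detect_events <- function(trace, template, mode = "sd_multiple", k = 3,
                          band = c(1, 200)) {
  det <- deconvolve(trace, template, band = band)
  n_unmasked <- length(det$values) -
    length(excluded_sample_idx(length(det$values), det$fs, det$excluded))
  if (n_unmasked < 1000) {
    # (near-)fully masked wave: nothing to detect
    empty <- data.frame(onset_index = integer(0), onset_time = numeric(0),
                        detector_peak = numeric(0))
    return(list(candidates = empty, events = list(), features = NULL,
                detector = det))
  }
  det <- estimate_noise_sd(det)
  cand <- find_candidates(det, mode = mode, k = k)
  events <- lapply(seq_len(nrow(cand)), function(i) {
    ev <- extract_event(trace, cand$onset_index[i], template,
                        detector_peak = cand$detector_peak[i])
    compute_features(ev, template)
  })
  list(candidates = cand, events = events,
       features = if (length(events)) feature_matrix(events) else NULL,
       detector = det)
}

#' Label candidates from simulated ground truth
#'
#' The oracle label of a candidate is whether it matches a true simulated
#' onset under one-to-one matching within the tolerance — the programmatic
#' stand-in for expert manual labelling when training on simulated data.
#'
#' @param candidate_times Candidate onset times (s).
#' @param reference_times Ground-truth onset times (s).
#' @param tol Matching tolerance in seconds.
#' @return Logical vector parallel to `candidate_times`.
#' @export
oracle_labels <- function(candidate_times, reference_times, tol = 1.2e-3) {
  m <- match_events(candidate_times, reference_times, tol)
  seq_along(candidate_times) %in% m$pairs$detected_idx
}

#' Run detection and classification over waves, writing results to disk
#'
#' The batch entry point: reads (or accepts) one or more waves, optionally
#' splits and masks them, detects candidates, applies the configured
#' criterion (Pearson threshold, trained model, or none), and writes per
#' wave an event table CSV and an ensemble-average waveform CSV, plus a
#' settings echo JSON sufficient to replay the run exactly.
#'
#' @param traces A `psc_trace` or list of them.
#' @param config List of settings: `template` (`c(tau_rise, tau_decay)` ms),
#'   `band`, `threshold_mode`, `threshold_k`, `criterion` (one of
#'   `"none"`, `"pearson"`, `"model"`), `r_threshold`, `model_path`,
#'   `epoch_s` (optional split), `exclusions` (optional list of intervals),
#'   `tol`.
#' @param output_dir Directory for outputs (created if needed).
#' @return Invisibly, a list with per-wave results (`candidates`,
#'   `accepted`) and the paths written.
#' @export
run_detect <- function(traces, config, output_dir) {
  if (inherits(traces, "psc_trace")) traces <- list(traces)
  cfg <- run_config(config)
  if (cfg$criterion == "model") {
    model <- load_model(cfg$model_path)  # fail before any computation
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(cfg$epoch_s)) {
    traces <- unlist(lapply(traces, split_trace, epoch_s = cfg$epoch_s),
                     recursive = FALSE)
  }
  if (length(cfg$exclusions)) {
    traces <- lapply(traces, apply_exclusions, intervals = cfg$exclusions)
  }
  template <- build_kernel(cfg$template[1], cfg$template[2],
                           traces[[1]]$fs)
  results <- vector("list", length(traces))
  for (w in seq_along(traces)) {
    res <- tryCatch(
      detect_events(traces[[w]], template, mode = cfg$threshold_mode,
                    k = cfg$threshold_k, band = cfg$band),
      error = function(e) stop("wave ", w, ": ", conditionMessage(e)))
    accepted <- if (!length(res$events)) logical(0) else switch(cfg$criterion,
      none = rep(TRUE, length(res$events)),
      pearson = screen_pearson(res$events, cfg$r_threshold)$accepted,
      model = classify_events(res$events, model))
    tab <- cbind(res$candidates,
                 pearson_r = vapply(res$events, `[[`, 0, "pearson_r"),
                 accepted = accepted)
    write.csv(tab, file.path(output_dir, sprintf("wave%03d_events.csv", w)),
              row.names = FALSE)
    acc_events <- res$events[accepted]
    if (length(acc_events)) {
      len <- min(lengths(lapply(acc_events, `[[`, "window")))
      ens <- rowMeans(vapply(acc_events,
                             function(e) e$window[seq_len(len)],
                             numeric(len)))
      write.csv(data.frame(time_ms = (seq_len(len) - 1L -
                             acc_events[[1]]$pre_samples) * 1000 /
                             traces[[w]]$fs,
                           mean_pA = ens),
                file.path(output_dir, sprintf("wave%03d_ensemble.csv", w)),
                row.names = FALSE)
    }
    results[[w]] <- list(candidates = tab, accepted = accepted)
  }
  jsonlite::write_json(cfg[!vapply(cfg, is.null, TRUE)],
                       file.path(output_dir, "settings.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(waves = results, output_dir = output_dir))
}

run_config <- function(config) {
  cfg <- list(template = c(0.44, 6.12), band = c(1, 200),
              threshold_mode = "sd_multiple", threshold_k = 3,
              criterion = "none", r_threshold = 0.5, model_path = NULL,
              epoch_s = NULL, exclusions = list(), tol = 1.2e-3)
  cfg[names(config)] <- config
  if (!cfg$criterion %in% c("none", "pearson", "model")) {
    stop("criterion must be one of none / pearson / model")
  }
  if (cfg$criterion == "model" &&
      (is.null(cfg$model_path) || !file.exists(cfg$model_path))) {
    stop("criterion 'model' requires an existing model_path")
  }
  cfg
}

#' Train a model from a wave and a label table
#'
#' Detects candidates in the training wave, joins the supplied labels by
#' onset time, trains the forest, and writes the `.evtm` model file. Every
#' candidate must be labelled; unlabelled onsets are reported in the error.
#'
#' @param trace Training wave (`psc_trace`).
#' @param labels Data frame with columns `onset_time` (s) and `label`
#'   (logical), covering all detected candidates, or a logical vector
#'   parallel to the candidates.
#' @param config As in [run_detect()]; plus `n_trees` and `seed`.
#' @param model_path Output path for the model file.
#' @return Invisibly, the trained `psc_model` (OOB error in `$oob_error`).
#' @export
run_train <- function(trace, labels, config, model_path) {
  cfg <- run_config(config)
  n_trees <- if (is.null(config$n_trees)) 400 else config$n_trees
  seed <- if (is.null(config$seed)) 1 else config$seed
  template <- build_kernel(cfg$template[1], cfg$template[2], trace$fs)
  res <- detect_events(trace, template, mode = cfg$threshold_mode,
                       k = cfg$threshold_k, band = cfg$band)
  if (is.data.frame(labels)) {
    idx <- vapply(res$candidates$onset_time, function(t0) {
      hit <- which(abs(labels$onset_time - t0) <= cfg$tol)
      if (length(hit)) hit[1] else NA_integer_
    }, integer(1))
    if (anyNA(idx)) {
      stop("unlabelled candidate onsets (s): ",
           paste(format(res$candidates$onset_time[is.na(idx)], digits = 6),
                 collapse = ", "))
    }
    lab <- as.logical(labels$label[idx])
  } else {
    if (length(labels) != nrow(res$candidates)) {
      stop("label vector does not match the number of candidates")
    }
    lab <- as.logical(labels)
  }
  model <- train_forest(res$events, lab, n_trees = n_trees, seed = seed,
                        template = template,
                        detection_threshold = list(mode = cfg$threshold_mode,
                                                   k = cfg$threshold_k))
  save_model(model, model_path)
  invisible(model)
}

#' Scaled emulation of the accuracy study
#'
#' Simulates independent training and test waves under the reference
#' data-generating process (log-normal amplitude and kinetics, 40 events
#' per 9.9-s wave at 40 kHz) on Gaussian white noise, detects candidates at
#' `k` detector-noise SDs with the standard template, trains one forest per
#' training wave on oracle-labelled candidates, classifies each test wave
#' with a different model, and scores every criterion against the simulated
#' ground truth by onset matching.
#'
#' @param seed Master seed; wave seeds and forest seeds derive from it.
#' @param n_train,n_test Number of training / test waves (default 4 + 4).
#' @param n_events Events per wave (default 40).
#' @param duration,fs Wave geometry (default 9.9 s at 40 kHz).
#' @param noise_rms White-noise RMS in pA (default 2.43, the measured RMS
#'   of the reference recording noise this simulation stands in for).
#' @param template_constants `c(tau_rise, tau_decay)` ms of the detection
#'   template (default `c(0.44, 6.12)`).
#' @param k Detection threshold in noise SDs (default 3).
#' @param band Detector band (default 1–200 Hz).
#' @param r_threshold Pearson screening threshold (default 0.5).
#' @param tol Onset matching tolerance in s (default 1.2 ms).
#' @param n_trees Trees per forest (default 400).
#' @return List with per-test-wave vectors `accuracy_ml`,
#'   `accuracy_pearson`, `accuracy_none`, per-training-wave `oob_error` and
#'   `n_candidates_train`, `n_true_train`, and the per-wave confusion
#'   counts in `details`.
#' @export
run_accuracy_emulation <- function(seed = 1, n_train = 4, n_test = 4,
                                   n_events = 40, duration = 9.9,
                                   fs = 40000, noise_rms = 2.43,
                                   template_constants = c(0.44, 6.12),
                                   k = 3, band = c(1, 200),
                                   r_threshold = 0.5, tol = 1.2e-3,
                                   n_trees = 400) {
  template <- build_kernel(template_constants[1], template_constants[2], fs)
  wave_seed <- function(i) (seed * 131L + i * 17L) %% .Machine$integer.max
  make_wave <- function(i) {
    synthesize(simulation_spec(n_events = n_events, duration = duration,
                               fs = fs, noise_rms = noise_rms,
                               seed = wave_seed(i)))
  }
  models <- vector("list", n_train)
  oob <- n_cand_train <- n_true_train <- numeric(n_train)
  for (i in seq_len(n_train)) {
    sim <- make_wave(i)
    res <- detect_events(sim$trace, template, k = k, band = band)
    lab <- oracle_labels(res$candidates$onset_time, sim$truth$onset_time,
                         tol)
    models[[i]] <- train_forest(res$events, lab, n_trees = n_trees,
                                seed = wave_seed(i) + 1L,
                                template = template)
    oob[i] <- models[[i]]$oob_error
    n_cand_train[i] <- nrow(res$candidates)
    n_true_train[i] <- sum(lab)
  }
  acc_ml <- acc_pearson <- acc_none <- numeric(n_test)
  details <- vector("list", n_test)
  for (j in seq_len(n_test)) {
    sim <- make_wave(n_train + j)
    res <- detect_events(sim$trace, template, k = k, band = band)
    times <- res$candidates$onset_time
    truth <- sim$truth$onset_time
    model <- models[[(j - 1L) %% n_train + 1L]]
    acc <- classify_events(res$events, model)
    cc_ml <- confusion_counts(times, times[acc], truth, tol)
    scr <- screen_pearson(res$events, r_threshold)
    cc_p <- confusion_counts(times, times[scr$accepted], truth, tol)
    cc_n <- confusion_counts(times, times, truth, tol)
    acc_ml[j] <- roc_metrics(cc_ml)[["accuracy"]]
    acc_pearson[j] <- roc_metrics(cc_p)[["accuracy"]]
    acc_none[j] <- suppressWarnings(roc_metrics(cc_n)[["accuracy"]])
    details[[j]] <- list(ml = cc_ml, pearson = cc_p, none = cc_n,
                         n_candidates = length(times))
  }
  list(accuracy_ml = acc_ml, accuracy_pearson = acc_pearson,
       accuracy_none = acc_none, oob_error = oob,
       n_candidates_train = n_cand_train, n_true_train = n_true_train,
       details = details)
}
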