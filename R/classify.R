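#' Screen candidate events by Pearson correlation
#'
#' Partitions candidates into accepted (`r >= r_threshold`) and rejected.
#' A threshold of -1 accepts every candidate (screening switched off); a
#' threshold of +1 accepts only exact template shapes.
#'
#' @param events List of `psc_event` objects with `pearson_r` computed.
#' @param r_threshold Correlation threshold in `[-1, 1]`.
#' @return List with logical vector `accepted` (parallel to `events`) plus
#'   the partitioned lists `accepted_events`, `rejected_events`.
#' @export
screen_pearson <- function(events, r_threshold) {
  if (!is.numeric(r_threshold) || length(r_threshold) != 1L ||
      r_threshold < -1 || r_threshold > 1) {
    stop("`r_threshold` must be a single value in [-1, 1]")
  }
  r <- vapply(events, function(e) {
    if (is.na(e$pearson_r)) stop("pearson_r not computed for all events")
    e$pearson_r
  }, numeric(1))
  acc <- r >= r_threshold
  list(accepted = acc,
       accepted_events = events[acc],
       rejected_events = events[!acc])
}

#' Train a random-forest event classifier
#'
#' Grows a bagged ensemble of decision trees: each tree sees a bootstrap
#' resample of the labelled candidates and considers a random subset of
#' features at every split (Gini impurity, unlimited depth). The out-of-bag
#' (OOB) error — the misclassification rate of each example under the votes
#' of the trees that did not see it — estimates the prediction error without
#' a held-out set. Training is deterministic given `seed`.
#'
#' @param events List of `psc_event` objects with features computed, or a
#'   feature data frame from [feature_matrix()].
#' @param labels Logical vector (`TRUE` = real event), one per candidate.
#' @param n_trees Number of trees (default 400).
#' @param features_per_split Features tried at each split (default
#'   `ceiling(sqrt(10))` = 4).
#' @param seed Integer seed for the bootstrap/feature-sampling streams.
#' @param template Optional `psc_template` whose constants are stored in the
#'   model metadata.
#' @param detection_threshold Optional `(mode, k)` detection setting stored
#'   in the metadata.
#' @return An object of class `psc_model`: `forest`, `n_trees`,
#'   `feature_names`, `feature_version`, `oob_error`, `template_constants`,
#'   `detection_threshold`, `created`, `training_summary`.
#' @export
train_forest <- function(events, labels, n_trees = 400,
                         features_per_split = ceiling(sqrt(10)), seed = 1,
                         template = NULL, detection_threshold = NULL) {
  x <- if (is.data.frame(events)) events else feature_matrix(events)
  if (nrow(x) != length(labels)) stop("labels do not match events in length")
  if (!identical(names(x), PSC_FEATURE_NAMES)) {
    stop("feature columns do not match the canonical feature set")
  }
  labels <- as.logical(labels)
  tab <- table(factor(labels, levels = c(FALSE, TRUE)))
  if (any(tab < 2L)) {
    stop("need at least 2 labelled examples in each class")
  }
  y <- factor(labels, levels = c(FALSE, TRUE))
  forest <- withr::with_seed(seed,
    randomForest::randomForest(x = x, y = y, ntree = n_trees,
                               mtry = features_per_split))
  oob <- unname(forest$err.rate[n_trees, "OOB"])
  structure(
    list(forest = forest, n_trees = n_trees,
         feature_names = PSC_FEATURE_NAMES,
         feature_version = PSC_FEATURE_VERSION,
         oob_error = oob,
         template_constants = if (is.null(template)) c(NA_real_, NA_real_)
           else c(template$tau_rise, template$tau_decay),
         detection_threshold = detection_threshold,
         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         training_summary = c(n_false = unname(tab[1]),
                              n_true = unname(tab[2]))),
    class = "psc_model"
  )
}

#' @export
print.psc_model <- function(x, ...) {
  cat(sprintf(
    "<psc_model> %d trees, OOB error %.3g, trained on %d true / %d false\n",
    x$n_trees, x$oob_error, x$training_summary[["n_true"]],
    x$training_summary[["n_false"]]))
  if (!anyNA(x$template_constants)) {
    cat(sprintf("  template: tau_rise %.3g ms, tau_decay %.3g ms\n",
                x$template_constants[1], x$template_constants[2]))
  }
  invisible(x)
}

#' Classify candidate events with a trained model
#'
#' Majority vote over the forest; an exact tie (possible with an even number
#' of trees) resolves to `FALSE`, i.e. the candidate is rejected —
#' conservative toward suppressing false positives.
#'
#' @param events List of `psc_event` objects with features, or a feature
#'   data frame.
#' @param model A `psc_model`.
#' @return Logical vector of predicted labels (`TRUE` = accepted as a real
#'   event).
#' @export
classify_events <- function(events, model) {
  stopifnot(inherits(model, "psc_model"))
  x <- if (is.data.frame(events)) events else feature_matrix(events)
  if (!identical(names(x), model$feature_names)) {
    stop("feature names do not match the model's feature version")
  }
  votes <- predict(model$forest, newdata = x, type = "vote")
  votes[, "TRUE"] > 0.5
}

#' Save / load a trained model
#'
#' The `.evtm` model file is a self-describing archive of the forest plus
#' metadata (feature version and names, template constants, detection
#' threshold, training summary), portable across machines running this
#' package. Loading validates the feature version so a model is never
#' applied to features it was not trained on.
#'
#' @param model A `psc_model`.
#' @param path File path (conventionally `*.evtm`).
#' @return `load_model` returns the restored `psc_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "psc_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  model <- try(readRDS(path), silent = TRUE)
  if (inherits(model, "try-error") || !inherits(model, "psc_model")) {
    stop("corrupt or incompatible model file: ", path)
  }
  if (length(model$feature_names) != 10L ||
      !identical(model$feature_version, PSC_FEATURE_VERSION)) {
    stop("model feature version mismatch: expected ", PSC_FEATURE_VERSION)
  }
  model
}
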