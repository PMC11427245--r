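#' Extract a baseline-subtracted candidate-event window
#'
#' The window spans 1 ms before the candidate onset to the end of the
#' template (`duration_ms` after onset). The baseline is the mean of the
#' 1 ms pre-onset segment and is subtracted from the window; if the onset is
#' too close to the start of the trace for a full pre-onset segment, the
#' baseline falls back to the first 0.25 ms of the window and the event is
#' flagged `truncated`. Windows running past the end of the trace are
#' likewise truncated and flagged.
#'
#' @inheritParams trace_duration
#' @param onset_index 1-based sample index of the candidate onset.
#' @param template The detection template ([build_kernel()]).
#' @param detector_peak Detector-trace height at the candidate (carried into
#'   the feature vector; default `NA`).
#' @return An object of class `psc_event`: `onset_index`, `onset_time`,
#'   `window` (baseline-subtracted, pA), `pre_samples` (number of pre-onset
#'   samples included), `baseline`, `baseline_sd`, `truncated`,
#'   `detector_peak`, plus `pearson_r` and `features` slots filled by
#'   [pearson_vs_template()] and [compute_features()].
#' @export
extract_event <- function(trace, onset_index, template, detector_peak = NA) {
  stopifnot(inherits(trace, "psc_trace"), inherits(template, "psc_template"))
  n <- length(trace$samples)
  onset_index <- as.integer(onset_index)
  if (onset_index < 1L || onset_index > n) stop("onset outside trace")
  fs <- trace$fs
  pre_n <- as.integer(round(1e-3 * fs))
  post_n <- length(template$kernel)
  i0 <- onset_index - pre_n
  i1 <- onset_index + post_n - 1L
  truncated <- i0 < 1L || i1 > n
  i0 <- max(1L, i0)
  i1 <- min(n, i1)
  w <- trace$samples[i0:i1]
  pre_samples <- onset_index - i0
  if (pre_samples >= 1L) {
    base_seg <- w[seq_len(pre_samples)]
  } else {
    # no pre-onset data: fall back to the first 0.25 ms of the window
    base_seg <- w[seq_len(max(1L, round(0.25e-3 * fs)))]
  }
  baseline <- mean(base_seg)
  structure(
    list(onset_index = onset_index, onset_time = (onset_index - 1L) / fs,
         window = w - baseline, pre_samples = pre_samples,
         baseline = baseline, baseline_sd = sd(base_seg),
         truncated = truncated, detector_peak = detector_peak, fs = fs,
         pearson_r = NA_real_, features = NULL, label = NA),
    class = "psc_event"
  )
}

#' @export
print.psc_event <- function(x, ...) {
  cat(sprintf("<psc_event> onset %.5g s, %d samples, baseline %.4g%s\n",
              x$onset_time, length(x$window), x$baseline,
              if (x$truncated) " (truncated)" else ""))
  invisible(x)
}

# Post-onset portion of the event window and the aligned template samples.
aligned_event_template <- function(event, template) {
  w <- event$window[(event$pre_samples + 1L):length(event$window)]
  k <- template$kernel[seq_along(w)]
  list(w = w, k = k)
}

#' Pearson correlation of an event against the template
#'
#' Standard product-moment correlation between the post-onset span of the
#' baseline-subtracted event window and the template kernel sampled over the
#' same span. By affine invariance, any event of the exact template shape
#' scores `r = 1` regardless of amplitude or offset.
#'
#' @param event A `psc_event`.
#' @param template The template the event was detected with.
#' @return The event with `pearson_r` filled in (in `[-1, 1]`).
#' @export
pearson_vs_template <- function(event, template) {
  stopifnot(inherits(event, "psc_event"), inherits(template, "psc_template"))
  al <- aligned_event_template(event, template)
  if (sd(al$w) == 0) stop("zero-variance event window")
  event$pearson_r <- cor(al$w, al$k)
  event
}

#' Compute the ten-feature description of a candidate event
#'
#' The classifier sees each candidate as a fixed, ordered vector of ten
#' features spanning amplitude, kinetics, template match, and noise context:
#' \enumerate{
#'   \item `amplitude` — peak of the baseline-subtracted window (pA);
#'   \item `rise_time_10_90` — 10–90% rise time (ms, linear interpolation);
#'   \item `half_width` — width at half amplitude (ms);
#'   \item `decay_tau` — decay time constant (ms) from a log-linear
#'     least-squares fit of the decay phase (peak down to 5% of peak), with
#'     the time-to-1/e as fallback for short or noisy decays;
#'   \item `area` — integral of the baseline-subtracted window (pA ms);
#'   \item `pearson_r` — correlation against the template;
#'   \item `baseline_sd` — SD of the pre-onset baseline segment (pA);
#'   \item `time_to_peak` — onset-to-peak latency (ms);
#'   \item `skewness` — sample skewness of the window;
#'   \item `detector_peak` — height of the deconvolution peak that proposed
#'     the candidate.
#' }
#' The order is fixed, named by `colnames`, and versioned inside model files
#' so a model is only applied to the feature set it was trained on.
#' Degenerate measurements (e.g. skewness of an all-zero window) are coded
#' 0 so the vector is always finite.
#'
#' @inheritParams pearson_vs_template
#' @return The event with a named 10-element `features` vector.
#' @export
compute_features <- function(event, template) {
  stopifnot(inherits(event, "psc_event"))
  if (anyNA(event$window)) stop("NaN in event window")
  if (is.na(event$pearson_r)) event <- pearson_vs_template(event, template)
  al <- aligned_event_template(event, template)
  w <- al$w
  dt_ms <- 1000 / event$fs
  ipk <- which.max(w)
  a <- w[ipk]
  f <- c(
    amplitude = a,
    rise_time_10_90 = rise_time_10_90(w, ipk, dt_ms),
    half_width = half_width(w, ipk, dt_ms),
    decay_tau = decay_tau_fit(w, ipk, dt_ms),
    area = sum(event$window) * dt_ms,
    pearson_r = event$pearson_r,
    baseline_sd = event$baseline_sd,
    time_to_peak = (ipk - 1L) * dt_ms,
    skewness = e1071::skewness(w),
    detector_peak = event$detector_peak
  )
  f[!is.finite(f)] <- 0
  names(f) <- PSC_FEATURE_NAMES
  event$features <- f
  event
}

rise_time_10_90 <- function(w, ipk, dt_ms) {
  a <- w[ipk]
  if (a <= 0) return(0)
  t10 <- interp_cross_up(w, 0.1 * a, ipk)
  t90 <- interp_cross_up(w, 0.9 * a, ipk)
  if (is.na(t10) || is.na(t90)) return(0)
  (t90 - t10) * dt_ms
}

# Last upward crossing of `lev` before the peak, in fractional sample units.
interp_cross_up <- function(w, lev, ipk) {
  below <- which(w[seq_len(ipk)] < lev)
  if (!length(below)) return(0)
  i <- max(below)
  if (i == ipk) return(NA_real_)
  frac <- (lev - w[i]) / (w[i + 1L] - w[i])
  (i - 1) + frac
}

# First downward crossing of `lev` after the peak, fractional sample units.
interp_cross_down <- function(w, lev, ipk) {
  after <- which(w[ipk:length(w)] < lev)
  if (!length(after)) return(NA_real_)
  i <- ipk + after[1] - 1L
  if (i == ipk) return(ipk - 1)
  frac <- (w[i - 1L] - lev) / (w[i - 1L] - w[i])
  (i - 2) + frac
}

half_width <- function(w, ipk, dt_ms) {
  a <- w[ipk]
  if (a <= 0) return(0)
  up <- interp_cross_up(w, a / 2, ipk)
  dn <- interp_cross_down(w, a / 2, ipk)
  if (is.na(up) || is.na(dn)) return(0)
  (dn - up) * dt_ms
}

decay_tau_fit <- function(w, ipk, dt_ms) {
  a <- w[ipk]
  if (a <= 0) return(0)
  seg <- w[ipk:length(w)]
  stop_i <- which(seg <= 0.05 * a)[1]
  if (!is.na(stop_i)) seg <- seg[seq_len(max(stop_i - 1L, 1L))]
  seg <- seg[seg > 0]
  if (length(seg) >= 3L) {
    t <- (seq_along(seg) - 1L) * dt_ms
    slope <- coef(lm(log(seg) ~ t))[[2]]
    if (is.finite(slope) && slope < 0) return(-1 / slope)
  }
  # fallback: time from peak to 1/e of peak
  i_e <- interp_cross_down(w, a / exp(1), ipk)
  if (is.na(i_e)) 0 else (i_e - (ipk - 1)) * dt_ms
}

#' Feature matrix for a list of events
#'
#' @param events List of `psc_event` objects with features computed.
#' @return Data frame, one row per event, columns in the canonical feature
#'   order.
#' @export
feature_matrix <- function(events) {
  rows <- lapply(events, function(e) {
    if (is.null(e$features)) stop("event has no features; run compute_features()")
    e$features
  })
  df <- as.data.frame(do.call(rbind, rows))
  names(df) <- PSC_FEATURE_NAMES
  df
}
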