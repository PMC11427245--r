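#' Build the peak-scaled biexponential event template
#'
#' The canonical synaptic waveform is the difference of two exponentials,
#' `k(t) = s * (exp(-t / tau_decay) - exp(-t / tau_rise))`, with the scale
#' `s` chosen so the sampled maximum equals 1 exactly ("peak scaling"): the
#' coefficient multiplying the kernel is then the event's peak amplitude.
#' The analytic peak time is
#' `t_peak = tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)`.
#'
#' @param tau_rise,tau_decay Rise and decay time constants in ms;
#'   `0 < tau_rise < tau_decay`.
#' @param fs Sampling rate in Hz.
#' @param duration_ms Kernel duration in ms. The default `8 * tau_decay`
#'   truncates less than 0.04% of the decay tail.
#' @return An object of class `psc_template` with fields `tau_rise`,
#'   `tau_decay` (ms), `fs`, `kernel` (peak 1, `kernel[1] = 0`),
#'   `duration_ms`, and `t_peak_ms`.
#' @export
#' @examples
#' tpl <- build_kernel(0.44, 6.12, fs = 40000)
#' max(tpl$kernel)     # 1
#' tpl$t_peak_ms
build_kernel <- function(tau_rise, tau_decay, fs,
                         duration_ms = 8 * tau_decay) {
  if (!is.numeric(tau_rise) || !is.numeric(tau_decay) ||
      tau_rise <= 0 || tau_decay <= 0) {
    stop("time constants must be positive")
  }
  if (tau_rise >= tau_decay) {
    stop("degenerate template: tau_rise must be < tau_decay")
  }
  if (duration_ms < 5 * tau_decay) {
    warning("kernel duration < 5 * tau_decay truncates a substantial tail")
  }
  t_ms <- seq(0, duration_ms, by = 1000 / fs)
  k <- exp(-t_ms / tau_decay) - exp(-t_ms / tau_rise)
  k <- k / max(k)
  structure(
    list(tau_rise = tau_rise, tau_decay = tau_decay, fs = fs, kernel = k,
         duration_ms = duration_ms,
         t_peak_ms = kernel_peak_time(tau_rise, tau_decay)),
    class = "psc_template"
  )
}

#' Analytic peak time of the biexponential kernel
#' @inheritParams build_kernel
#' @return Peak time in ms.
#' @export
kernel_peak_time <- function(tau_rise, tau_decay) {
  tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
}

#' @export
print.psc_template <- function(x, ...) {
  cat(sprintf(
    "<psc_template> tau_rise %.3g ms, tau_decay %.3g ms @ %g Hz (%d samples, peak at %.4g ms)\n",
    x$tau_rise, x$tau_decay, x$fs, length(x$kernel), x$t_peak_ms))
  invisible(x)
}

# Peak-scaled kernel values at arbitrary times (ms), analytic peak scaling.
kernel_values <- function(t_ms, tau_rise, tau_decay) {
  tp <- kernel_peak_time(tau_rise, tau_decay)
  peak <- exp(-tp / tau_decay) - exp(-tp / tau_rise)
  out <- (exp(-t_ms / tau_decay) - exp(-t_ms / tau_rise)) / peak
  out[t_ms < 0] <- 0
  out
}

#' Fit template time constants to an exemplar event
#'
#' Nonlinear least squares (Levenberg-Marquardt) fit of
#' `baseline + A * k(t - t0; tau_rise, tau_decay)` to a window of the trace
#' containing one rising-then-decaying deflection, with the onset offset
#' `t0` free. Initial values: `tau_rise` = 10% of the span from window start
#' to the observed peak, `tau_decay` = time from the peak to the 1/e decay
#' point.
#'
#' @inheritParams trace_duration
#' @param window `(start, end)` in seconds delimiting the exemplar.
#' @return List with `tau_rise`, `tau_decay` (ms), `amplitude`, `baseline`
#'   (trace units), and `onset_s`.
#' @export
fit_template <- function(trace, window) {
  stopifnot(inherits(trace, "psc_trace"), length(window) == 2L)
  fs <- trace$fs
  i0 <- max(1L, floor(window[1] * fs) + 1L)
  i1 <- min(length(trace$samples), ceiling(window[2] * fs))
  if (i1 - i0 + 1L < 10L) stop("fit window shorter than 10 samples")
  y <- trace$samples[i0:i1]
  t_ms <- (seq_along(y) - 1L) * 1000 / fs
  if (sd(y) == 0) stop("fit did not converge: flat window")
  ipk <- which.max(y - y[1])
  base0 <- median(y[seq_len(max(1L, ipk %/% 4L))])
  a0 <- y[ipk] - base0
  rise_span <- max(t_ms[ipk], 2000 / fs)
  tr0 <- 0.1 * rise_span
  dec <- y[ipk:length(y)] - base0
  i_e <- which(dec <= a0 / exp(1))[1]
  td0 <- if (is.na(i_e)) (t_ms[length(t_ms)] - t_ms[ipk]) / 2 else
    (i_e - 1L) * 1000 / fs
  td0 <- max(td0, 2 * tr0)
  fit <- try(minpack.lm::nlsLM(
    y ~ b + A * kernel_values(t_ms - t0, tr, td),
    start = list(b = base0, A = a0, t0 = max(0, t_ms[ipk] - td0), tr = tr0,
                 td = td0),
    lower = c(-Inf, 0, 0, 1e-4, 1e-3),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) stop("fit did not converge")
  cf <- coef(fit)
  tr_ms <- min(cf[["tr"]], cf[["td"]]); td_ms <- max(cf[["tr"]], cf[["td"]])
  list(tau_rise = tr_ms, tau_decay = td_ms, amplitude = cf[["A"]],
       baseline = cf[["b"]], onset_s = window[1] + cf[["t0"]] / 1000)
}

#' Serialise / restore a template as JSON
#'
#' @param template A `psc_template`.
#' @param path File path.
#' @return `read_template` returns a `psc_template` rebuilt from the stored
#'   constants.
#' @export
write_template <- function(template, path) {
  stopifnot(inherits(template, "psc_template"))
  jsonlite::write_json(
    list(tau_rise_ms = template$tau_rise, tau_decay_ms = template$tau_decay,
         fs_hz = template$fs, duration_ms = template$duration_ms),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_template
#' @export
read_template <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  build_kernel(m$tau_rise_ms, m$tau_decay_ms, m$fs_hz, m$duration_ms)
}
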