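#' Specify a ground-truth synaptic-event simulation
#'
#' The simulator emulates miniature postsynaptic current recordings: each
#' event's amplitude, rise time constant, and decay time constant are drawn
#' by exponential transformation of normal deviates (i.e. log-normally),
#' the decay redrawn until it exceeds the rise; the event's peak-scaled
#' biexponential kernel is placed at a uniformly drawn onset sample by FFT
#' circular convolution, scaled by the amplitude, and summed onto the noise.
#'
#' Defaults reproduce the reference data-generating process: 40 events over
#' 9.9 s at 40 kHz, log-parameter distributions `N(2.46, 0.35)` (amplitude,
#' pA), `N(-0.31, 0.60)` (rise, ms), `N(1.48, 0.46)` (decay, ms), no
#' spacing constraint, white noise.
#'
#' @param n_events Number of events (>= 0).
#' @param duration Recording duration in seconds.
#' @param fs Sampling rate in Hz.
#' @param amp_params,rise_params,decay_params `(mu, sigma)` of the log of
#'   each parameter (amplitude in pA, time constants in ms).
#' @param min_iei Minimum inter-event interval in ms, or `NULL` for none.
#' @param noise_rms RMS of the Gaussian white background noise in pA
#'   (ignored when `noise_trace` is given).
#' @param noise_trace Optional `psc_trace` to use as the background noise
#'   instead of white noise; must match `duration * fs` samples.
#' @param seed Integer seed; one stream consumed in the order
#'   amplitude, rise, decay (with redraws), onset for each event in turn.
#' @return An object of class `psc_simspec`.
#' @export
simulation_spec <- function(n_events = 40, duration = 9.9, fs = 40000,
                            amp_params = c(2.46, 0.35),
                            rise_params = c(-0.31, 0.60),
                            decay_params = c(1.48, 0.46),
                            min_iei = NULL, noise_rms = 2,
                            noise_trace = NULL, seed = 1) {
  stopifnot(n_events >= 0, duration > 0, fs > 0,
            amp_params[2] >= 0, rise_params[2] >= 0, decay_params[2] >= 0,
            is.null(noise_trace) || inherits(noise_trace, "psc_trace"))
  if (!is.null(min_iei) && min_iei > 0 &&
      n_events * min_iei / 1000 >= duration) {
    stop("infeasible packing: n_events * min_iei exceeds the duration")
  }
  structure(
    list(n_events = as.integer(n_events), duration = duration, fs = fs,
         amp_params = amp_params, rise_params = rise_params,
         decay_params = decay_params, min_iei = min_iei,
         noise_rms = noise_rms, noise_trace = noise_trace,
         seed = as.integer(seed)),
    class = "psc_simspec"
  )
}

# One event's parameters, consuming the current RNG stream in the order
# amplitude -> rise -> decay (redrawn until decay > rise, capped retries).
draw_event_params <- function(spec, max_retry = 1e4) {
  amp <- exp(rnorm(1, spec$amp_params[1], spec$amp_params[2]))
  tr <- exp(rnorm(1, spec$rise_params[1], spec$rise_params[2]))
  td <- exp(rnorm(1, spec$decay_params[1], spec$decay_params[2]))
  tries <- 0L
  while (td <= tr) {
    td <- exp(rnorm(1, spec$decay_params[1], spec$decay_params[2]))
    tries <- tries + 1L
    if (tries > max_retry) stop("decay resampling retry cap exceeded")
  }
  c(amplitude = amp, tau_rise = tr, tau_decay = td)
}

#' Sample event amplitude and kinetic parameters
#'
#' @param spec A [simulation_spec()].
#' @param n Number of events to draw (default `spec$n_events`).
#' @param seed Seed (default `spec$seed`); the global RNG state is left
#'   untouched.
#' @return Data frame with columns `amplitude` (pA), `tau_rise`, `tau_decay`
#'   (ms); every row satisfies `tau_decay > tau_rise`.
#' @export
sample_event_params <- function(spec, n = spec$n_events, seed = spec$seed) {
  withr::with_seed(seed, {
    out <- t(vapply(seq_len(n), function(i) draw_event_params(spec),
                    numeric(3)))
    as.data.frame(out)
  })
}

#' Closed-form summaries of a log-normal parameter distribution
#'
#' For a parameter `exp(X)` with `X ~ N(mu, sigma)`: the mode is
#' `exp(mu - sigma^2)` and the central 95% interval is
#' `exp(mu +/- 1.959964 * sigma)`.
#'
#' @param mu,sigma Mean and SD of the log-parameter; `sigma >= 0`.
#' @return Named vector `mode`, `p2.5`, `p97.5`.
#' @export
#' @examples
#' lognormal_stats(2.46, 0.35)   # amplitude distribution: mode 10.4 pA
lognormal_stats <- function(mu, sigma) {
  stopifnot(sigma >= 0)
  mu <- unname(mu); sigma <- unname(sigma)
  z <- 1.959964
  c(mode = exp(mu - sigma^2),
    p2.5 = exp(mu - z * sigma),
    p97.5 = exp(mu + z * sigma))
}

#' Log-normal parameters from an arithmetic mean and CV
#'
#' Inverts the moment relations of the log-normal: `sigma^2 = log(1 + cv^2)`
#' and `mu = log(mean) - sigma^2 / 2`, so draws have the requested
#' arithmetic mean and coefficient of variation. The implied mode is
#' `mean / (1 + cv^2)^(3/2)`.
#'
#' @param mean Arithmetic mean (> 0).
#' @param cv Coefficient of variation (>= 0).
#' @return Named vector `mu`, `sigma` on the log scale.
#' @export
lognormal_from_mean_cv <- function(mean, cv) {
  if (mean <= 0) stop("`mean` must be positive")
  if (cv < 0) stop("`cv` must be non-negative")
  s2 <- log(1 + cv^2)
  c(mu = log(mean) - s2 / 2, sigma = sqrt(s2))
}

#' Draw event onset sample indices
#'
#' Onsets are uniform over the simulation samples. When `min_iei` is set,
#' onsets violating the minimum spacing to their predecessor are redrawn
#' until the whole set satisfies the constraint (retry-capped).
#'
#' @inheritParams sample_event_params
#' @return Sorted integer vector of 1-based onset sample indices.
#' @export
place_onsets <- function(spec, seed = spec$seed) {
  withr::with_seed(seed, draw_onsets(spec))
}

draw_onsets <- function(spec, max_retry = 1e4) {
  n_samples <- round(spec$duration * spec$fs)
  if (spec$n_events == 0L) return(integer(0))
  onsets <- sample.int(n_samples, spec$n_events, replace = TRUE)
  if (is.null(spec$min_iei) || spec$min_iei <= 0) return(sort(onsets))
  gap <- round(spec$min_iei / 1000 * spec$fs)
  for (try in seq_len(max_retry)) {
    onsets <- sort(onsets)
    bad <- which(diff(onsets) < gap) + 1L
    if (!length(bad)) return(onsets)
    onsets[bad] <- sample.int(n_samples, length(bad), replace = TRUE)
  }
  stop("could not satisfy min_iei spacing within the retry cap")
}

#' Gaussian white-noise trace
#'
#' @param duration Duration in seconds.
#' @param fs Sampling rate in Hz.
#' @param rms Noise RMS (= SD, since the mean is 0) in pA.
#' @param seed Integer seed.
#' @return A `psc_trace` of i.i.d. `N(0, rms^2)` samples.
#' @export
white_noise <- function(duration, fs, rms, seed = 1) {
  stopifnot(rms >= 0)
  n <- round(duration * fs)
  samples <- if (rms == 0) numeric(n) else
    withr::with_seed(seed, rnorm(n, 0, rms))
  new_trace(samples, fs = fs, units = "pA",
            source = sprintf("white_noise(rms=%g, seed=%d)", rms, seed))
}

#' Synthesise a ground-truth recording
#'
#' For each event in turn, parameters and onset are drawn from the seeded
#' stream (amplitude, rise, decay, onset); a unit impulse at the onset is
#' circularly convolved (via FFT) with that event's own peak-scaled
#' biexponential kernel, scaled by its amplitude, and accumulated. The sum
#' is added to the background noise. Circular wrap-around is retained:
#' an event starting near the end of the record continues at the start,
#' while the ground truth records the pre-wrap onset.
#'
#' @param spec A [simulation_spec()].
#' @return List with `trace` (a `psc_trace`) and `truth`, a data frame
#'   (`onset_index`, `onset_time` s, `amplitude` pA, `tau_rise`,
#'   `tau_decay` ms) sorted by onset.
#' @export
#' @examples
#' sim <- synthesize(simulation_spec(n_events = 5, duration = 0.5,
#'                                   fs = 10000, seed = 7))
#' sim$truth
synthesize <- function(spec) {
  stopifnot(inherits(spec, "psc_simspec"))
  n <- round(spec$duration * spec$fs)
  draws <- withr::with_seed(spec$seed, {
    lapply(seq_len(spec$n_events), function(i) {
      p <- draw_event_params(spec)
      onset <- if (is.null(spec$min_iei) || spec$min_iei <= 0) {
        sample.int(n, 1L)
      } else {
        NA_integer_  # spaced onsets drawn jointly below
      }
      list(params = p, onset = onset)
    })
  })
  onsets <- vapply(draws, function(d) d$onset, integer(1))
  if (anyNA(onsets)) {
    onsets <- withr::with_seed(spec$seed + 1L, draw_onsets(spec))
  }
  signal <- numeric(n)
  if (spec$n_events > 0L) {
    freq_phase <- -2i * pi * (seq_len(n) - 1L) / n
    for (i in seq_len(spec$n_events)) {
      p <- draws[[i]]$params
      kern <- build_kernel(p[["tau_rise"]], p[["tau_decay"]], spec$fs)$kernel
      if (length(kern) > n) kern <- kern[seq_len(n)]
      K <- fft(c(kern, numeric(n - length(kern))))
      # FFT of a unit impulse at the onset is a pure phase ramp
      delta_hat <- exp(freq_phase * (onsets[i] - 1L))
      signal <- signal +
        p[["amplitude"]] * Re(fft(K * delta_hat, inverse = TRUE)) / n
    }
  }
  noise <- if (is.null(spec$noise_trace)) {
    white_noise(spec$duration, spec$fs, spec$noise_rms,
                seed = spec$seed + 2L)
  } else {
    if (length(spec$noise_trace$samples) != n) {
      stop("noise_trace length does not match duration * fs")
    }
    spec$noise_trace
  }
  trace <- new_trace(noise$samples + signal, fs = spec$fs, units = "pA",
                     source = sprintf("synthesize(seed=%d)", spec$seed))
  truth <- data.frame(
    onset_index = onsets,
    onset_time = (onsets - 1L) / spec$fs,
    amplitude = vapply(draws, function(d) d$params[["amplitude"]], 0),
    tau_rise = vapply(draws, function(d) d$params[["tau_rise"]], 0),
    tau_decay = vapply(draws, function(d) d$params[["tau_decay"]], 0)
  )
  truth <- truth[order(truth$onset_index), , drop = FALSE]
  rownames(truth) <- NULL
  list(trace = trace, truth = truth)
}
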