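#' Construct a trace object
#'
#' A `psc_trace` holds one uniformly sampled single-channel recording:
#' the sample values (typically membrane current in pA, or fluorescence in
#' arbitrary units), the sampling rate, and an optional set of excluded time
#' intervals that downstream detection must ignore.
#'
#' @param samples Numeric vector of finite sample values.
#' @param fs Sampling rate in Hz (> 0).
#' @param units Unit label for the samples (default `"pA"`).
#' @param excluded List of length-2 numeric vectors, each a half-open
#'   interval `[start, end)` in seconds to exclude from analysis. Intervals
#'   are normalised: sorted, merged if overlapping, and checked against the
#'   trace bounds.
#' @param source Provenance string (file name, simulation seed, ...).
#' @param partial Logical; marks a trailing remainder epoch produced by
#'   [split_trace()].
#'
#' @return An object of class `psc_trace` with fields `samples`, `fs`,
#'   `units`, `excluded`, `source`, `partial`.
#' @seealso [read_trace()], [split_trace()], [apply_exclusions()]
#' @export
#' @examples
#' tr <- new_trace(rnorm(1000), fs = 1000)
#' trace_duration(tr)
new_trace <- function(samples, fs, units = "pA", excluded = list(),
                      source = "", partial = FALSE) {
  if (!is.numeric(samples)) stop("`samples` must be numeric")
  if (!all(is.finite(samples))) stop("`samples` must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a single positive number")
  }
  tr <- structure(
    list(samples = as.numeric(samples), fs = as.numeric(fs),
         units = as.character(units), excluded = list(),
         source = as.character(source), partial = isTRUE(partial)),
    class = "psc_trace"
  )
  if (length(excluded)) tr <- apply_exclusions(tr, excluded)
  tr
}

#' Trace duration in seconds
#' @param trace A `psc_trace`.
#' @return Duration `length(samples) / fs` in seconds.
#' @export
trace_duration <- function(trace) {
  stopifnot(inherits(trace, "psc_trace"))
  length(trace$samples) / trace$fs
}

#' @export
print.psc_trace <- function(x, ...) {
  cat(sprintf("<psc_trace> %d samples @ %g Hz (%.4g s), units: %s\n",
              length(x$samples), x$fs, trace_duration(x), x$units))
  if (length(x$excluded)) {
    cat(sprintf("  excluded: %s s\n", paste(
      vapply(x$excluded, function(iv) sprintf("[%g, %g)", iv[1], iv[2]), ""),
      collapse = ", ")))
  }
  if (x$partial) cat("  (partial remainder epoch)\n")
  if (nzchar(x$source)) cat(sprintf("  source: %s\n", x$source))
  invisible(x)
}

# Normalise exclusion intervals: validate, sort, merge overlaps.
normalize_intervals <- function(intervals, duration) {
  if (!length(intervals)) return(list())
  ivs <- lapply(intervals, function(iv) {
    if (length(iv) != 2L || !is.numeric(iv)) {
      stop("each exclusion interval must be a numeric (start, end) pair")
    }
    if (iv[1] >= iv[2]) stop("inverted exclusion interval: start >= end")
    if (iv[1] < 0 || iv[2] > duration + 1e-12) {
      stop("exclusion interval out of trace bounds")
    }
    as.numeric(iv)
  })
  ivs <- ivs[order(vapply(ivs, `[`, 0, 1L))]
  merged <- list(ivs[[1]])
  for (iv in ivs[-1]) {
    last <- merged[[length(merged)]]
    if (iv[1] <= last[2]) {
      merged[[length(merged)]] <- c(last[1], max(last[2], iv[2]))
    } else {
      merged <- c(merged, list(iv))
    }
  }
  merged
}

#' Record excluded time intervals on a trace
#'
#' Samples are never mutated; the mask is carried with the trace so that
#' detection drops candidates whose onset falls inside a masked interval and
#' noise estimation omits masked samples. Intervals are half-open
#' `[start, end)` seconds; an onset exactly at `end` is retained.
#'
#' @inheritParams trace_duration
#' @param intervals List of `(start, end)` pairs in seconds, within the trace
#'   bounds. Appended to any intervals already recorded.
#' @return The trace with a normalised (sorted, merged) exclusion mask.
#' @export
apply_exclusions <- function(trace, intervals) {
  stopifnot(inherits(trace, "psc_trace"))
  all_iv <- c(trace$excluded, intervals)
  trace$excluded <- normalize_intervals(all_iv, trace_duration(trace))
  trace
}

# TRUE for each time in `times` (s) that falls inside an excluded interval.
in_excluded <- function(times, excluded) {
  if (!length(excluded)) return(rep(FALSE, length(times)))
  out <- rep(FALSE, length(times))
  for (iv in excluded) out <- out | (times >= iv[1] & times < iv[2])
  out
}

# Integer sample indices (1-based) covered by the exclusion mask.
excluded_sample_idx <- function(n, fs, excluded) {
  if (!length(excluded)) return(integer(0))
  idx <- lapply(excluded, function(iv) {
    lo <- max(1L, floor(iv[1] * fs) + 1L)
    hi <- min(n, ceiling(iv[2] * fs))
    if (lo > hi) integer(0) else lo:hi
  })
  unique(unlist(idx))
}
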