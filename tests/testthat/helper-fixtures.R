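# Shared fixtures, all generated in code.

std_template <- function(fs = 40000) build_kernel(0.44, 6.12, fs)

# A trace containing template-shaped events of given amplitudes at given
# onset sample indices (1-based), linear (non-circular) placement.
trace_with_events <- function(onsets, amplitudes, n, fs = 40000,
                              tau_rise = 0.44, tau_decay = 6.12,
                              noise_sd = 0, seed = 1) {
  k <- build_kernel(tau_rise, tau_decay, fs)$kernel
  x <- if (noise_sd > 0) withr::with_seed(seed, rnorm(n, 0, noise_sd))
       else numeric(n)
  for (i in seq_along(onsets)) {
    span <- onsets[i]:min(n, onsets[i] + length(k) - 1L)
    x[span] <- x[span] + amplitudes[i] * k[seq_along(span)]
  }
  new_trace(x, fs = fs)
}

# Naive O(n^2) DFT for the deconvolution oracle.
naive_dft <- function(x, inverse = FALSE) {
  n <- length(x)
  sgn <- if (inverse) 2i else -2i
  W <- exp(sgn * pi * outer(0:(n - 1), 0:(n - 1)) / n)
  as.vector(W %*% x)
}

# The accuracy emulation is expensive enough to share between the
# acceptance checks that consume it.
emulation_cache <- new.env(parent = emptyenv())
get_emulation <- function() {
  if (is.null(emulation_cache$res)) {
    emulation_cache$res <- run_accuracy_emulation(seed = 1)
  }
  emulation_cache$res
}
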