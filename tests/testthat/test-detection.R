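test_that("FFT deconvolution matches a direct DFT-division oracle", {
  n <- 256
  fs <- 2000
  tr <- trace_with_events(c(40, 150), c(12, 8), n = n, fs = fs,
                          tau_rise = 1, tau_decay = 8, noise_sd = 0.5,
                          seed = 4)
  got <- deconvolve(tr, build_kernel(1, 8, fs), band = NULL)$values
  k <- build_kernel(1, 8, fs)$kernel
  oracle <- Re(naive_dft(naive_dft(tr$samples) /
                           naive_dft(c(k, numeric(n - length(k)))),
                         inverse = TRUE)) / n
  expect_lt(max(abs(got - oracle)) / max(abs(oracle)), 1e-9)
})

test_that("deconvolution inverts convolution and is linear", {
  fs <- 40000
  n <- 8000
  d <- 1500
  tr <- trace_with_events(d, 10, n = n, fs = fs)
  det <- deconvolve(tr, std_template(fs), band = NULL)
  expect_lte(abs(which.max(det$values) - d), 1)

  tr3 <- new_trace(3 * tr$samples, fs)
  det3 <- deconvolve(tr3, std_template(fs), band = NULL)
  expect_equal(det3$values, 3 * det$values, tolerance = 1e-10)
})

test_that("two separated events give two detector maxima at their onsets", {
  fs <- 40000
  d <- c(2000, 20000)
  tr <- trace_with_events(d, c(10, 14), n = 40000, fs = fs,
                          noise_sd = 0.2, seed = 9)
  det <- estimate_noise_sd(deconvolve(tr, std_template(fs)))
  cand <- find_candidates(det, k = 3)
  # both onsets are recovered, and they carry the two largest detector peaks
  hits <- vapply(d, function(d0) {
    any(abs(cand$onset_index - d0) <= 0.0012 * fs)
  }, TRUE)
  expect_true(all(hits))
  top2 <- cand$onset_index[order(-cand$detector_peak)][1:2]
  expect_true(all(vapply(d, function(d0) {
    any(abs(top2 - d0) <= 0.0012 * fs)
  }, TRUE)))
})

test_that("detector noise SD estimation is robust to sparse outliers", {
  mk <- function(values, fs = 10000) {
    structure(list(values = values, fs = fs, sigma = NA_real_,
                   band = c(NA, NA), excluded = list()),
              class = "psc_detector")
  }
  x <- withr::with_seed(5, rnorm(1e5))
  expect_equal(estimate_noise_sd(mk(x))$sigma, 1, tolerance = 0.05)

  expect_equal(estimate_noise_sd(mk(rep(2, 5000)))$sigma, 0)

  x_out <- x
  x_out[seq_len(1000)] <- 10        # 1% outliers
  expect_equal(estimate_noise_sd(mk(x_out))$sigma, 1, tolerance = 0.10)

  expect_error(estimate_noise_sd(mk(rnorm(100))), "too few")
})

test_that("thresholding yields one candidate per supra-threshold region", {
  fs <- 10000
  v <- numeric(5000)
  v[2000:2004] <- c(2, 4, 5, 4, 2)   # a single 5-sigma spike
  det <- structure(list(values = v + 0, fs = fs, sigma = 1,
                        band = c(NA, NA), excluded = list()),
                   class = "psc_detector")
  cand <- find_candidates(det, k = 3)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$onset_index, 2002L)
  expect_equal(cand$detector_peak, 5)

  det0 <- det; det0$values <- v * 0.1
  expect_equal(nrow(find_candidates(det0, mode = "absolute", k = 3)), 0L)
  expect_error(find_candidates(det, k = -1), "positive")
})

test_that("candidate count is monotone non-increasing in the threshold", {
  fs <- 40000
  sim <- synthesize(simulation_spec(n_events = 20, duration = 2, fs = fs,
                                    seed = 21))
  det <- estimate_noise_sd(deconvolve(sim$trace, std_template(fs)))
  ks <- c(1, 2, 3, 4, 5)
  counts <- vapply(ks, function(k) nrow(find_candidates(det, k = k)),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("exclusion masks drop candidates by the half-open onset rule", {
  fs <- 10000
  v <- numeric(10000)
  spikes <- c(2000, 5000, 8000)
  v[spikes] <- 10
  mk <- function(excl) structure(
    list(values = v, fs = fs, sigma = 1, band = c(NA, NA), excluded = excl),
    class = "psc_detector")
  # exclusion starting one sample after a spike retains it
  t_spike <- (spikes[1] - 1) / fs
  cand <- find_candidates(mk(list(c(t_spike + 1 / fs, 0.6))), k = 3)
  expect_true(spikes[1] %in% cand$onset_index)
  expect_false(spikes[2] %in% cand$onset_index)  # 5000 is inside the mask
  # exclusion covering everything drops all candidates
  expect_equal(nrow(find_candidates(mk(list(c(0, 1))), k = 3)), 0L)
})
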