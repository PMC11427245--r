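---
title: "Detecting and classifying spontaneous synaptic events"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and classifying spontaneous synaptic events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pscdetect)
```

## The model

Spontaneous postsynaptic currents are modelled as scaled copies of a
canonical waveform, the peak-scaled difference of two exponentials

$$k(t) = s\,\bigl(e^{-t/\tau_d} - e^{-t/\tau_r}\bigr),\qquad
0 < \tau_r < \tau_d,$$

with $s$ chosen so $\max_t k(t) = 1$. Peak scaling makes the coefficient
multiplying the kernel the event's peak amplitude, and gives the analytic
peak time $t_{peak} = \frac{\tau_r\tau_d}{\tau_d-\tau_r}\ln(\tau_d/\tau_r)$.
A recording is treated as a sum of such events at unknown onsets plus
noise. Deconvolving the recording by the template in the frequency domain
(divide the DFTs, invert) turns each template-like event into a sharp
spike at its onset whose height estimates the amplitude — the *detector
trace*. Detection is then a thresholding problem on the detector, and
classification of the resulting candidates is a supervised learning
problem on a small, fixed feature set.

The pipeline deliberately detects with a *low* threshold (3 detector-noise
SDs) so that essentially all true events are among the candidates,
accepting tens of false positives per wave, and delegates the screening to
either a Pearson-correlation threshold against the template or a random
forest trained on expert (or, in simulations, oracle) labels.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `tau_rise`, `tau_decay` | 0.44, 6.12 | ms | Template kinetics for AMPA-receptor mEPSCs in CA1-like recordings; fit your own exemplar with `fit_template()`. |
| kernel duration | `8 * tau_decay` | ms | Truncates < 0.04% of the decay tail. |
| detector band | 1–200 | Hz | High-pass removes baseline drift; low-pass suppresses the noise amplified by the spectral division. |
| threshold `k` | 3 | detector-noise SDs | Low enough to recover ~all true events while leaving candidates for the classifier to reject. |
| Pearson threshold | 0.5 | – | The screening level at which false positives drop sharply while the true-positive rate is still near its plateau; −1 disables screening. |
| `n_trees`, `mtry` | 400, 4 | – | Standard random-forest defaults (`mtry = ⌈√10⌉` for 10 features). |
| matching tolerance | 1.2 | ms | Onset agreement window for evaluation and oracle labelling. |

The matching tolerance deserves a note: the evaluation protocol this
follows states the window as "1.2" without units; 1.2 ms is the only
physically sensible reading at 40 kHz sampling with millisecond-scale
kinetics (1.2 s would merge unrelated events; 1.2 samples would reject
correct detections), and it is exposed as an argument everywhere it is
used.

## Numerical choices

**Detector filtering.** The band-pass is applied as a zero-phase response
in the frequency domain: a 2nd-order Butterworth *magnitude* high-pass and
a Gaussian low-pass with −3 dB at the cutoff. Two reasons. First,
zero-phase filtering is exact in the frequency domain, whereas a
forward–backward time-domain filter at 1 Hz on 40 kHz data is numerically
fragile (normalised cutoff 5·10⁻⁵). Second, the low-pass must roll off
faster than the deconvolution amplifies noise: the biexponential kernel's
spectrum decays as $f^{-2}$, so the quotient's noise grows as $f^{2}$, and
a 2nd-order (f⁻²) low-pass would only cancel it, leaving white detector
noise up to Nyquist and thousands of threshold crossings per wave. The
Gaussian response (super-polynomial roll-off, no ringing, monotone step
response) suppresses it while preserving onset timing.

**Noise SD of the detector.** A naive SD is inflated by the event spikes.
`estimate_noise_sd()` fits a Gaussian to the histogram of detector values
bounded by the Tukey fences of the inter-quartile range (spikes are sparse
and extreme, so they fall outside), with `mad(x)` as fallback; a constant
detector yields 0. Restricting the histogram to the inter-quartile range
itself was tried and rejected: fitting only the top of the bell is
ill-conditioned and biased ~16% low.

**Deconvolution regularisation.** The division is exact by default (no
Wiener floor); the band-pass performs the noise control. A configurable
`epsilon` floor exists for pathological templates but is off by default.

**Candidate onsets.** One candidate per contiguous supra-threshold region
of the detector, at the region's maximum; the detector peak is taken as
the onset time, and the event's peak is at onset + $t_{peak}$. Sample
indices are 1-based (native R); all times are in seconds with half-open
`[start, end)` exclusion intervals — an onset exactly at an interval's end
is retained.

**Feature degeneracies.** Features that are undefined on a degenerate
window (skewness of all zeros, rise time of a non-positive peak) are coded
0 so feature vectors are always finite; the forest learns whatever
discriminative value that carries.

**Tie votes.** With an even number of trees a 50/50 vote is possible; it
resolves to *reject*, conservative toward false-positive suppression.

**Decay-τ feature.** A log-linear least-squares fit of the decay phase
(peak down to 5% of peak), falling back to the time-to-1/e for short or
noisy decays. This is a feature for the classifier, not a kinetics
estimator; speed and robustness matter more than unbiasedness here.

**Template fitting.** `fit_template()` uses Levenberg–Marquardt least
squares with onset offset free, initialised from the observed peak
(τ_r: 10% of the rise span, τ_d: time from peak to 1/e). The exemplar-fit
algorithm is not prescribed by the protocol this package follows; these
choices are documented so fits are reproducible.

## The simulator

`synthesize()` draws, per event, amplitude and kinetics by exponential
transformation of normal deviates — defaults $N(2.46, 0.35)$ (log-pA),
$N(-0.31, 0.60)$ and $N(1.48, 0.46)$ (log-ms), the decay redrawn until it
exceeds the rise — and a uniform onset sample, in the documented stream
order (amplitude, rise, decay, onset per event) from a single seed. Each
event's own kernel is placed by FFT *circular* convolution (an event near
the end wraps to the start; the ground truth records the pre-wrap onset)
and the sum is added to Gaussian white noise (default RMS 2 pA; 2.43 pA in
the accuracy emulation, matching the measured RMS of the whole-cell
recording noise that the white noise stands in for). The closed-form
summaries of the defaults — amplitude mode 10.4 pA [5.9–23.2], rise
0.51 ms [0.23–2.38], decay 3.56 ms [1.78–10.82] — are available from
`lognormal_stats()`, and `lognormal_from_mean_cv()` converts a mean/CV
specification (e.g. 20 pA with CV 0.5) to log-scale parameters.

What the simulator does *not* emulate: real recording noise is coloured
(membrane/electrode filtering, 4 kHz anti-alias filtering, stochastic
channel openings), non-stationary, and occasionally contains artifacts.
White noise of matched RMS is spectrally flat, which makes the detector
quieter at low frequencies and the candidate features more separable than
in real data. Consequently the pipeline's accuracy on simulated waves
(~0.96–0.99) should be read as an upper bound; on real recordings with
expert labels, accuracies nearer 0.9 are the realistic expectation, and
passing tests here demonstrate correctness of the machinery, not field
performance. When a realistic noise floor matters, pass a recorded noise
trace via `simulation_spec(noise_trace = ...)`.

## Evaluation design

Matching is greedy nearest-neighbour one-to-one within the tolerance,
ties broken by earlier reference time; candidates are matched against the
reference once, and each candidate's classification then determines its
cell: matched+accepted = TP, unmatched+accepted = FP, unmatched+rejected =
TN, and FN = references with no accepted match (covering both rejected
and undetected events), so TP + FN equals the reference count. Metrics
with zero denominators are returned as `NA` with a warning rather than
propagated silently.

The Matthews correlation coefficient uses the standard numerator
$TP \cdot TN - FP \cdot FN$. For inter-rater agreement, two raters'
candidate pools are aligned by onset matching; a candidate absent from
one rater's pool counts as rejected by that rater, so raters are compared
over the union of what either proposed. Grid-level condition comparisons
(`rater_consistency_test()`) permute whole event-time sets per subject
between conditions and recompute both grids per replicate, because the
pairwise MCCs are correlated and subject-level exchange is the valid
exchangeability unit; `paired_permutation_test()` is the scalar
per-subject version, exhaustive over all $2^n$ sign assignments up to
$n = 25$ (32,768 assignments at $n = 15$) with the observed assignment
included, and Monte-Carlo beyond.

## Problem sizes and determinism

The test suite and the acceptance script work at the scale of the
reference protocol itself — 9.9-s waves at 40 kHz (396,000 samples), 40
events per wave, 4 training + 4 test waves, 400-tree forests — which runs
in well under a minute per full emulation; property checks against
$O(n^2)$ oracles (direct DFT division, direct circular convolution) use
traces of ≤ 4096 samples where the oracle is exact and affordable, and
moment-recovery checks use $10^5$ draws. Every stochastic step (simulation
streams, forest bootstraps, Monte-Carlo permutations) is seeded
explicitly, and model training uses an isolated RNG scope so library
calls never perturb the caller's stream.

## Known limitations

* Overlapping events are detected (deconvolution tolerates overlap well)
  but their windows are extracted independently, without subtracting
  neighbouring fits, so amplitude/area features of closely spaced events
  are contaminated by their neighbours.
* The ten-feature set is this package's own documented choice, versioned
  in model files; models are refused when the feature version differs.
  It spans amplitude, kinetics, shape match, and noise context, but no
  claim is made that it is optimal.
* File support is deliberately narrow (CSV/TSV columns, raw int16 with a
  JSON sidecar); convert vendor formats externally.
* The decay constraint $\tau_d > \tau_r$ truncates the decay
  distribution, biasing its log-mean upward by a small amount (~0.007 at
  the defaults); this is measured, documented behaviour rather than a
  bug, and mirrors the generating process being emulated.
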