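---
title: "Methods: multivariate multiscale modified distribution entropy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multivariate multiscale modified distribution entropy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmdisten)
```

## The estimator

`mm_mdisten()` quantifies the irregularity of a `c`-channel recording at a
coarse-graining scale `s` by the Shannon entropy of its *similarity
distribution*. The chain is: window-average each channel at width `s`
(`coarse_grain()`), concatenate all channels' delay vectors at a common
time index into `(c*m)`-dimensional composite states (`phase_space()`),
take Chebyshev distances between every distinct pair of states
(`pairwise_distances()`), map each distance through a fuzzy exponential
membership `exp(-(d/r)^n)` (`fuzzy_similarity()`), histogram the resulting
similarities into `B` equal bins over [0, 1] (`empirical_pdf()`), and
normalize the Shannon entropy of that histogram by `log2(B)` so the result
lies in [0, 1].

Assumptions worth stating:

* Channels are commensurate: one distance matrix couples all channels, so
  amplitudes must be comparable across channels (true for same-device EEG;
  not for mixed modalities). Because the tolerance `r` scales with the
  pooled SD, a *global* rescaling of the recording cancels exactly — the
  estimator is amplitude-scale invariant — but relative channel gains
  matter.
* The sampling rate is metadata only; the estimator sees sample indices.
* `m` and `tau` are uniform across channels. Per-channel embedding
  parameters are representable in principle, but one montage-wide `(m,
  tau)` is the only configuration ever used here, and supporting ragged
  embeddings would complicate the composite-vector algebra for no tested
  benefit.

## Parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `m` | 3 | embedding dimension; 3 samples per channel per state distinguishes the reference series while keeping `V` large at high scales |
| `tau` | 1 | delay between embedded samples (in samples) |
| `r_coeff` | 0.2 | tolerance as a fraction of the pooled SD of the *coarse-grained* data; recomputed per scale so that the similarity kernel tracks the variance the windowing removes |
| `n` | 2 | fuzzy exponent: the "step" of the exponential membership; larger values sharpen the cutoff around `r` |
| `B` | 64 | histogram bins; with `V(V-1)/2` pairs in the thousands, 64 bins keep the ePDF well populated |
| `scales` | 1–15 | coarse-graining widths; at 128 Hz these span ~8 ms to ~120 ms windows |
| `metric` | chebyshev | max-coordinate distance, the distribution-entropy convention; euclidean available as an alternative |
| `sd_pooling` | pooled | one SD over the whole coarse-grained matrix (population convention); a per-channel variant (mean of channel SDs) is available |

The feasibility constraint `floor(N/s) - (m-1)*tau >= 2` must hold at
every requested scale; `entropy_profile()` checks all scales up front and
names the offending one.

## Numerical choices

* **Histogram support.** Bins span the *fixed* interval [0, 1] of the
  similarity codomain, not the data range. This is what makes the value
  reproducible and amplitude-invariant; a data-dependent range would make
  the bins (and hence the entropy) depend on the extreme pair alone.
  Interior bin edges assign upward (`floor(v*B) + 1`) and exactly 1.0
  falls in the last bin, so identical vectors (similarity 1) are counted
  once, deterministically.
* **Zero-probability bins** contribute 0 to the sum (the `x log x -> 0`
  limit).
* **Zero-variance input** would give `r = 0` and an undefined membership;
  the estimator raises a named "degenerate input" error rather than
  returning a value.
* **SD convention.** Population SD (divide by the count), computed on the
  coarse-grained matrix at the scale being evaluated.
* **Coarse-grain remainder.** The trailing `N mod s` samples are
  discarded (floor convention).
* **Determinism.** The whole chain is deterministic; identical input and
  configuration give bit-identical output, and the test suite holds the
  vectorized path to within 1e-10 of an independent brute-force
  implementation that enumerates every vector pair with explicit loops.

## Reading the value

A subtlety that shapes every downstream result: because the histogram is
taken over *fuzzy similarities* on [0, 1] rather than over raw distances,
the estimator rewards *recurrence structure*, not brute randomness. For a
broadband noise signal almost every pair of states sits many tolerances
apart, `exp(-(d/r)^n)` underflows toward 0, the histogram piles into the
first bin, and the entropy is small. A narrowband or chaotic signal
revisits its trajectory, produces similarities spread across many bins,
and scores higher. The reference-series ordering the tests enforce is
therefore sinusoid > chaotic logistic map > Gaussian white noise — the
three are cleanly distinguished (disjoint replicate ranges over 20 seeded
replicates of 400 samples), which is the property the embedding dimension
was chosen for, but the *direction* is inverted relative to classical
raw-distance DistEn. Interpret the value as "richness of the similarity
distribution at tolerance r", not as "randomness".

This also dictates the regime in which the estimator is informative:
states must occasionally come within a few tolerances of each other. That
happens for band-limited, temporally correlated, cross-channel-correlated
signals — which preprocessed EEG is — and fails for independent white
noise across many channels, where the max-coordinate distance over `c*m`
dimensions essentially never drops near `r` and the entropy degenerates to
0 regardless of class.

## The synthetic test bench

`generate_series()` provides the parameter-selection series (400 samples
each): Gaussian white noise, the fully chaotic logistic map
(`x_{t+1} = 4 x_t (1 - x_t)`, 100-iteration burn-in, initial conditions
whose orbit collapses onto a fixed point are redrawn), a sinusoid, and 1/f
pink noise as the third broadband reference (the standard third series in
multiscale-entropy validation). All generators are pure functions of their
arguments including the seed.

`generate_labeled_dataset()` emulates a multi-subject two-class emotion
study at desk scale: 28 subjects x 20 trials, 14 channels, 384 samples
per trial (3 s at 128 Hz, a standard EEG epoch length), with continuous
1–9 ratings straddling the 4.5 binarization threshold. Trials follow a
shared-source model: one source waveform per trial is projected onto all
channels with random gains (uniform 0.6–1.4) plus 5% independent sensor
noise. The shared source is deliberate realism, not convenience: volume
conduction makes real EEG channels strongly correlated, and (per the
regime argument above) it is exactly this cross-channel correlation that
keeps the composite-state similarity distribution non-degenerate. Class 0
uses a narrowband 8–12 Hz sinusoid source, class 1 a broadband 1/f
source; under this estimator class 0 scores the *higher* entropy, and the
two classes' scale-1 values separate with no overlap.

What the generator does **not** emulate: non-stationarity, artifacts
(blinks, EMG), realistic spectra beyond 1/f, per-subject variability in
SNR, or any neural forward model. Passing the end-to-end test therefore
shows that the pipeline recovers a *constructed* irregularity contrast
through the full feature-extraction and cross-validation machinery — it
does not certify accuracy on real recordings.

## Classifier and evaluation

The classifier is a fully connected network — hidden widths `c(64, 32)`
with ReLU, a single sigmoid output — trained by backpropagation on binary
cross-entropy with RMSprop (learning rate 1e-3, decay 0.9), mini-batches
of 32, at most 300 epochs with early stopping after 20 epochs without
training-loss improvement, all seeded. The architecture and stopping rule
are free choices exposed in `mlp_spec()`; nothing in the entropy method
depends on them, and any competent binary classifier separates the
synthetic feature sets.

Evaluation is stratified 10-fold cross-validation: per-class round-robin
assignment of shuffled trials, feature standardization fit on each
training split only (no leakage into the held-out fold), decision
threshold 0.5, and per-fold precision / recall / F1 / accuracy in percent
with mean and SD across folds. A metric with a zero denominator (e.g.
precision when nothing is called positive) reports 0% with a `degenerate`
flag and a warning rather than NaN, so batch reports never fail. Ratings
exactly at 4.5 are assigned to "low" (the threshold is defined by strict
inequalities; ties break downward, documented in `binarize_rating()`).
Trials are pooled across subjects for the default report; per-subject
training — the protocol for real studies — is a `dplyr::filter()` away
and is left to the user at desk scale, where 20 trials per subject is too
few to cross-validate a network per subject meaningfully.

## Problem sizes

The shipped tests run the estimator-vs-oracle comparison on 50 random
signals (up to 3 channels x 100 samples, scales up to 4), the
normalization sweep on 1000 randomized inputs, the discrimination check
on 20 replicates x 3 series x 400 samples, and the end-to-end
classification on the full default dataset (560 trials x 14 channels x
384 samples, 15 scales, 10 folds, plus a permuted-label control). These
sizes give stable statistics while keeping a full run in the
tens-of-seconds range on one CPU.

## Known limitations

* The fuzzy-similarity histogram underflows to a single bin when no state
  pairs fall within a few tolerances (many independent rough channels);
  the estimator reports 0 there rather than failing, which is truthful
  but uninformative.
* `r` depends on the pooled SD, so a single channel with outsized
  variance inflates the tolerance for all channels; the `per_channel`
  pooling flag mitigates but does not remove this.
* Scales are integers; no overlap or composite coarse-graining variants.
* The CLI reads channel-matrix CSV and `.rds` arrays only; no EDF/BDF
  ingestion — convert upstream.
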