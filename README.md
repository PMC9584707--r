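# mmdisten

Multivariate multiscale modified distribution entropy for multichannel
physiological time series, with a complete synthetic-signal test bench and
a cross-validated neural classifier.

## The problem

Emotion-related EEG analysis (and physiological signal analysis more
broadly) needs a single-number summary of how *irregular* a multichannel
recording is, robust across time scales and channels. Classical
distribution entropy (DistEn) summarizes one channel at one scale; this
package implements its multivariate, multiscale, fuzzy-modified extension
and the downstream pipeline that turns per-scale entropy values into a
binary (e.g. high/low valence or arousal) classification.

## The estimator

For a recording `X` with `c` channels and `N` samples, at each scale
factor `s`:

1. **Coarse-graining** — each channel is replaced by means of
   non-overlapping windows of width `s`:
   `g_{c,j} = (1/s) * sum_{i=(j-1)s+1}^{js} x_{c,i}`, giving `floor(N/s)`
   samples per channel.
2. **Phase-space reconstruction** — composite delay vectors concatenate
   all channels at one time index:
   `M_j = (g_{1,j}, g_{1,j+tau}, ..., g_{1,j+(m-1)tau}, g_{2,j}, ..., g_{c,j+(m-1)tau})`,
   one `(c*m)`-dimensional state per time point, `V = floor(N/s) - (m-1)tau`
   vectors in all.
3. **Distance matrix** — Chebyshev (max-coordinate) distances `D_ij`
   between all distinct vector pairs (`i != j`).
4. **Fuzzy modification** — each distance passes through the fuzzy
   exponential membership `mu_ij = exp(-(D_ij / r)^n)` with tolerance
   `r = 0.2 * SD(coarse-grained data)` and exponent `n = 2`, giving a
   similarity in (0, 1].
5. **Entropy** — the empirical PDF `P_t` of the similarities over `B = 64`
   equal-width bins on [0, 1] yields
   `MM-mDistEn = -(1/log2 B) * sum_t P_t log2 P_t`, a value in [0, 1].

Defaults: `m = 3`, `tau = 1`, `r = 0.2 * SD`, `n = 2`, `B = 64`, scales
1–15. Per-scale values form the feature vector of a recording; a
feed-forward network (ReLU hidden layers, sigmoid output, binary
cross-entropy, RMSprop) classifies recordings, evaluated with stratified
10-fold cross-validation and precision / recall / F1 / accuracy in
percent.

## Worked example

```r
library(mmdisten)

x <- generate_series("logistic_chaotic", n_samples = 400, n_channels = 2, seed = 42)
x
#> <multichannel_signal> 2 channel(s) x 400 samples @ 128 Hz

entropy_profile(x, entropy_config(scales = 1:5))
#> # A tibble: 5 x 2
#>   scale entropy
#>   <int>   <dbl>
#> 1     1 0.0118
#> 2     2 0.00215
#> 3     3 0.00114
#> 4     4 0
#> 5     5 0
```

Each row is the entropy of the chaotic pair of channels after
coarse-graining at that scale: the value at scale 1 reflects the map's
recurrence structure, and averaging windows of growing width destroys it,
driving the value toward 0.

The full pipeline, desk-sized:

```r
ds  <- generate_labeled_dataset(n_subjects = 4, trials_per_class = 5, seed = 1)
ft  <- extract_features(ds)            # 40 trials x 15 scale features
rep <- cross_validate(ft, mlp_spec(seed = 1), k = 5)
rep
#> <cv_report> 5-fold stratified cross-validation (positive = 'high')
#>   precision  96.00% +/- 8.94
#>   recall    100.00% +/- 0.00
#>   f1         97.78% +/- 4.97
#>   accuracy   97.50% +/- 5.59
```

The two synthetic classes (narrowband shared-source trials vs broadband
ones) have sharply different entropy profiles, so the classifier recovers
the labels almost perfectly even from 40 trials; `tidy(rep)` gives the
per-fold confusion counts and `glance(rep)` a one-row summary.

A command-line interface wraps the same pipeline:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "mmdisten.R", package = "mmdisten"))')
Rscript $CLI simulate --outdir data/ --n-subjects 2 --seed 1
Rscript $CLI entropy  --input data/S01/S01_c0_t01.csv --output profile.csv
Rscript $CLI classify --features features.csv --output report.csv
```

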