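---
title: "Effective degrees of freedom from wavelet despiking: model, parameters and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Effective degrees of freedom from wavelet despiking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wavedf)
```

## The model

An fMRI voxel time series of length $N$ is colored: successive samples
are positively correlated, so the series carries fewer than $N$
independent observations. Denoising removes further information, and does
so unevenly across voxels. `wavedf` estimates the *effective* degrees of
freedom (df) left at each voxel in each frequency band, and uses those df
for Normal-theory inference on correlations.

The engine is the maximal overlap discrete wavelet transform (MODWT), an
undecimated transform defined for any series length that yields one
detail coefficient series per dyadic scale $j$, each acting as an
approximate band-pass filter for $1/2^{j+1} < |f| \le 1/2^j$
cycles/sample. The pyramid recursion uses orthonormal Daubechies filters
rescaled by $1/\sqrt{2}$ per level (the Percival–Walden convention), so
the energy of the detail plus final approximation coefficients equals the
energy of the input exactly — the property the variance-based df
accounting relies on. The number of scales is bounded by
$J \le \log_2(N/(L-1) + 1)$ for an $L$-tap filter.

**Despiking.** Motion and other non-stationary artifacts appear as
localised high-amplitude excursions across one or more scales. The detail
coefficients are split into two disjoint, additive sets — "signal" and
"noise" — and the denoised series is the inverse transform of the signal
set. The shipped detector is a deliberate, documented stand-in: per scale
it flags coefficients beyond `threshold_k` robust standard deviations
(1.4826 × MAD), extends flags along contiguous same-sign runs
(maxima/minima chains), and optionally propagates them to the
next-coarser scale within the filter support. Because every downstream
equation consumes only the binary mask, an externally produced mask
(`coefficient_mask()`, importable from text) yields exactly the same df
and inference machinery with any detector you prefer.

**df accounting.** Scale $j$ of a clean length-$N$ series carries
$N/2^j$ df (its share of the spectrum). Each removed noise coefficient is
subtracted before the division:

$$\hat\eta_j = \max\left\{\frac{M_j - M_{\phi,j}}{2^j},\, 1\right\}$$

where, under the reflection boundary (the default; the series is extended
to $[x, \mathrm{rev}(x)]$ and $2N$ coefficients are produced per scale),
$M_j = N$ and noise flags are counted over the first $N$ time indices
only — counting the mirrored half as well would double-count the same
events against an unchanged $M_j = N$. Under the periodic boundary the
$(2^j - 1)(L - 1)$ boundary-contaminated coefficients are discounted from
$M_j$ and from the noise count. df are kept as real numbers, never
rounded, add across scales, and sum to at most $N$.

**Inference.** A correlation between two series with df $\eta_a, \eta_b$
is assigned $\min(\eta_a, \eta_b)$ — the more-denoised series limits the
information in the pair — and tested with
$Z = \operatorname{atanh}(r)\sqrt{\eta - 3}$ against the standard Normal.
Multiple comparisons are handled by the Benjamini–Hochberg step-up rule
with $c(N)$ either 1 (classical BH, valid under positive dependence) or
the harmonic sum $\sum_{i=1}^N 1/i$ (valid under arbitrary dependence and
strictly harsher). Graphs are built by adding edges in order of
increasing P — not decreasing $|r|$ — so a strong correlation between
heavily denoised nodes can legitimately rank below a weaker one between
clean nodes; when df are constant across nodes the two orderings
coincide.

## Parameters that matter

| Parameter | Default | Meaning and guidance |
|---|---|---|
| `filter` | `"d8"` | Daubechies 8-tap (4 vanishing moments): good within-scale decorrelation while keeping artifact responses compact. `d4` localises artifacts more sharply but decorrelates less; `d12`/`d16` the reverse. |
| `boundary` | `"reflection"` | Avoids wraparound discontinuities and keeps $M_j = N$; `periodic` costs $(2^j-1)(L-1)$ coefficients per scale. |
| `threshold_k` | 5 | Robust-sd units for the noise detector. At 5 the false-flag rate on Gaussian data is negligible (~$6\times10^{-7}$ per coefficient before chaining), so clean voxels keep $\hat\eta_j = N/2^j$. |
| `scales` | 2–4 (examples) | At TR = 2 s, scales 2–4 cover 0.02–0.13 Hz, the conventional resting-state band; scale 1 (0.13–0.25 Hz) is noisier. |
| `q`, `cn_mode` | 0.05 / `"harmonic"` | FDR level and penalty. Harmonic mode is the conservative default; unit mode is the classical BH rule. |
| `tails` | 2 | Two-tailed P values let negative correlations form (negatively weighted) edges. |
| `w` (windows) | — | Target *effective* window length in samples (seconds accepted with `TR`). Each window's summed signal fraction lands in $[w-1, w]$, so consecutive windows differ by at most 1 df. |

## Numerical choices and degenerate inputs

- Edges with df $\le 3$ get $Z =$ NA and $P = 1$ by default — a heavily
  denoised pair can never be significant; `low_df = "strict"` errors
  instead. $|r| = 1$ (self or duplicate series) is reported as an
  infinite-Z / zero-P sentinel and excluded from seed-map testing.
- Equal P values tie-break by larger $|r|$, then lexicographic node pair;
  the rule is recorded on the graph object for reproducibility.
- Coefficient phase alignment is not applied: despiking and df counting
  operate on unshifted coefficients, so time indices of masks line up
  with the raw pyramid output.
- The dynamic-window rule keeps every window whose summed signal fraction
  reaches $w - 1$; trailing starts that cannot reach it are dropped. With
  SF $\equiv 1$ all interior windows have exactly $w$ samples.
- Degenerate detector inputs (constant or all-zero series, hence zero
  MAD) produce empty masks rather than errors.
- Windowed df maps drop scales whose level bound the window length cannot
  support, and error on windows shorter than the filter.

## What the synthetic generator does and does not emulate

`generate_run()` produces unit-variance AR(1) baselines (default
$\phi = 0.4$, an fMRI-like autocorrelation), planted networks that mix a
shared latent AR(1) signal to hit a target pairwise correlation, and
additive ramped artifact bursts with 50% sample-to-sample amplitude
jitter — so events carry both low- and high-frequency content — scaled
along a spatial gradient, with head-position displacement co-timed to the
bursts. It does **not** model hemodynamic convolution, physiological
(cardiac/respiratory) cycles, spatial smoothness of the baseline noise,
or scanner drifts. Passing tests on generated data therefore demonstrate
the statistical machinery (df accounting, error control, edge ordering)
under known ground truth; they do not certify detector sensitivity on
real scanner artifacts, for which the external-mask interface exists.

## Problem sizes used in the shipped checks

The test suite exercises series lengths 50–512, volumes up to
$8 \times 8 \times 8 \times 256$, 16-region graphs, 100 phase-randomization
repetitions over 55 series pairs for the error-control checks, and 50
repetitions of the end-to-end planted-edge recovery; these sizes give
Monte-Carlo standard errors small enough for the stated bounds while the
whole suite runs in a few minutes.

## Known limitations

- **Multi-scale time-domain correlation on strongly colored data.** The
  per-scale df $N/2^j$ equals the band's capacity, which is exact when the
  spectrum is flat within the band. Combining several scales into one
  time-domain correlation (seed maps over scales 2–4) and summing their df
  is well calibrated on white-ish data (observed $\alpha = 0.047$ at
  nominal 0.05 in our simulations) but becomes mildly anticonservative
  when the spectrum is strongly tilted within the combined band (AR(1)
  $\phi = 0.6$: observed $\alpha \approx 0.1$ at 0.05), because the
  low-frequency scale then dominates the variance with fewer effective
  samples than the capacity count. Per-scale wavelet-domain correlation
  (`wavelet_correlation_matrix()`), as used for graphs, does not have this
  issue; on real despiked data the subtracted noise coefficients push the
  estimate further toward conservatism.
- The detector is not the maxima/minima-chain algorithm of the original
  despiking toolbox; bit-exact mask replication is a non-goal and external
  masks are the supported route to it.
- df estimates are not spatially regularised; neighbouring voxels are
  treated independently.
- No decimated DWT, wavelet packets, wavestrapping, or partial-correlation
  edge weights.
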