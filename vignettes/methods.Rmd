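---
title: "Multivariate bi-dimensional entropy for color textures: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multivariate bi-dimensional entropy for color textures: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rgbentropy)
```

## The measures

`rgbentropy` quantifies the texture irregularity of a multichannel raster
image with two related statistics: multivariate sample entropy
(`msampen_rgb()`) and multivariate fuzzy entropy (`mfuzen_rgb()`).  Both
extend the bi-dimensional (grayscale) sample/fuzzy entropies to `q`
channels through a multivariate embedding, so that the R, G and B planes
of a color image are treated as one coupled system rather than three
independent images.

**Embedding.**  Given per-channel patch sizes `M = [m_1, ..., m_q]` and
`n = max(M)`, every anchor pixel `(i, j)` on the `(H - n) x (W - n)` grid
yields a *composite delay vector*: the concatenation, channel by channel,
of the `m_k x m_k` patch anchored there, read out row-wise.  Each channel
contributes `m_k^2` elements, so the composite dimension is
`m = sum(M^2)`.  There are `N_m = (H - n)(W - n)` such vectors.

**Matching.**  Similarity between two composite vectors is judged by the
Chebyshev (maximum-norm) distance pooled over all elements of all
channels.  For sample entropy a pair *matches* when the distance is at
most the tolerance `r`; for fuzzy entropy every ordered pair contributes
the graded similarity `exp(-d^s / r)` with fuzzy power `s`.  Self-matches
are excluded at both dimensions.

**Dimension extension.**  From dimension `m` the system can evolve by
enlarging any one channel's patch from `m_k` to `m_k + 1`, giving
`q * N_m` extended vectors on the same anchor grid (an enlarged patch
always fits: anchors reach at most index `H - n - 1` and the extended
patch spans `m_k <= n` further pixels).  All extended vectors are pooled
and compared as flat vectors, exactly as the one-dimensional multivariate
sample entropy this construction descends from.  The entropy is

```
MSampEn = -ln(B_{m+1} / B_m),    MFuzEn = -ln(Phi_{m+1} / Phi_m),
```

the negative log of the conditional probability (or mean similarity) that
patterns close at dimension `m` remain close at dimension `m + 1`.
Irregular textures score high; self-similar ones low.

## Parameters

* `M` — per-channel patch sizes.  `[1,1,1]` compares single pixels across
  channels; `[2,2,2]` compares 2x2 neighborhoods and resolves finer
  spatial structure.  The kernels require all `m_k` equal: with unequal
  sizes, vectors extended in different channels would have different
  lengths (`2 m_k + 1` new elements), and the pooled flat Chebyshev
  comparison between them is undefined.  `build_composite_delay_vectors()`
  still accepts arbitrary `M` for inspection.
* `r` — tolerance, in absolute intensity units.  It is *not* rescaled
  inside the kernel: images z-normalized by `normalize_image()` make `r`
  effectively relative to one standard deviation, while synthetic MIX
  validation runs on raw generated values.  Typical values from the
  texture literature: `0.02`–`1` on normalized images.
* `s` — fuzzy power (fuzzy variant only); `s = 2` gives a Gaussian-like
  fall-off `exp(-d^2/r)`.  The similarity kernel is `exp(-d^s / r)`
  exactly — not the `exp(-d^s / r^s)` variant found elsewhere.
* `normalization` — how match counts become frequencies.  The mode
  `"consistent"` (default) divides by the actual number of comparison
  vectors minus the self-match, `N_m - 1` and `q N_m - 1`.  The mode
  `"literal"` uses the constants printed in the defining equations,
  `N_m - n - 1` and `q(N_m - n) - 1`, which carry the `- n` of the 1D
  notation (where `N - n` counts vectors) into a 2D setting where the
  vector count is `N_m` itself.  The choice shifts the entropy by a
  constant `ln c` that depends only on `N_m`, `n` and `q` — the test
  suite checks exactly this — so comparative analyses are unaffected.

## Undefined values

With a hard threshold and small `r`, an image may have zero matching
pairs at one of the two dimensions, and the log-ratio is then undefined.
This is intrinsic to sample entropy; the package reports it as a flagged
`defined = FALSE` result (never an error), and `multiscale_profile()`
records such scales as gaps.  It is also the practical argument for the
fuzzy variant, whose positive similarities make it defined for every
valid input.  The effect is not marginal: on raw MIX images (values in
`[-3, 3]`) with `r = 0.02` and `M = [2,2,2]`, a match requires twelve
intensities to agree within 0.02 simultaneously, so matches only arise
from patches of the deterministic template and vanish once the noise
fraction passes roughly one half.  Sample-entropy irregularity curves at
such small tolerances therefore break off at high noise levels, while the
fuzzy curves continue.

## Symmetries — what holds and what does not

Distances depend only on intensity differences, so both measures are
exactly invariant under adding a constant to every pixel.  At the base
dimension `m`, transposing the image or relabeling channels permutes
every composite vector identically and leaves `B_m` unchanged.  The
pooled extended dimension is less symmetric: a pair of vectors extended
in *different* channels have different element layouts, so transposition
or channel relabeling permutes the two sides differently and the flat
Chebyshev distance between them can change.  Likewise, base patches never
touch the last row/column of the image (anchors stop at `H - n - 1` so
that extended patches can grow), which breaks exact 180-degree-rotation
invariance.  With `q = 1` there is a single extension class and
transposition invariance is exact.  These are properties of the
algorithm as defined — inherited from the 1D multivariate construction —
not implementation artifacts; the test suite asserts the true symmetry
group and documents the rest.

## Multiscale extension

`coarse_grain()` implements the bi-dimensional analogue of the classic
coarse-graining: each channel is partitioned into non-overlapping
`tau x tau` blocks from the top-left corner, each block replaced by its
mean, trailing rows/columns discarded (padding would inject artificial
regularity).  `multiscale_profile()` evaluates the chosen measure at
`tau = 1..tau_max` with `r` held fixed across scales — the standard
convention, since the variance reduction of block averaging is precisely
the signature that makes white-noise entropy fall with `tau` while
spatially correlated textures stay high.  The profile is the feature
vector used for classification.

## The MIX generators

`generate_mix1d()` / `generate_mix2d()` produce the controlled-
irregularity validation substrate: each sample/pixel is, independently
with probability `p`, replaced by uniform noise on `[-3, 3]`; otherwise
it carries the deterministic sinusoid `sin(2*pi*i/12)` (1D) or
`sin(2*pi*i/12) + sin(2*pi*j/12)` (2D), with 0-based indices.  `p` is the
irregularity dial: `p = 0` is periodic with period 12, `p = 1` pure white
noise.  By default the Bernoulli mask and the noise are drawn
independently per channel, making each variate a distinct MIX process;
`shared_mask = TRUE` reproduces the literal reading of the defining
equation, in which the mask carries no channel index.  One seeded RNG
stream per call (mask first, then noise, column-major fill) makes output
bit-identical for identical parameters.

What the generator emulates is a known, tunable amount of spatial
irregularity with an exactly known ground truth; what it does not emulate
is anything resembling natural color textures — no cross-channel
correlation structure, no illumination effects, no spatial nonstationarity.
Tests passing on MIX fixtures therefore validate the *measurement
machinery* (the entropy responds monotonically to injected irregularity,
profiles separate classes), not classification performance on real
histology or material images.

## Classification harness

`multiscale_profile()` values become rows of a `feature_table()`; rows
containing any undefined entropy are excluded and counted, never imputed
(imputation would manufacture texture information).  `make_splits()`
draws repeated random train/test splits (default five at 75/25),
stratified by class, with per-class training counts apportioned by
largest remainder so the overall training fraction is honored; within
each class, candidates are ordered by sample id so a split depends only
on the seed, not on row order.  `evaluate_splits()` standardizes features
with training-fold statistics only (no leakage), fits a support vector
machine (libsvm via `e1071`; RBF kernel, cost 1 by default — a linear
kernel is exposed), and reports per-split accuracies
`100 * correct / total` and their arithmetic mean.

## Numerical choices

* The pair loops run in C++.  Vectors are pre-sorted by their first
  element, so the inner loop stops once the first-element gap exceeds the
  current distance cutoff — an exact pruning, since the Chebyshev
  distance bounds that gap from below.
* The fuzzy kernel skips pair terms that provably cannot influence the
  result: a term is dropped only when it is below `1e-15 / P` of the
  running sum (`P` = total pair count), which bounds the total dropped
  mass below `1e-15` of the final sum; until the sum is positive, only
  terms beyond the double-precision underflow of `exp` (exponent > 745)
  are skipped.  Kahan compensated summation keeps accumulation error near
  machine precision.  The optimized kernels match naive full summation
  (the shipped `*_brute` references) to 1e-10 on the test grid.
* Population standard deviation (divide by the pixel count) throughout
  normalization; z-normalization pools all channels by default so that
  cross-channel intensity relations — which the pooled Chebyshev distance
  compares — survive; `per_channel = TRUE` is available.
* Center-crop offsets are `floor((source - target)/2)` on both axes;
  grayscale conversion uses the 4-digit BT.601 luma weights
  0.2989/0.5870/0.1140.
* Constant images: `normalize_image()` refuses them (zero spread); the
  entropy kernels themselves return exactly 0 on constant arrays (every
  distance is 0 at both dimensions).

## Problem sizes used by the shipped validations

The test suite and `scripts/acceptance.R` generate everything they need
at run time: oracle comparisons on 8x8 images across
`q ∈ {1,3}`, `M ∈ {1,2}`, `r ∈ {0.02, 0.15, 1}`; irregularity curves on
ten seeded 100x100 MIX images per noise level `p ∈ {0, 0.2, ..., 1}` with
`M = [2,2,2]` and `[1,1,1]`, `r = 0.02`, `s = 2`; multiscale noise
signatures at `tau = 1..5` on ten 100x100 `p = 1` images; and a two-class
benchmark (`p = 0.2` vs `0.8`, fifty 50x50 images per class, profiles at
`tau = 1..5`) evaluated over five stratified 75/25 splits.  These sizes
keep a full run on a single CPU in the minutes range while leaving the
statistical checks well-powered.

## Known limitations

* Unequal per-channel patch sizes are accepted by the embedding builder
  but rejected by the entropy kernels (see *Parameters*).
* Sample entropy at small `r` is frequently undefined on noisy images;
  use the fuzzy variant when a totally defined feature vector is needed.
* The fuzzy irregularity response need not be strictly monotone in the
  MIX noise fraction near `p = 1` at very small tolerances: residual
  template coincidences at `p` just below 1 create close pairs at
  dimension `m` that rarely stay close at `m + 1`, which can push the
  conditional ratio above the pure-noise value.
* Image readers cover PNG and TIFF; color spaces beyond RGB-to-grayscale
  are out of scope.
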