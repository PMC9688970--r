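# rgbentropy

Texture irregularity measures for multichannel (RGB) images: bi-dimensional
**multivariate sample entropy** and **multivariate fuzzy entropy**, their
multiscale extension, the MIX family of synthetic validation images, and an
SVM harness that classifies images from their multiscale entropy profiles.

## The problem and the measures

Entropy-based texture descriptors quantify how irregular an image is: high
entropy for disordered texture, low entropy for self-similar structure.
Classic bi-dimensional sample/fuzzy entropy operate on grayscale images
only; color images are usually collapsed to luma first, discarding
cross-channel structure. This package treats a `q`-channel image as one
coupled system through a multivariate embedding.

For an `H x W x q` image with per-channel patch sizes `M = [m_1, ..., m_q]`
and `n = max(M)`, every anchor `(i, j)` on the `(H-n) x (W-n)` grid yields a
*composite delay vector*: the channel-by-channel concatenation of the
`m_k x m_k` patches anchored there (length `m = sum(M^2)`). Two vectors
match when their Chebyshev distance (max absolute difference pooled over
all channels) is within a tolerance `r`. The dimension is extended by
enlarging any one channel's patch to `(m_k + 1) x (m_k + 1)`, giving
`q * N_m` extended vectors. With `B_m` and `B_{m+1}` the mean
frequencies of matches at the two dimensions (self-matches excluded),

    MSampEnRGB(I, M, r)    = -ln( B_{m+1}(r) / B_m(r) )
    MFuzEnRGB(I, M, r, s)  = -ln( Phi_{m+1}(s, r) / Phi_m(s, r) )

where the fuzzy variant replaces hard matching with the graded similarity
`exp(-d^s / r)`, and is therefore defined for every input (sample entropy
is undefined when no pairs match). The multiscale profile evaluates the
measure on block-mean coarse-grained images at scales `tau = 1..tau_max`
and is the feature vector used for classification.

## Worked example

```r
library(rgbentropy)

# a 60x60 RGB MIX image: 30% of pixels are uniform noise, the rest a
# doubly periodic sinusoid -- a medium-irregularity synthetic texture
img <- generate_mix2d(mix_params(p = 0.3, shape = c(60, 60), q = 3, seed = 42))
img
#> <mcimage 60 x 60, 3 channels (R,G,B)>
#>   range [-3, 2.998], mean -0.009882
#>   provenance: mix2d(p=0.3, seed=42)

cfg <- embedding_config(M = c(2, 2, 2), r = 1, s = 2)
msampen_rgb(img, cfg)
#> <msampen M=[2,2,2] r=1 s=2> value = 3.103699  (b_m = 0.00172136, b_m1 = 7.72597e-05, N_m = 3364)
mfuzen_rgb(img, cfg)
#> <mfuzen M=[2,2,2] r=1 s=2> value = 1.436583  (b_m = 0.00543447, b_m1 = 0.00129198, N_m = 3364)

multiscale_profile(img, cfg, method = "mfuzen", tau_max = 5)
#> <multiscale_profile mfuzen M=[2,2,2] r=1, tau = 1..5>
#>   tau1=1.4366  tau2=0.8106  tau3=0.7999  tau4=0.7661  tau5=0.4868
```

The entropy value is the negative log conditional probability that pixel
neighborhoods similar at dimension `m` stay similar when one channel's
patch grows: 3.10 (sample) / 1.44 (fuzzy) sit between the near-zero values
of a periodic image and the high values of pure noise. The profile falling
from 1.44 to 0.49 across scales is the signature of the uncorrelated noise
component being averaged away by coarse-graining.

End-to-end classification of two synthetic texture classes:

```r
cfg <- run_config(method = "mfuzen", M = c(2, 2, 2), r = 0.02, s = 2,
                  tau_max = 5, seed = 1)
spec <- mix_spec(c(p02 = 0.2, p08 = 0.8), n_per_class = 50, shape = c(50, 50))
res <- run_pipeline(cfg, spec, out_dir = "run")       # features.csv + report.json
res$report$mean_accuracy
```

A command-line front end wrapping the same functions ships in
`inst/cli/rgbentropy.R` (subcommands `generate`, `compute`, `multiscale`,
`classify`, `pipeline`).

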