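# discrn — discriminative scale learning for multi-scale texture features

Texture descriptors (local binary patterns, Gabor filter banks, Haralick
co-occurrence statistics, dense-SIFT/PHOW) are computed over a pixel
neighborhood whose size — the *scale* — is a free parameter, and the
discriminative information for lesion detection is rarely spread evenly
across scales or shared between feature families. `discrn` learns, from
labeled training pixels, a sparse nonnegative weight per scale for each
family, selects the scales that carry the weight, and runs a
superpixel-aware pixel-classification pipeline (SLIC segmentation, balanced
sampling, Random Forest, majority-vote heatmap smoothing) on the selected
scales only — matching the accuracy of the all-scales pipeline at a
fraction of the feature-extraction cost. It is aimed at researchers
building pixel-wise lesion detectors on 2-D grayscale imagery
(radiology slices, histology tiles) with co-registered binary masks.

## The method

For a family extracted at `S` scales, a pixel pair has a per-scale distance
vector `h` (Hamming for LBP bit codes, Euclidean otherwise) and weighted
dissimilarity `wᵀh`. With `H_p` / `H_b` the matrices of sampled
within-positive and positive-vs-negative pair distance vectors, and
`S_p = H_p H_pᵀ`, `S_b = H_b H_bᵀ` the intra-/inter-class kernels, a
discriminative weighting maximizes `wᵀ S_b w / wᵀ S_p w`. This is solved in
a relaxed least-squares form (`R_pᵀ R_p` the Cholesky factorization of
`S_p`):

    min over a, w >= 0 of  || H_bᵀ R_p⁻¹ − H_bᵀ w aᵀ ||² + η ||w||₁

by alternating a closed-form `a`-update,
`a = R_p⁻ᵀ S_b w / sqrt(wᵀ S_b S_b w)`, with a sparse nonnegative
least-squares `w`-update (active-set solver; ridge `α`, sparsity `η`).
Scales with `w_s ≥ σ·max(w)` are selected (defaults `α = 0.1`,
`η = 0.001`, `σ = 0.3`). Full details and every numerical convention are
in the vignette, `vignettes/scale-learning.Rmd`.

## Worked example

Everything is testable without external data: seeded phantoms plant the
class difference at a known window scale (period-5 grating, amplitude
contrast inside an elliptical lesion).

```r
library(discrn)
train <- lapply(1:4, function(s) generate_phantom(phantom_spec(seed = s)))
test  <- generate_phantom(phantom_spec(seed = 99))
model <- discrn_fit(lapply(train, `[[`, "image"), lapply(train, `[[`, "mask"),
                    discrn_config(), seed = 1, verbose = TRUE)
#> family lbp      selected scales: 5
#> family gabor    selected scales: 5
#> family haralick selected scales: 7
#> family phow     selected scales: 5, 7
#> descriptor (family, scale) pairs: 5 of 12 (42%)

print(model$weights$gabor)
#> scale_weights (gabor): w = 0.0000, 1.0000, 0.0000
#> selected scales: 5 (sigma = 0.3)

hm <- discrn_predict(model, test$image, smooth = FALSE)
evaluate_auc(hm, test$mask)
#> [1] 0.999
```

The learned Gabor weights put all mass on the planted 5×5 scale; Haralick
prefers the next-larger window (a real property of co-occurrence
statistics — see the vignette); the pipeline keeps 5 of 12 (family, scale)
descriptor sets and still separates lesion from background almost
perfectly (pixel AUC 0.999 on the held-out phantom). `discrn_predict(...,
smooth = TRUE)` returns the quantized, superpixel-voted map instead;
`write_heatmap()` saves a PNG preview plus an exact CSV sidecar.

A thin command-line front end with `simulate`, `learn-scales`, `train`,
`predict` and `evaluate` subcommands is installed at
`inst/scripts/discrn`.

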