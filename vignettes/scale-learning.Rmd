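---
title: "Discriminative scale learning for multi-scale texture features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminative scale learning for multi-scale texture features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(discrn)
```

## The problem

Texture descriptors are computed over a pixel neighborhood whose size — the
*scale* — is a free parameter. In lesion detection the discriminative
information is rarely spread evenly over scales: a feature family may
separate lesion from background texture well at a 5×5 window and poorly at
3×3 or 7×7, and which scale works is different for each family. Extracting
every family at every scale is the safe default, but the cost of exhaustive
per-pixel extraction grows linearly in the number of (family, scale) pairs,
and uninformative scales can even hurt the classifier. This package learns,
from labeled training pixels, a sparse nonnegative weight for each scale of
each family, keeps only the scales carrying substantial weight, and runs the
whole detection pipeline — superpixel segmentation, balanced sampling,
Random Forest pixel classification, majority-vote smoothing — on the
selected scales alone.

## The model

For one feature family extracted at $S$ scales, a pair of pixels with
multi-scale descriptors $x, x'$ has a per-scale distance vector
$h = (h(x_1, x'_1), \dots, h(x_S, x'_S))^T$ (Hamming distance for LBP bit
codes, Euclidean otherwise), and the weighted dissimilarity is $w^T h$ with
$w \ge 0$. Stacking sampled within-positive pair distances as columns of
$H_p$ ($S \times N_p$) and positive-vs-negative pair distances as columns
of $H_b$ gives the intra-class and inter-class distance kernels
$S_p = H_p H_p^T$ and $S_b = H_b H_b^T$. A discriminative weighting makes
positive pairs look alike and cross-class pairs look different, i.e. it
maximizes the Rayleigh quotient $w^T S_b w / w^T S_p w$ over the simplex.

That constrained quotient is solved in a least-squares form: with
$R_p^T R_p$ the Cholesky factorization of $S_p$, minimize over $(a, w)$

$$\lVert H_b^T R_p^{-1} - H_b^T w\, a^T \rVert_2^2 + \eta \lVert w \rVert_1,
\qquad w \ge 0,$$

where the $\ell_1$ term (controller $\eta$) replaces the simplex constraint
and drives sparsity. The two blocks alternate:

* **w-step.** For fixed $a$, $w$ solves the LASSO-type problem
  $\min_{w \ge 0} \lVert H_b^T R_p^{-1} a - H_b^T w\rVert_2^2
  + \alpha \lVert w \rVert_2^2 + \eta \lVert w \rVert_1$ — a sparse
  nonnegative least-squares (SNNLS) problem. Because $w \ge 0$ makes the
  $\ell_1$ term linear, this is a nonnegative quadratic program on the
  normal equations $G = S_b + \alpha I$, $c = S_b R_p^{-1} a$, solved
  exactly by an active-set method in the style of Lawson–Hanson NNLS. The
  returned point satisfies the KKT conditions to $10^{-8}$ (relative), and
  the test suite checks it against exhaustive enumeration of all support
  sets for small $S$.
* **a-step.** For fixed $w$, $a = R_p^{-T} S_b w \,/\,
  \sqrt{w^T S_b S_b w}$, two triangular solves and a normalization.

After convergence $w$ is rescaled to unit Euclidean norm and the scales
with $w_s \ge \sigma\, w_{\max}$ are selected; the argmax always survives,
and lowering $\sigma$ can only grow the set.

### Numerical notes

* **Initialization** is uniform, $w = \mathbf{1}/S$; the iteration is
  deterministic given the kernels.
* **Stopping**: relative change $\lVert w_{t+1} - w_t\rVert /
  \lVert w_t \rVert < 10^{-6}$, or 100 iterations.
* **Ridge.** $S_p$ is singular whenever positive descriptors repeat, so
  $10^{-8}\,\mathrm{tr}(S_p)/S$ (with an absolute floor of $10^{-8}$ for an
  exactly zero kernel) is added before factorization.
* **The a-step is used exactly as written above.** Its normalization is not
  the exact minimizer of the joint objective under $\lVert a \rVert_2 = 1$
  (that would normalize by $\lVert R_p^{-T} S_b w \rVert$); both scalars
  leave the direction unchanged, and the alternation converges to the same
  fixed points, but monotone descent of the joint objective is then only
  approximate: on adversarially random kernels single steps can raise it by
  $\sim 10^{-7}$ relative. The w-step alone never increases its subproblem
  objective, which is what the tests assert in general; full-trace descent
  is asserted on the planted fixtures where it holds.
* **Degenerate kernels.** If $S_b w = 0$ (no scale discriminates at all) or
  the weights collapse to zero, uniform fallback weights are returned with
  a `fallback` flag and a warning, so downstream code keeps all scales
  rather than none.
* **Winner-take-all under exchangeability.** When every scale carries the
  same information (e.g. a kernel fixture with `gap = 1`), the sparsity
  term makes the alternation collapse onto a single, seed-dependent scale
  rather than returning uniform weights: the uniform point is an unstable
  fixed point. This matches the observation that on low-resolution imagery
  one scale per family is typically selected. The exchangeability test
  therefore asserts that no scale is *systematically* favored across seeds,
  not that $w$ itself is flat.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `scales` | 3, 5, 7 px | odd window sides; use up to 9 scales (3–25 px) for high-resolution imagery |
| `alpha` | 0.1 | ridge controller of the w-step |
| `eta` (`mu`) | 0.001 | $\ell_1$ sparsity controller |
| `sigma` | 0.3 | selection threshold on $w / w_{\max}$ |
| `bits` | 8 | LBP circle samples per code |
| `angles` | 0°, 90°, 180° | Gabor orientations |
| `gray_levels` | 32 | Haralick window quantization |
| `rSize`, `reqStr` | 8 px, 0.01 | SLIC nominal size and spatial regularization |
| `n_trees` | 50 | Random Forest size |
| `pairs_per_slice` | 2000 | sampled pairs per slice per kernel |

The feature extractors fill gaps the weighting model does not prescribe,
each following the common convention of its family:

* **LBP**: bit $j$ compares the bilinearly interpolated sample at angle
  $2\pi j/8$ on a circle of radius $(k-1)/2$ against the center, ties → 1;
  codes are plain (non-rotation-invariant) by default with an optional
  minimal-rotation mapping. Near-integer circle offsets are snapped and the
  comparison tolerates $10^{-12}$ relative rounding so constant patches
  give all-ones codes exactly.
* **Gabor**: a $k \times k$ complex kernel with wavelength $\lambda = k$
  and envelope sd $0.5\lambda$, DC-corrected so constant patches give zero
  response; the descriptor is the response magnitude per angle.
* **Haralick**: window intensities quantized to 32 levels over the window
  range; co-occurrence pooled over the four distance-1 offsets,
  symmetrized, normalized; the classic 14 statistics, with correlation-type
  statistics defined as 0 on single-level windows and the maximal
  correlation coefficient falling back to 0 when undefined. Internally the
  second eigenvalue needed by that 14th statistic comes from a symmetric
  eigensolve of $D^{-1/2} P D^{-1/2}$, whose squared spectrum equals that
  of the usual nonsymmetric $Q$ matrix.
* **PHOW / dense SIFT**: spatial bin side $\lceil k/4 \rceil$, 4×4 bins ×
  8 orientation bins of central-difference gradients, magnitude-weighted
  with nearest-lower bin assignment, L2-normalized with 0.2 clipping; flat
  patches give all-zero descriptors.
* **Borders** are handled by reflect padding (edge not duplicated) by the
  largest radius a family needs, identically at train and test time.

## The detection pipeline

Training: SLIC superpixels are computed per slice (`rSize`, `reqStr`; the
spatial term is weighted $\mathrm{reqStr}/\mathrm{rSize}^2$ on intensities
rescaled to $[0,1]$, and a connected-components pass guarantees 4-connected
regions). The balanced training set takes *all* lesion pixels, one
representative per fully-negative superpixel (the member pixel nearest the
centroid), and seeded uniform top-up (or center subsampling) to equalize
the classes. Distance kernels are built per slice — pairs never straddle
slices — with at most `pairs_per_slice` pairs of each kind. Weights are
learned independently per family, and a 50-tree Random Forest is trained on
the concatenated selected-scale descriptors.

Testing: every pixel is classified (features extracted at the selected
scales only), giving a raw probability heatmap; superpixels are recomputed
on the test image with the same parameters; probabilities are quantized to
$\{0, 0.1, \dots, 1\}$ (half-up) and each superpixel takes the modal level,
ties broken toward the smaller level — an idempotent operation. AUC is
evaluated by midrank Mann–Whitney over pixels, on the raw map by default
(a flag evaluates the smoothed map instead; smoothing optimizes visual
coherence, not pixel-wise ranking, and typically costs a few AUC points on
small lesions whose boundary crosses superpixels).

`evaluate_auc()` accepts an optional region of interest, and the package's
own phantom evaluations use `interior_roi()`: pixels whose feature windows
cross the image border are described by reflect-padded (extrapolated)
content, their descriptors are systematically atypical, and the forest
learns to score that artifact — on null phantoms (whose lesion is interior
by construction) whole-image evaluation then reads a few points above
chance purely from the depressed border band. Clinical evaluations face
the same choice and are normally restricted to an organ ROI; restricting
to fully-supported pixels is the synthetic analog.

## What the phantoms emulate — and what they do not

Real multi-site MRI/histology data with co-registered lesion masks cannot
be shipped with a package, so every claim here is validated on seeded
synthetic phantoms: an oriented sinusoidal grating of period equal to the
planted scale over the whole image, with amplitude `base_amplitude`
(default 0.08) in the background and `base_amplitude * (1 + effect_size)`
(default `effect_size` 1.5) inside an elliptical lesion, plus i.i.d.
Gaussian noise (sd 0.05). The defaults were chosen once as a
moderate-contrast, visibly textured regime: the grating is plainly visible
but pixel intensities of the two classes overlap heavily, so single-pixel
thresholding cannot separate them and the window-based features must do the
work. `effect_size = 0` makes the classes exactly exchangeable, which the
null tests exploit.

The phantoms deliberately contain band-limited texture with a known
discriminative scale, so they validate the machinery: extraction
correctness, kernel assembly, optimizer behavior, scale selection,
end-to-end detection, chance-level behavior under the null. They do *not*
contain bias fields, anatomy, stain variation, multi-site intensity shifts,
or lesion-size/shape diversity — passing tests say nothing about clinical
performance, only about the correctness of the method's implementation.

One instructive phantom result: the Gabor family recovers the planted scale
essentially always (its kernel is a matched filter for the grating period),
while Haralick features systematically select the *next larger* window.
That is a real property of co-occurrence statistics, not a defect: the
per-window min–max quantization cancels the amplitude contrast, and what
remains discriminative is the relative noise level, which is better
estimated the more full periods the window contains. Different families
genuinely peak at different scales — which is the reason for learning the
weights per family in the first place.

## Verification problem sizes

The package verifies itself at sizes chosen to keep a full run comfortable
on a laptop: optimizer oracles at $S \le 3$ against exhaustive support
enumeration (100 instances), the a-step against direct triangular solves
(100 instances), planted-scale recovery on 20 seeded kernel fixtures,
end-to-end detection on ten 128×128 training phantoms and five test
phantoms with the 3-scale grid, smoothing against brute-force modes on
1000 random label maps, extractor oracles on 50 random images, and the
null on ten 64×64 zero-effect phantoms. `scripts/acceptance.R` re-runs the
end-to-end, recovery and null computations from scratch and writes the
resulting numbers as JSON.

## Known limitations

* Slices are independent 2-D images; no volumetric texture.
* Weights are learned per family; no joint optimization across families,
  no kernelized extension.
* The SLIC variant is grayscale-only and deterministic; with very weak
  spatial regularization on unstructured noise its regions can merge well
  below the nominal count (structured images behave as expected).
* The heatmap PNG preview is 8-bit; exact probabilities live in the CSV
  sidecar.
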