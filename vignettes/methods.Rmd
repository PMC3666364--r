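---
title: "Unsupervised SOM–FCM brain tissue segmentation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised SOM-FCM brain tissue segmentation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

`somseg` segments a skull-stripped T1-weighted brain MRI volume into
cerebrospinal fluid (CSF), gray matter (GM) and white matter (WM) without any
training labels. The method has four stages:

1. **Per-voxel descriptors.** Every brain voxel is described by a
   23-dimensional statistical vector computed from its 3×3×3 neighbourhood:
   12 Haralick texture statistics derived from three-dimensional gray-level
   co-occurrence matrices (GLCMs), 3 first-order window statistics (central
   intensity, window mean, window population variance), 7 local-histogram
   moments (mean, variance, energy, entropy, skewness, kurtosis, mode), and
   the voxel's global intensity probability. In 3D there are 27 window
   offsets with components in {−1, 0, 1}; excluding the null offset and
   folding antipodal pairs (a symmetric GLCM satisfies G<sub>d</sub> =
   G<sub>−d</sub><sup>T</sup>) leaves 13 independent directions. One GLCM is
   accumulated per direction and each Haralick statistic is averaged over the
   13 directions for rotation invariance.
2. **Vector quantization.** A self-organizing map (SOM; default 10×10
   hexagonal lattice) quantizes the descriptor cloud into prototype vectors
   ω<sub>i</sub>. The best matching unit (BMU) of a vector v is the prototype
   minimizing Euclidean distance.
3. **Fuzzy clustering of prototypes.** Fuzzy c-means (FCM) groups the U
   prototypes into K = 3 tissue clusters by minimizing
   J<sub>m</sub> = Σ<sub>k</sub>Σ<sub>i</sub> u<sub>ki</sub><sup>m</sup>
   ‖v<sub>k</sub> − c<sub>i</sub>‖², alternating the membership and center
   updates until the largest membership change falls below ε. Each voxel
   inherits the membership row of its BMU.
4. **Defuzzification and partial-volume labeling.** The crisp label is the
   maximum membership. Because a voxel may contain signal from two tissues
   (the partial volume effect, PVE), any cluster whose membership lies within
   τ of the voxel's maximum membership is added to its label set
   (τ = 0.02 by default; τ = 0 reduces exactly to crisp labeling). Clusters
   are named CSF/GM/WM by ranking their mean raw intensity ascending, which
   on T1 contrast orders CSF < GM < WM.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| window size `w` | 3 | odd edge of the descriptor cube (voxels); 3 trades texture capture against resolution and cost |
| gray levels `N_g` | 16 | equal-width re-quantization bins over the masked intensity range; 16² GLCM cells keep per-window cost tractable |
| border | `pad_reflect` | mirror volume faces so every masked voxel keeps a descriptor; `skip` drops voxels whose window leaves the mask |
| SOM shape | 10×10 | quantization error stabilizes around 64–100 units on brain-scale data |
| SOM epochs / σ schedule | 200, σ(t) = σ0·e^(−t/λ), λ = epochs | batch training; σ0 = half the lattice diameter; `lambda` can be shortened to anneal to the exact-quantization limit |
| training subsample | 100 000 | voxels used for SOM training (seeded); BMU mapping afterwards covers all voxels |
| FCM `k`, `m`, `eps` | 3, 2, 1e−5 | tissue count, fuzzifier, membership-change tolerance |
| PVE threshold `tau` | 0.02 | membership-difference window for multi-label assignment |

All stages take explicit seeds and are deterministic given them.

## Numerical and design choices

* **Quantization.** GLCMs over all intensity levels present in 16-bit data
  are intractable; equal-width binning to `N_g = 16` over the masked min–max
  range is the standard texture-analysis compromise. Values outside the mask
  are binned by the same rule and clamped so reflect-padded windows stay
  defined.
* **Haralick formula set.** The canonical 1973 definitions are used, with
  gray levels indexed 0…N−1: energy Σp², entropy −Σp·log₂p (0·log 0 := 0),
  correlation (Σij·p − μₓμᵧ)/(σₓσᵧ) (0 when a marginal is degenerate),
  contrast Σ(i−j)²p, homogeneity Σp/(1+(i−j)²), variance Σ(i−μ)²p,
  sum average Σ(i+j)p, dissimilarity Σ|i−j|p, cluster shade and cluster
  tendency Σ(i+j−μₓ−μᵧ)^k·p with k = 3 and 2, maximum probability max p,
  and difference variance = the variance of the difference histogram
  p₍ₓ₋ᵧ₎ (equal to contrast − dissimilarity²). The feature registry lists
  difference variance at index 12; an *inverse variance* variant
  (Σ_{i≠j} p/(1+(i−j)²)) is additionally resolvable by name because the
  published optimized subset names it at that index — the two tables of the
  source disagree, and we register both.
* **Symmetrization.** Each GLCM is accumulated with its transpose, so a
  constant 3×3×3 window yields 18 ordered pairs and a diagonal count of 36
  for a face offset — the analytic pair count w²(w−1) doubled.
* **Standardization.** Features are z-scored per column over the masked
  voxels before SOM training: SOM and FCM distances are Euclidean, and raw
  intensity-scale columns would otherwise dominate. Constant columns become
  zeros. Whether the original method standardized is unstated; this is the
  package's choice, applied consistently.
* **Zero-variance moments.** Skewness and kurtosis of a constant window are
  defined as 0 to keep the descriptor finite.
* **Batch SOM by default.** The classical online rule (with learning rate
  α(t) = α₀·e^(−t/λ)) is implemented as `mode = "online"`, but the default is
  the deterministic batch rule with a Gaussian neighbourhood — the standard
  desk-scale choice, order-independent and reproducible. With λ = epochs the
  neighbourhood anneals only to σ0/e; tests of the exact vector-quantization
  limit shorten `lambda`.
* **BMU and FCM tie rules.** BMU ties break to the lowest unit index; a
  point coincident with an FCM center receives a one-hot membership row;
  FCM initialization is a seeded random row-stochastic matrix with an
  iteration cap of 1000.
* **Tissue naming.** The source text's sentence about GM being darker than
  CSF contradicts T1 physics and its own figures; ascending mean intensity
  → CSF, GM, WM is implemented. Empty clusters warn and drop their tissue
  label; exact mean ties keep cluster-index order (stable sort) with a
  warning.
* **PVE rule.** The threshold is applied per voxel against the maximum
  membership: label set = {crisp} ∪ {k : u_max − u_k < τ}. For K = 2 this is
  exactly the pairwise membership-difference rule; for K > 2 it matches the
  stated intent without the ambiguity of pairwise indices.
* **Jaccard conventions.** Empty-vs-empty tissue sets score 1 with a
  warning; empty-vs-nonempty scores 0. Evaluation is restricted to the
  intersection of the prediction's and the reference's brain masks so
  brain-extraction differences do not contaminate the overlap.
* **Coordinates.** Voxel linear indices are 1-based in R's native
  column-major (x-fastest) order; the on-disk format's affine is carried but
  never used in computation.
* **GA selection.** Fixed-length bit masks over the 23 feature names;
  tournament selection (size 3), uniform crossover (rate 0.8), per-bit
  mutation (rate 1/23), elitism 1, fitness −(J_WM + J_GM + J_CSF) from a
  full pipeline run per training volume, cached per mask. The encoding is a
  subset mask: the search object is which features to keep.

## What the phantom emulates — and what a green test does not establish

`make_phantom()` builds a three-tissue, brain-like volume: nested
ellipsoidal shells (WM core, GM shell, CSF rim) inside an ellipsoidal brain
mask, tissue means (30, 100, 180) with additive Gaussian noise σ = 10
(seven-σ tissue separation, comparable to skull-stripped T1 contrast),
optional smooth multiplicative bias (a normalized low-order gradient field,
emulating coil shading), and per-tissue spatial smoothing of the noise
(default scales 0.5/1/1.5 voxels) so each tissue has a distinct local
texture. It deliberately omits MRI physics: no Rician noise, no scanner
point-spread function, no anatomy. Consequently tissue interfaces are *step
edges*, which real scanners never produce — every real boundary voxel is a
partial-volume mixture.

That difference matters for interpreting results. On this phantom the
descriptor windows that straddle an interface take extreme values on the
texture columns (contrast, variance, entropy, …), forming a compact,
dominant cluster in the z-scored feature space. FCM over the SOM prototypes
of the **full 23-feature** descriptor then prefers an interface-vs-interior
partition to the tissue partition: the effect is not an optimization
accident — initializing FCM at the tissue-aligned partition converges to
the same interface-structured optimum with the identical objective value,
and the behaviour persists with iid noise. The end-to-end acceptance test
asserting per-tissue Jaccard ≥ 0.85 under the all-features default is
therefore red in this stated world, and is left red rather than weakened.
With intensity-led subsets (e.g. central intensity, window mean, histogram
mean — the kind of subset wrapper selection finds on phantoms) the same
pipeline recovers the phantom at J ≈ 0.99/0.94/0.90 (CSF/GM/WM), which the
feature-selection tests exercise. This mirrors the source method's own
observation that using all features degrades clustering and that its
headline results use a GA-selected subset.

Green tests on the phantom therefore establish: correctness of each stage's
arithmetic against independent oracles, determinism, the geometry of the
offset set, membership algebra, the PVE rule, and tissue recovery under
discriminative feature subsets. They do not establish segmentation accuracy
on real MRI, which depends on texture statistics a piecewise-constant
phantom cannot reproduce.

## Known limitations

* NIfTI-1 support is minimal (single-file, scalar 3D, common datatypes,
  sform affine); it exists because no NIfTI reader is available in the
  pinned environment and is validated against nibabel in the tests.
* The 3D SOM lattice option is provided for fidelity experiments, but the
  default is the 2D 10×10 hexagonal map; the source is ambiguous about the
  exact 3D shape it used.
* FCM fuzzifier, GA operator constants and the SOM schedule constants are
  conventional defaults, not values from the source (which does not state
  them); all are configurable.
* Reproducing the published IBSR Jaccard table requires the external IBSR
  dataset and is out of scope; phantom-based surrogates stand in.
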