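---
title: "Methods: a deep-learning-radiomics pipeline for three-class liver lesion differentiation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a deep-learning-radiomics pipeline for three-class liver lesion differentiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the model

Dual-phenotype hepatocellular carcinoma (DPHCC) is an HCC subtype that
co-expresses cholangiocyte immunomarkers and behaves more aggressively than
ordinary HCC; distinguishing it preoperatively from HCC and from
intrahepatic cholangiocarcinoma (ICC) on contrast-enhanced MRI is a
three-class problem in which the discriminating signal is spread over
morphology (capsule, margin), dual-phase enhancement dynamics
(arterial-phase hypervascularity and portal-venous washout in HCC,
progressive enhancement in ICC, intermediate patterns in DPHCC) and
internal texture.  The package implements the standard
deep-learning-radiomics answer to this problem: hand-engineered 3-D
radiomics features and frozen deep embeddings of 2-D tumor crops are
extracted per contrast phase, filtered for reader reproducibility,
selected by sparse regression, optionally fused, and fed to a bank of
shallow classifiers evaluated with multiclass one-vs-rest ROC analysis.

The class coding is fixed throughout: 0 = HCC, 1 = DPHCC, 2 = ICC.

# The phantom: a stated world

The clinical images behind this design cannot be redistributed, so the
package is organized around a synthetic phantom cohort whose planted
structure covers exactly the axes the clinical problem names.  Each case
is a homogeneous background "liver" compartment (mean 100) holding one
lesion:

* a sphere with radius drawn from `lesion_radius_mm` (default 6–9 mm),
  whose boundary is displaced by a smooth random field with per-class
  amplitude `margin_irregularity` (defaults 0.4 / 2.2 / 1.2 mm — DPHCC
  most irregular);
* an optional 1.5 mm hyperintense rim ("capsule") just outside the mask,
  drawn with per-class probability (0.85 / 0.10 / 0.10 — encapsulated HCC,
  capsule-free DPHCC and ICC);
* per-class mean enhancement offsets in the arterial phase
  (+55 / +32 / +10) and portal-venous phase (−12 / +2 / +26), i.e.
  hypervascular HCC with washout, hypovascular ICC with progressive
  enhancement, DPHCC in between;
* an interior Gaussian texture field with per-class correlation length
  (2 / 3.5 / 5.5 mm) and common SD 12, mean-centred over the lesion so the
  planted enhancement offset is exact up to white noise;
* white acquisition noise (SD 5) everywhere.

The native grid is 32×32×24 voxels at 1×1×2 mm — anisotropic like an
abdominal MRI stack — and the preprocessing resamples to 1 mm isotropic.
These values were chosen once as a realistic desk-scale world; they are
not estimates of any clinical cohort, which also means a green end-to-end
test establishes that the pipeline recovers *planted* class structure,
not that it attains any clinical accuracy.  Setting every per-class field
equal (`phantom_spec_null()`) removes all label information and defines
the chance-level control.

Two-reader delineation variability, needed by the ICC filter, is simulated
by perturbing the mask with a smooth offset field applied to its signed
Euclidean distance transform: typical boundary displacement is about
0.6 × `reader_jitter_mm` and hard-bounded by `reader_jitter_mm` (default
1 mm; Dice ≈ 0.95–0.98 against the original at a 10 mm radius).  The
intra-reader repeat mask uses the same scale with a different seed.
Perturbation acts on delineation only — intensities are untouched.

# Preprocessing

The fixed order is: linear 0–255 normalization (a constant volume maps to
zeros — the only divide-by-zero-free choice), classical CDF histogram
equalization with 256 bins (8-bit convention; applied per volume, not per
slice), isotropic resampling via separable linear interpolation (nearest
neighbour for masks, so they stay binary), and per-VOI fixed-bin-width
discretization, `level = floor((x − min)/5) + 1`.  New grid dimensions
follow `round(dim × spacing / target)`.  Discretization is invariant to
adding a constant to the VOI, which the tests assert.

# The radiomics engine

The feature vector per phase is 14 shape features plus 93
intensity/texture features on each of 19 image types — original plus 18
derived: 8 one-level stationary Haar wavelet sub-bands (undecimated, so
outputs keep the input shape), Laplacian-of-Gaussian at σ = 2, 3, 4, 5 mm,
four monotone intensity transforms (square, square root, logarithm,
exponential, each rescaled back into 0–255), gradient magnitude, and
per-slice 8-neighbour local binary patterns.  The stated filter set of
wavelet + LoG alone yields 1223 features; the 18-type bank reproduces the
canonical total of 1781 = 14 + 19 × 93, and the set is config-switchable
(`radiomics_config(filters = ...)`), with `filters = list()` giving the
reduced 107-feature original-image configuration used by the fast
end-to-end tests.

Texture matrices follow the IBSI-style definitions:

* **GLCM** (24 features): symmetric co-occurrence counts at distance 1
  over the 13 unique 3-D directions, each normalized; features are
  computed per direction and averaged (matrix merging is the other
  defensible aggregation; averaging was chosen and pinned).
* **GLRLM** (16): maximal runs per direction, features averaged over the
  13 directions.
* **GLSZM** (16): 26-connected equal-level zones (labelled via a graph
  components pass).
* **GLDM** (14): dependence = number of in-mask 26-neighbours within
  α = 0 levels, tabulated from d = 0; feature formulas use j = d + 1 so
  small/large-dependence denominators never vanish (equivalently, the
  centre voxel is counted).
* **NGTDM** (5): per-level counts, probabilities and summed absolute
  differences from the mean in-mask neighbour level.

Every builder is checked against an independent brute-force enumeration
(pair counting, run walking, flood fill, neighbour scans) on hundreds of
random ≤ 4×4×4 VOIs, and the partition identities (GLCM sums to 1,
Σ j·R = N, Σ s·S = N, Σ D = N, Σ p = 1) on 1000 more.

Degenerate single-level VOIs make correlation-type denominators vanish;
those features (GLCM Correlation, Imc1, MCC, ...) return 0
deterministically.  NGTDM Coarseness on a flat VOI returns the customary
1e6 cap.

**Shape.**  Surface area comes from a marching-tetrahedra iso-surface at
0.5 of the mask indicator smoothed with a σ = 0.7 voxel Gaussian: raw
binary marching overestimates curved surfaces by ~25% (staircase), while
smoothing recovers the analytic sphere area to within ±1% at radii
8–12 mm (tests assert ±2%).  Smoothing pulls curved iso-surfaces slightly
inward, so mesh *volume* instead uses the unsmoothed midpoint mesh
(within ~2% of the analytic sphere; tests assert ±3%).  Axis lengths come
from PCA of the voxel coordinates (4√λ), maximum diameters from pairwise
distances between boundary voxels.

# Max-ROI slices and deep features

The Max-ROI rule picks the axial slice with the largest tumor area (ties:
lowest index), takes offsets −2…+2, and crops each slice to the tumor's
minimum bounding rectangle (no margin is added; boxes are 0-based,
half-open, axial = third grid axis).  A thin lesion whose offset slice
holds no tumor is substituted by the nearest tumor-bearing slice in that
direction with a warning — an automated pipeline cannot hand-exclude such
cases, and this keeps the 5-crop contract.  Crops are taken from the
normalized/equalized volumes and exported as 8-bit grayscale PNGs.

The deep-feature stage treats the published penultimate-layer dimensions
as contracts: ViT 1024, vgg19 4096, googlenet 1024, inception_v3 2048
(input 224² / 299²).  No deep-learning runtime is available in the
offline build, so `weights = "pretrained"` raises an explicit error and
the embeddings are served by a deterministic seeded filterbank: bilinear
resize to the backend input size, min-max standardization with fixed
channel constants (0.45 / 0.225), 24 zero-mean 5×5 convolutions at a
64×64 working resolution, ReLU, 4×4-grid average+max pooling, and a
seeded tanh random projection to the contracted dimension.  This is a
fixed random feature map — reproducible across platforms, sensitive to
image content, and honest about not being a trained network; no gradient
training is in scope.  The five slice embeddings of a case-phase are
mean-pooled (permutation-invariant; max pooling is available).

# Selection, fusion, modelling, evaluation

* **ICC filter**: ICC(2,1) — two-way random effects, absolute agreement,
  single rater — per feature for inter-reader (reader 1 vs 2) and
  intra-reader (reader 1 vs repeat) pairs over the reproducibility cases;
  retained iff both ≥ 0.8.  Zero-variance features have undefined ICC and
  are dropped with a warning.  The filter applies to radiomics features,
  the delineation-sensitive modality.
* **Z-score**: training-rows-only mean/SD (sample SD convention: train
  {1,2,3} → {−1,0,1}); the same affine transform is applied to test rows.
* **LASSO**: one multinomial L1 path (glmnet) rather than three
  one-vs-rest fits — one model, one λ.  Stratified 5-fold CV of the
  multinomial deviance; λ_1se = the largest λ within one SE of the
  minimum (the sparsest acceptable model); selected features have any
  nonzero class coefficient at λ_1se.  Tiny cohorts shrink the fold count
  to the smallest class size.  An empty selection falls back to an
  intercept-only prior model with a warning.
* **Fusion**: per-modality selection first, then concatenation
  (radiomics block first), then a greedy scan in that fixed order
  dropping any feature with training Spearman |ρ| > 0.9 against an
  already-kept feature.  The fixed order makes the prune deterministic;
  the post-hoc invariant max |ρ| ≤ 0.9 is asserted in tests.
* **Classifiers** (defaults pinned): SVM = RBF C-SVM (C = 1, γ = 1/(p·v̄)),
  dual solved exactly with quadprog, one-vs-one with Platt-scaled pairwise
  probabilities coupled by averaging; LR = ridge multinomial (glmnet,
  λ = 0.01); RF = 500 bagged CART trees with per-node √p feature
  subsampling; DT = single CART, unlimited depth.  The environment has no
  SVM/tree package, so these are built in-package and verified on
  separable toy data.
* **Split**: internal test size = ceil(0.2 n), apportioned across classes
  by largest remainder of proportional quotas (306 cases at 108/102/96
  reproduce the canonical 244/62), seeded shuffle within class; cases
  tagged `external` never enter training.
* **Evaluation**: per-class one-vs-rest AUC by the rank statistic
  (tie-corrected), macro = unweighted mean over present classes (absent
  classes are reported NA with a warning), micro = AUC over the pooled
  (case, class) indicators, macro-averaged precision/recall/F1, and a
  stratified case-level bootstrap percentile 95% CI (default 2000
  replicates) for the macro-AUC.

# Numerical choices and determinism

All randomness (phantom, reader jitter, splits, CV folds, bootstrap,
forests, filterbank weights) flows through explicit seeds and a
save/restore RNG wrapper, so cohorts and the experiment summary are pure
functions of config + seeds; the test suite asserts byte-identical
summary CSVs across reruns.  Convolutions use reflect padding; logs use
base 2 with zero-probability terms dropped; LoG kernels are zero-sum by
construction and scale-normalized by σ².

# Scale-down choices in the tests

The oracle and invariant sweeps run at full prescribed size (200 and 1000
random VOIs).  The end-to-end recovery criterion (n = 300, macro-AUC
≥ 0.9 on the internal test; null cohort in [0.4, 0.6]) runs the
reduced original-image radiomics configuration (107 features/phase)
rather than the 1781-feature bank so the whole suite stays inside a
desktop CPU budget; the full configuration is exercised for structure and
count on single cases.  The planted enhancement differences carry most of
the class signal either way, so the reduction does not weaken what the
criterion establishes about the selection/modelling/evaluation chain.

# Known limitations

* The phantom has one lesion, one homogeneous background compartment and
  no MRI physics (no bias fields, no k-space artefacts); realism claims
  stop at the planted axes.
* The deep backends are frozen random feature maps, not pretrained
  networks; their discriminative power is far below a real vgg19, and
  fusion results should be read accordingly.
* Mesh volume and surface area come from two meshes (unsmoothed and
  smoothed) chosen for accuracy on smooth bodies; very thin or
  single-voxel-thick masks fall back to voxel-count volume.
* Whether the original workflow aggregated texture matrices by merging or
  feature-averaging, equalized per slice or per volume, and which
  precision/recall averaging it reported are unstated there; the choices
  made here (feature-averaging, per-volume, macro) are pinned and
  documented.
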