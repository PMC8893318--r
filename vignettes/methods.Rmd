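---
title: "Methods: morphometrics, radiomics and nested evaluation in aneufuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: morphometrics, radiomics and nested evaluation in aneufuse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

aneufuse estimates intracranial-aneurysm rupture risk by fusing four
feature groups — mesh morphometrics, a radiomics battery, two deep-feature
scores and two clinical covariates — into a 136-column table, selecting a
consensus subset, and benchmarking five classifiers under nested
cross-validation. This vignette records the scientific choices behind each
stage and why they were made. Everything here runs on synthetic phantoms;
no clinical data are required.

## The phantom cohort

Real angiographic cohorts cannot ship with a package, so the generator in
`generate_cohort()` defines the study conditions: a randomly oriented
ellipsoidal lesion (semi-axes 2.5–7 mm) perturbed by a degree-2 real
spherical-harmonic lobulation (amplitude up to 0.3 of the local radius),
rendered three ways from the same implicit surface — a binary mask on a
48³ grid at 0.5 mm, a noisy smoothed intensity volume (foreground 100,
background 10, Gaussian sd 5 after a σ = 1 smoothing), and a watertight
surface mesh obtained by radially deforming a subdivided icosahedron
(the surface is star-shaped by construction, so the deformation cannot
self-intersect).

Labels carry a planted morphology signal: rupture log-odds are linear in
the cohort-standardized maximum semi-axis (weight 3) and lobulation
amplitude (weight 2), with an intercept bisected so the empirical
prevalence lands near the target. The two ground-truth drivers — size and
irregularity — mirror the risk factors the clinical literature agrees on,
and because they are knowable here, recovery of the signal is a testable
end-to-end property rather than a hope.

```{r}
library(aneufuse)
params <- phantom_params(seed = 42L)
cohort <- generate_cohort(125L, params)
```

One caveat worth stating plainly: the phantom is deliberately simple. Its
Bayes ceiling is finite (the labels are stochastic given the morphology),
and the lobulation amplitude is only indirectly visible to the extracted
features, so measured discrimination is bounded away from 1 even for an
ideal model.

## Morphometrics (25 features)

The mesh module computes oriented-bounding-box length/width/height (PCA
axes of the vertex cloud — pose-invariant by construction), surface area,
divergence-theorem enclosed volume, and summary statistics of five
discrete curvature scalars. Gaussian curvature comes from the angle
deficit with Meyer-style mixed Voronoi areas, mean curvature from the
cotangent Laplacian; principal curvatures are recovered as
κ₁, κ₂ = H ± √(H² − K). Where the two independent discrete estimates
disagree (H² < K, typical near umbilic vertices), the discriminant is
clamped to zero and the reported K is recomputed as κ₁κ₂ so that the
algebraic identities K = κ₁κ₂ and H = (κ₁ + κ₂)/2 hold at every vertex;
the raw deficits are retained separately so the Gauss–Bonnet sum (4π on a
closed genus-0 surface) stays exact. Curvedness √((κ₁² + κ₂²)/2) is the
fifth scalar — a magnitude measure that, unlike K or H, does not vanish
on saddle-shaped necks.

Meshes must be watertight and consistently oriented; `orient_faces()`
repairs winding by flood-fill across shared edges and flips the global
orientation when the signed volume is negative.

## Radiomics (107 features)

The battery follows the Imaging Biomarker Standardization Initiative
definitions: 18 first-order, 14 shape, and 24/16/16/5/14 features from
the GLCM, GLRLM, GLSZM, NGTDM and GLDM texture matrices. Preprocessing is
fixed and documented rather than configurable per study: isotropic
resampling to 0.5 mm (trilinear for intensities, nearest-neighbour for
the mask), linear rescaling of the image range onto [0, 100], and
fixed-bin-count discretization with 32 bins. Thirty-two bins keeps the
matrices dense on lesion-sized regions of interest (a few thousand
voxels) while preserving enough contrast for the difference-based GLCM
statistics; it is the midpoint of the 16–64 range in common radiomics
practice.

Texture matrices aggregate all 13 unique 3D directions into a single
merged matrix (GLCM symmetrized) instead of averaging per-direction
features. The merged strategy is the better-conditioned choice on small
regions — per-direction matrices are sparse and their feature averages
noisy — and it makes the matrix builders exactly testable against
brute-force pair/run/zone enumeration oracles, which the test suite does
exhaustively on small regions.

```{r}
case <- cohort$cases[[1]]
feats <- extract_case_features(case$volume, case$mask, case$mesh)
lengths(feats)   # morph 25, radiomics 107, deep 2
```

## Deep features (2 scores)

The trained 3D convolutional network is out of scope — it needs a GPU and
a clinical training set — so the deep branch is specified as a contract:
any function `(volume, mask, seed) -> 2 raw scores` can be plugged in
(`resolve_extractor()` also wraps external commands). Three output
variants are provided: the raw scores, their logistic transform, and the
thresholded transform (boundary 0.5 mapped to 1). The bundled
`stub_extractor()` is deterministic and intentionally *not* a learned
model; it exists so the fusion, selection and evaluation stages are
exercised end-to-end with the correct arity. Conclusions about deep
features themselves should not be drawn from the stub.

## Fusion and consensus selection

`fuse_features()` aligns the four groups by case id (misalignment is an
error naming the offending cases) into 25 + 107 + 2 + 2 = 136 columns.
Selection is a two-step consensus: per fold, a random forest and a
gradient-boosted-tree model are fit on the standardized training split,
and a feature is retained when its importance exceeds that method's mean
importance in *both* models; the per-fold intersections are merged over
the 8 folds into M (Step 1). Each method's importances are then
accumulated over folds, the top ⌈|M|/2⌉ features per method give M_r and
M_x, and the final subset is N = M_r ∩ M_x (Step 2), so
N ⊆ M_r, M_x ⊆ M and |M_r| = |M_x| = ⌈|M|/2⌉ always hold.

Two thresholds in this procedure are conventions, stated here because no
single standard exists: "selected" means importance strictly above the
per-method mean (the common default when no cutoff is given), and ties in
the accumulated ranking break lexicographically by feature name so the
result is deterministic. Degenerate cohorts fall back loudly: an empty M
to the full feature set, an empty N to M_r ∪ M_x, each with a warning.

## Nested evaluation

`nested_cv()` runs stratified 8-fold outer cross-validation; within each
outer training split the scaler is re-estimated, the consensus selection
is re-run, and a 7-fold inner grid search tunes each classifier by mean
F2. Seven inner folds keeps at least one positive per inner fold at
cohort sizes around a hundred. Five classifiers are benchmarked — RBF
SVM, ridge logistic regression, random forest, gradient boosting and
KNN — over small exhaustive grids documented in `default_grids()`. The
headline metric is F2 (recall weighted twice as heavily as precision,
appropriate when missing a rupture is costlier than a false alarm),
reported alongside accuracy, Mann–Whitney AUC, precision, recall and a
pointwise-mean ROC on a common 101-point false-positive-rate grid.

Re-running selection inside every outer fold is the leakage-free
protocol and the package default. The alternative reading — one global
subset selected once from the full fold assignment — is available as
`global_selection = TRUE` (and `--global-selection` on the command line)
for comparison; it is slightly optimistic because the held-out fold
participated in choosing the columns.

```{r}
tab <- cohort_feature_table(cohort)
report <- nested_cv(tab, classifier_spec("knn"), seed = 42L)$knn
report
```

## Limitations

The stub extractor contributes no learned information; the phantom's
texture is homogeneous apart from smoothing and noise, so the texture
families mostly encode noise statistics here; and absolute metric values
on phantoms say nothing about clinical performance — the package's claims
are about the correctness and leak-freedom of the pipeline, which is what
the oracle-based test suite pins down.
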