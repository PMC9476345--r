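---
title: "Trabecular morphometry and radiomics of subchondral bone MRI"
author: "boneRadiomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trabecular morphometry and radiomics of subchondral bone MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boneRadiomics)
```

## The problem

Knee osteoarthritis (OA) remodels the subchondral trabecular bone long
before radiographs change. On a balanced fast-field-echo (BFFE-like) 3D
MRI sequence, marrow is bright and trabeculae are dark, so the bone
microstructure in the four weight-bearing subchondral regions — lateral
and medial femoral condyle (LF, MF) and lateral and medial tibial
plateau (LT, MT) — can be quantified from the image directly. This
package implements the full quantitative chain for that setting:

1. **Morphometry**: adaptive binarization into bone/marrow, per-slice
   Euclidean distance transform sampled on morphological skeletons, and
   the four structural parameters BV/TV, Tb.Th, Tb.Sp, Tb.N.
2. **Radiomics**: 93 features per region and image type — 18 first-order
   statistics plus 75 texture features from the GLCM, GLRLM, GLSZM,
   NGTDM and GLDM matrices — on the original image and on
   Laplacian-of-Gaussian (LoG) filtered images at σ = 1.0, 1.5, 2.0,
   2.5 mm.
3. **Selection**: z-scoring, LASSO-penalized logistic regression with a
   cross-validated penalty, Mann–Whitney retention at two-sided
   P < 0.05, and |r| > 0.90 correlation pruning.
4. **Classification**: SVMs (linear, RBF, cubic, sigmoid kernels) for
   the four severity contrasts (normal vs. OA, mild vs. advanced,
   normal vs. advanced, normal vs. mild), evaluated by pooled
   out-of-fold ROC/AUC with stratified-bootstrap confidence intervals
   and a Youden-threshold metric panel.

Because clinical MRI volumes of this kind are not freely
redistributable, the package ships a synthetic-data module whose
phantoms have analytically known parameters; every downstream stage is
validated against those ground truths.

## Conventions

Arrays are indexed (row, column, slice); spacing is stored per axis in
mm in the same order. The default grid is the acquisition resolution
0.234 × 0.234 mm in-plane with 1.5 mm slices — 6.4× anisotropic.
Trabecular bone is **dark**, marrow **bright**; binarization is told
which phase is bone via `boneIsDark`.

## Morphometry

`binarizeAdaptive()` thresholds each voxel at the mean of the in-mask
intensities inside a local window (default 15 × 15 voxels in-plane,
one slice deep) minus an `offset`. Ties go to marrow.

* **Window**: must exceed the width of the thickest structure; a window
  lying wholly inside one phase has its mean at that phase's level.
* **Offset** (default 10 intensity units ≈ 2 noise SDs at the default
  synthetic contrast of 100): guards exactly that situation — with a
  zero offset, noise flips about half the voxels of any pure-marrow
  window. Set `offset = 0` for noiseless data, where the two-level
  field is recovered exactly.
* Regions smaller than the window fall back to a global in-mask mean
  threshold, with a warning.

`localThickness()` works per slice: the 2D Euclidean distance transform
of the phase (distance to the nearest opposite-phase pixel) is
multiplied by the 2D morphological skeleton (Zhang–Suen thinning), and
thickness at a skeleton pixel is defined as **2 × distance ×
in-plane spacing — a diameter**. Two consequences worth knowing:

* A plate of even width w voxels measures exactly w; odd widths measure
  w + 1, i.e. quantization is at most one in-plane pixel.
* The computation is 2D by design: with 6.4× anisotropic voxels a 3D
  distance would be dominated by the slice thickness. A 3D variant
  would only be meaningful after isotropic resampling, which is
  deliberately not performed so that morphometry and radiomics see the
  identical grid.

`trabecularParams()` then reports BV/TV (bone voxels over region
voxels), Tb.Th (mean skeleton thickness of the bone phase), Tb.Sp (the
same for marrow) and Tb.N, **defined** as (BV/TV)/Tb.Th. That
plate-model definition reproduces the reference group-level panel
(`referenceTrabecularStats()`) to within 0.01 /mm in every cell; eleven
of the twelve cells agree within the printed rounding of the inputs,
and the remaining cell is consistent with Tb.N having been averaged
per subject (a mean of ratios rather than a ratio of means).

On noisy plate phantoms (5% noise, 64³ voxels, thickness 0.4–1.2 mm ×
separation 0.8–2.4 mm at 0.2 mm in-plane spacing) the pipeline recovers
BV/TV within 0.02 absolute and Tb.Th/Tb.Sp with a median error under
one in-plane pixel; `tests/testthat/test-acceptance.R` re-runs that
sweep. The grid uses 0.2 mm in-plane spacing because a 0.4 mm plate is
exactly at the two-pixel resolvability limit there; at the default
0.234 mm it would be unresolvable and the generator rejects it.

Two caveats on thickness. First, the diameter convention and the
distance-ridge skeleton mean the package measures the classical
"2 × EDT on the medial axis" quantity, not the maximal-covering-sphere
(Hildebrand) thickness; the two coincide on plates, rods and discs but
the covering-sphere value is strictly larger on branched shapes. The
test suite checks equality where the notions coincide and the
dominance inequality elsewhere. Second, at the clinical in-plane
resolution the reference Tb.Th of ≈ 0.16 mm is sub-voxel; measured
thickness on such structures saturates near the 2-pixel quantization
floor, so in realistic synthetic cohorts the group signal travels
through BV/TV (and age), not through the saturated thickness values.

## Radiomics

Intensities are re-anchored per (region, image type) at the in-mask
minimum and discretized with a **fixed bin width** (default 25
intensity units). Texture matrices are built in compiled code:

* GLCM: symmetric co-occurrence over the 13 unique distance-1 3D
  directions, features computed per direction and averaged;
* GLRLM: per-direction run lengths, averaged the same way;
* GLSZM: 26-connected equal-level zones;
* NGTDM: 26-neighborhood gray-tone differences;
* GLDM: 26-neighborhood dependence counts with tolerance α = 0.

Out-of-mask voxels are excluded everywhere — they break runs, separate
zones and are never zero-padded into neighborhoods. The registry is the
standard six-class default panel (18/24/16/16/5/14 = 93; entropies in
log2; kurtosis not excess-corrected; no StandardDeviation in the
first-order set, no SumVariance in the GLCM set, MCC included). Every
matrix builder and all 75 texture formulas are verified against an
exhaustive brute-force enumeration written independently in the test
helpers, to 1e-10, on dozens of random level maps.

Degenerate inputs return documented constants instead of NaN (e.g.
maximum probability 1 and contrasts/variances 0 on a constant region;
GLCM correlation and MCC defined as 1 there), so downstream selection
never silently drops subjects. Note that on a *finite* constant region
the GLDM dependence variance is legitimately nonzero: boundary voxels
have smaller neighborhoods than interior ones.

The LoG filter interprets σ in millimetres and converts it per axis, so
the physical scale is honored on the anisotropic grid. It is built from
sampled Gaussian and second-derivative kernels (mirror boundary,
zero-sum correction so constants map to exactly zero) and is
σ²-normalized; a bright blob of matching scale yields its most negative
response at the blob center. With the default bin width, coarse-σ LoG
images of fine-grained structure can discretize to a single level; the
affected feature block then takes its degenerate values and is dropped
later as a constant column — a warning is logged rather than an error
raised.

## Synthetic data

`platePhantom()` builds alternating bone/marrow slabs with analytic
ground truth (BV/TV = t/(t+s), Tb.Th = t, Tb.Sp = s). The mask band
along the slab axis covers a whole number of pattern periods — with
partial periods the voxelized bone fraction is biased by up to ~0.03 at
64³, which would contaminate recovery tests with a generator artifact.

`gaussianFieldPhantom()` thresholds a smoothed Gaussian random field at
the quantile that yields exactly the target BV/TV inside the mask, so
the BV/TV truth holds by construction to one-voxel quantization.

`generateCohort()` draws per-subject, per-region parameters from
group-level normal distributions; the defaults are the reference panel
(`referenceTrabecularStats()`, three severity groups of 32/27/29
subjects) and the reference age structure (37.2 ± 9.4 / 56.5 ± 9.9 /
64.7 ± 9.9 years). Regions are drawn independently given the group
because no cross-region covariance is available to calibrate against.
Each region block is a correlated-field phantom with the drawn BV/TV
and a correlation scale tied to the drawn thickness/separation.
Additive Gaussian noise (default SD 5 on a contrast of 100) stands in
for acquisition noise; Rician amplitude statistics, cartilage, and
anatomically realistic geometry are intentionally out of scope. Region
masks are interior boxes of volume comparable to the 10 mm subchondral
band, not cartilage-following surfaces — the downstream mathematics
never depends on the band's shape.

What passing tests therefore do and do not show: they validate the
*computational* chain (binarization, distance/skeleton measurement,
feature formulas, selection logic, evaluation statistics) under known
truth. They do not certify performance on clinical images, where
partial-volume effects, bias fields, and anatomy-correlated structure
are present.

## Selection and classification choices

* The cross-validated LASSO uses stratified five-fold deviance with an
  optimizer budget of 10,000 iterations (`cvIterations`); features from
  all four regions enter one pooled design matrix with region-prefixed
  names, and selected counts are then reported per region.
* The Mann–Whitney filter applies raw two-sided P < 0.05 — no multiple
  testing correction, mirroring common radiomics practice; the null
  retention rate is verified to be ≈ 0.05 by simulation.
* Correlation pruning visits pairs with |r| > 0.90 in order of
  decreasing |r| (name-pair lexicographic on ties) and drops the member
  with the larger Mann–Whitney P (lexicographically later name on P
  ties); pairs with an already-dropped member are skipped. The
  procedure is deterministic.
* Age is appended as a predictor column after selection — never subject
  to LASSO elimination — for both the radiomics and the
  trabecular-parameter models.
* SVMs: cost C = 1; RBF/sigmoid gamma = 1/(p · mean feature variance)
  computed on the standardized training fold; "cubic" is the
  polynomial kernel of degree 3. Standardization is re-fit inside each
  training fold so the held-out fold never leaks into the scaling.
  Feature selection itself is performed once on the full task data
  before cross-validation (as is conventional in this literature),
  which makes the radiomics AUCs optimistic on small synthetic cohorts.
* Metrics are pooled out-of-fold: AUC by the trapezoidal rule (equal to
  the tie-corrected concordant-pair statistic — asserted exactly in the
  tests), a stratified-bootstrap percentile CI (2000 resamples), and
  accuracy/sensitivity/specificity/F1 at the Youden-optimal threshold
  of the out-of-fold ROC. With no positive calls F1 is reported as 0
  and flagged.

## The pipeline and reproducibility

`runPipeline()` chains simulate → morphometry → features → select →
classify from a single YAML-able config (`demoRunConfig()`,
`loadRunConfig()`); every stage seed derives deterministically from the
one global seed, and a rerun with the same config reproduces
params.csv, features.csv, selection.json and report.json byte for
byte. The demo scale — 24 subjects, 32³-voxel region blocks — runs in
about a minute on one core and is the configuration exercised by the
acceptance tests; the full reference scale (88 subjects) is a config
change, not a code change.

```{r demo, eval = FALSE}
cfg <- demoRunConfig(seed = 7)
res <- runPipeline(cfg, outDir = "run1")
res$reports$normal_vs_oa$panel
```

On demo-scale synthetic cohorts the trabecular-parameter model shows
the expected ordering — normal vs. advanced is the easiest contrast
(largest age and BV/TV separation), mild vs. advanced and normal vs.
mild the hardest — while the radiomics model, with 1860 candidate
features selected on the full data, separates the small cohorts
essentially perfectly. Both behaviors are properties of the design at
this sample size and are computed, not asserted, by
`scripts/acceptance.R`.

## Known limitations

* 2D-slice thickness, diameter convention, and the saturation of
  sub-voxel structures (above) are inherent to the method at clinical
  resolution.
* The additive-Gaussian noise model understates the Rician floor of
  low-SNR magnitude MRI.
* The exact membership of the 93-feature panel follows the standard
  toolkit defaults; a study with a bespoke feature list would need the
  registry adjusted.
* No DICOM ingestion, registration, or resampling: NIfTI volumes with
  consistent geometry are the contract, enforced by `validatePair()`.
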