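# boneRadiomics

Quantitative analysis of subchondral trabecular bone in 3D knee MRI,
for researchers studying osteoarthritis (OA)-related bone
microstructure. On bright-marrow/dark-trabeculae (BFFE-like) volumes
with per-region label masks (lateral/medial femoral condyle, LF/MF;
lateral/medial tibial plateau, LT/MT), the package computes:

* **Trabecular morphometry** — local adaptive binarization, per-slice
  Euclidean distance transform sampled on morphological skeletons, and
  the structural panel
  BV/TV (bone volume fraction), Tb.Th and Tb.Sp (mean local thickness
  of the bone and marrow phases, in mm, as 2·EDT on the skeleton), and
  Tb.N = (BV/TV)/Tb.Th (1/mm);
* **Radiomics** — 93 features per region × image type: 18 first-order
  statistics and 75 texture features from the GLCM, GLRLM, GLSZM,
  NGTDM and GLDM matrices, on the original image and on
  Laplacian-of-Gaussian filtered images (σ = 1.0, 1.5, 2.0, 2.5 mm,
  interpreted in physical units on the anisotropic grid);
* **Feature selection** — z-scoring, LASSO-penalized logistic
  regression with five-fold cross-validated penalty, Mann–Whitney
  retention (two-sided P < 0.05), and |r| > 0.90 correlation pruning;
* **Classification** — SVMs (linear / RBF / cubic / sigmoid) for the
  four severity contrasts, with pooled out-of-fold ROC/AUC,
  stratified-bootstrap 95% CIs, and a Youden-threshold
  accuracy/sensitivity/specificity/F1 panel, for both radiomics-based
  and trabecular-parameter-based models.

A synthetic-data module generates plate and correlated-field phantoms
with analytically known parameters, and multi-subject cohorts with
reference group/age structure, so the entire chain is testable without
clinical data. Texture matrices and 2D thinning are implemented in
C++ (Rcpp); NIfTI I/O via RNifti; distance transforms via EBImage;
LASSO via glmnet; SVMs via e1071.

## Worked example

```r
library(boneRadiomics)

# a plate phantom: 0.5 mm plates, 1.5 mm gaps, 5% noise
ph <- platePhantom(phantomSpec(plateThicknessMm = 0.5,
                               plateSeparationMm = 1.5,
                               shape = c(64, 64, 8), noiseSd = 5,
                               seed = 9))
ph$truth
#>   bvtv tb_th_mm tb_sp_mm tb_n_per_mm
#> 1 0.25      0.5      1.5         0.5

subjectMorphometry(ph$volume, ph$mask)
#>   region      bvtv tb_th_mm tb_sp_mm tb_n_per_mm
#> 1     LF 0.2352941    0.546 1.635728   0.4309416
```

Measured BV/TV recovers the analytic 0.25 within 0.015 and both
thickness values land within one in-plane pixel (0.234 mm) of truth —
the quantization floor of a distance-transform measurement on a
~2-pixel plate.

```r
# features of one region on the original image: the 93-feature panel
f <- extractFeatures(ph$volume, ph$mask, codes = "LF",
                     filterCfg = filterConfig(logSigmasMm = numeric(0)))
length(f)                       # 93
f["LF|original|firstorder|Mean"]
#> 176.5  (bright marrow dominates a ~25% bone region)

# the full demo pipeline: 24 synthetic subjects, 4 regions, 5 image
# types, selection + SVM evaluation for all four severity contrasts
res <- runPipeline(demoRunConfig(seed = 7), outDir = "run1")
res$reports$normal_vs_advanced$panel
#>        metric radiomics trabecular
#> 1         auc     1.000      0.844
#> ...
```

The run directory contains `params.csv` (per subject × region
morphometry), `features.csv` (subjects × 1860 features),
`selection.json` (per-task audit trail of the LASSO → Mann–Whitney →
pruning chain) and `report.json` (per-task metric panels and ROC
points). Reruns with the same config are byte-identical.

A thin command-line wrapper over the same functions is provided:

```sh
Rscript inst/scripts/oabone.R simulate --out cohort_dir --seed 1
Rscript inst/scripts/oabone.R run --config cfg.yaml --out run_dir
```

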