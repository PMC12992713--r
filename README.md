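# f19rad

Repeatability analysis of radiomic features in fluorine-19 (¹⁹F) MRI.

¹⁹F MRI is background-free: tissue contains essentially no fluorine, so the
magnitude signal is directly proportional to the concentration of ¹⁹F nuclei
delivered by a perfluorocarbon tracer (PFPE or PFCE nanoemulsions). That makes
the modality attractive for quantitative imaging — but before radiomic
features extracted from ¹⁹F scans can serve as biomarkers, one has to know
which of them are *repeatable*: unchanged when the same object is scanned
twice in one session (intrasession) or days apart with complete repositioning
(intersession).

`f19rad` implements that repeatability analysis end to end, driven by a
seeded synthetic-acquisition generator that emulates the relevant study
conditions (agarose tube phantoms at two ¹⁹F concentrations, an in-vivo-like
liver/tumor/reference scene, magnitude (Rician) noise, 64 × 64 × 12 grids at
0.55 × 0.55 × 1.5 mm³ voxels):

* **Simulation** — cylinder phantoms rendered with subvoxel partial volume,
  Rician noise, pure-noise calibration scans, session perturbations (rigid
  repositioning, B1-like bias fields, gain and noise drift), a detection-limit
  calibration series.
* **Segmentation** — slice-wise noise floor `N_average` from noise scans, the
  two-step semi-automatic scheme (threshold at `3 × N_average`, then
  prior-guided ROI delineation), reader-perturbation re-reads, and study
  bookkeeping manifests.
* **Feature engine** — image filters (square, square-root, logarithm,
  exponential, gradient, Laplacian-of-Gaussian, one-level Haar wavelet),
  intensity discretization, 18 first-order features, 14 mesh-based 3D shape
  features honoring anisotropic spacing, and the five gray-level texture
  families (GLCM, GLRLM, GLSZM, GLDM, NGTDM) with compiled kernels.
* **Agreement statistics** — the two stability criteria

  ```
  CCC = 2 σ₁₂ / (σ₁² + σ₂² + (μ₁ − μ₂)²)                      (concordance)
  NDR = 1 − (1/n) Σᵢ |Testᵢ − Retestᵢ| / (Max − Min)          (dynamic range)
  ```

  with a feature called **stable** iff CCC ≥ 0.85 and NDR ≥ 0.90; plus
  Bland–Altman limits with an expected-CCC reference band, ICC(2,1) for
  reader agreement, Jensen–Shannon histogram similarity, and Kruskal–Wallis /
  Benjamini–Hochberg distribution comparisons.
* **Pipeline** — `run_study()` composes everything into a deterministic
  simulated study with per-class CCC summaries, stable-count tables,
  stable-set intersections across experiments, and threshold sensitivity
  grids.

## Worked example

```r
library(f19rad)

acq  <- acquisition_spec()                      # 64 x 64 x 12, 0.55 x 0.55 x 1.5 mm
ph   <- default_phantom("PFPE")                 # 5 tubes: 244 / 118 / 0 mM 19F
scan <- add_rician_noise(render_phantom(ph, acq), sigma = 1, seed = 11)

prof <- estimate_noise(acquire_noise_scan(acq, seed = 99))
seg  <- delineate_rois(threshold_mask(scan, prof, k = 3),
                       phantom_priors(ph), acq$spacing)
seg
#> <segment_mask> 4 segments (tube1_high, tube2_high, tube3_low, tube4_low)
#>   missing: control

ft <- extract_all(scan, seg)
ft
#> <feature_table> 4 segments x 1595 features
#>   classes: intensity=306, shape=14, texture=1275
```

The control tube carries no ¹⁹F and falls below the noise threshold, so four
segments are delineated per phantom scan — the bookkeeping the manifest
reproduces at study scale (`build_manifest()` gives 194 scans and 772
segments for the configured design). A full simulated study:

```r
res <- run_study(study_config(seed = 11))
res
#> <study_result>
#>   PFPE_intrasession      median CCC 0.796, stable 558/1595 (35.0%)
#>   PFPE_intersession      median CCC 0.458, stable 164/1595 (10.3%)
#>   PFCE_intrasession      median CCC 0.832, stable 653/1595 (40.9%)
#>   PFCE_intersession      median CCC 0.537, stable 250/1595 (15.7%)
#>   invivo_intrasession    median CCC 0.962, stable 1036/1595 (65.0%)
#>   phantom-core stable features: 146
#>   of those stable in vivo: 129 (88.4%)
```

Reading the output: repeatability is high intrasession and drops sharply
intersession; intensity (first-order) features stay the most stable class
while shape features collapse to zero stable intersession — the geometric
descriptors are the ones most sensitive to repositioning and partial-volume
changes. The `phantom-core` line counts features stable in *all four* phantom
arms, i.e. candidates for an agent-agnostic ¹⁹F radiomics signature, and most
of that core is also stable in the in-vivo-like arm.

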