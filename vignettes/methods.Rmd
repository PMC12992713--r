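---
title: "Methods: simulating and scoring ¹⁹F MRI radiomic repeatability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and scoring 19F MRI radiomic repeatability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Fluorine-19 MRI produces magnitude images whose signal is linear in the
concentration of ¹⁹F nuclei and whose background is pure noise. Radiomic
features — first-order intensity statistics, 3D shape descriptors, and
gray-level texture matrices — promise quantitative biomarkers for this
modality, but a feature is only useful if it is *repeatable*: stable between
a test and a retest acquisition of the same object. `f19rad` implements the
whole repeatability analysis as a reusable pipeline and, because raw ¹⁹F
phantom scans of this kind are not publicly available, pairs it with a
seeded synthetic-acquisition generator that reproduces the statistical
structure the analysis depends on.

# The generator and what it emulates

`render_phantom()` rasterizes analytic cylinders onto the acquisition grid
(default 64 × 64 × 12 voxels at 0.55 × 0.55 × 1.5 mm³, the ¹⁹F acquisition
geometry). Voxel values are `gain × local ¹⁹F concentration`; boundary
voxels get partial-volume fractions from 3 × 3 × 3 subvoxel supersampling of
the cylinder indicator. The default phantom holds five *identical* 0.5-mL
tubes (radius 3 mm, length 14 mm): two at 244 mM ¹⁹F nuclei, two at 118 mM,
one agarose-only control at 0 mM. Identical tube geometry matters: it makes
between-segment shape variance come only from where each tube sits on the
voxel lattice, which is precisely why shape features lose their test-retest
concordance once the sample is repositioned.

Two generator choices deserve justification:

* **Intra-tube heterogeneity.** Perfectly homogeneous tubes would make every
  texture feature a pure noise readout with no test-retest concordance at
  all. Real agarose/nanoemulsion preparations are mildly inhomogeneous, so
  each tube carries a smooth multiplicative concentration modulation (a
  four-mode random-phase cosine field in tube-local coordinates, RMS
  amplitude 15%, wavelengths 2.5–8 mm, fixed per tube by the phantom seed).
  Because the field lives in tube-local coordinates it travels rigidly with
  the tube under repositioning, as physical heterogeneity would.
* **Noise.** Magnitude reconstruction noise is Rician:
  `sqrt((S + g1)² + g2²)` with `g1, g2 ~ N(0, σ)`. Background voxels are
  then Rayleigh with mean `σ√(π/2)`, which is what the slice-wise noise
  floor estimator measures. The default gain (0.1 intensity/mM) and σ (1)
  put the weakest loaded tube at SNR ≈ 12, comfortably above the SNR > 5
  delineation requirement; the achieved SNR per concentration is otherwise
  unreported, so this is a declared default, not an inferred one.

Session conditions: an intrasession retest is the same noiseless render with
a fresh noise seed. An intersession retest applies a `session_perturbation`
— rigid repositioning, a multiplicative bias field (product of per-axis
quadratics, normalized to mean 1, amplitude = maximum fractional deviation),
a global gain factor (coil retuning) and a noise-σ drift. The pipeline draws
per-pair perturbations uniformly within ±1 mm in-plane, ±1.5 mm
through-plane, ±1°/±1°/±3°, with 5% bias amplitude and ±5% gain/noise drift
— a plausible magnitude for careful manual repositioning in a tube holder.
Perturbed geometry is re-rendered analytically rather than by resampling the
baseline render: re-rendering keeps the noiseless image exactly linear in
concentration under any rigid move, makes a one-voxel-pitch translation an
exact discrete shift, and avoids blurring only one arm of the pair with
interpolation.

The in-vivo-like scene (ellipsoidal liver with a hotter sub-lobe, ellipsoidal
tumor, cylindrical 5 mM PFPE ≙ 210 mM ¹⁹F reference tube, smoothed
multiplicative texture) is intrasession-only, matching the study design it
emulates.

**What the generator does not emulate:** pulse-sequence physics (no Bloch or
k-space simulation), chemical-shift artifacts of multi-peak tracers, motion,
reader subjectivity (delineation is deterministic given the threshold mask),
and scanner-to-scanner variation. Passing tests therefore demonstrate that
the *analysis* behaves correctly under the modeled statistical structure,
not that any particular scanner achieves these numbers.

# Segmentation

`estimate_noise()` computes the per-slice mean (`N_average`) and SD of a
pure-noise scan. `threshold_mask()` keeps voxels with intensity
≥ `k × N_average` of their slice, `k = 3` by default; ties keep the voxel.
For the simulated Rayleigh background `3 × mean ≈ 5.7 × SD`, consistent with
the claim that the threshold exceeds five noise SDs — verified for this
noise model only. `delineate_rois()` stands in for the blinded observer:
26-connected components of the threshold mask are assigned to the nearest
expected-region prior within its match radius; unmatched components are
dropped as artifacts (components below 3 voxels are discarded as noise
specks), several components matching one prior merge, and unmatched priors
are recorded as missing segments — the control tube is the standing example.
A degenerate rule: if the measured noise floor is exactly zero (noiseless
acquisition), the threshold would keep the empty background, so any strictly
positive voxel is taken as signal instead.

# The feature engine

Filters follow the reference radiomics definitions, with range-normalizing
constants (`m = max |x|`): square `x²/m`, square-root `sign(x)√(|x| m)`,
logarithm `sign(x) m log(1+|x|)/log(1+m)`, exponential `exp(x log m / m)`;
gradient magnitude uses central differences over physical spacing; the
Laplacian-of-Gaussian is a sum of separable sampled-Gaussian
second-derivative kernels (σ in mm, truncated at 4σ, scale-normalized by
σ²); the wavelet is a one-level undecimated separable Haar decomposition
(subband letters apply to x, y, z in order). Haar was chosen as the simplest
orthogonal kernel since only "wavelet" is specified by the source analyses.
The default filter set — original, the four intensity maps, gradient, LoG at
σ ∈ {1, 2, 3} mm, and the eight Haar subbands — yields a deterministic
1595-column feature table (107 for the original filter including the 14
shape features, 93 for each of the 16 derived filters). Discretization
defaults to 32 fixed bins over the ROI range (robust for filtered images
with shifted ranges); fixed-bin-width mode anchors bins at the ROI minimum.
No resampling to isotropic voxels is performed; all physical quantities use
the anisotropic spacing directly.

Texture matrices are computed by compiled kernels over distance-1
(26-neighborhood) relations: symmetric GLCM counts for the 13 unique 3D
directions, run-length counts with out-of-ROI voxels breaking runs, zone
sizes as 26-connected equal-level components, dependence counts
(`1 +` neighbors within level tolerance α = 0), and neighborhood gray-tone
sums excluding voxels with no in-ROI neighbor. Directional families average
features over directions (the dominant convention) rather than merging
matrices; directions with no voxel pairs are excluded from the average.
Every family is checked against an independent brute-force enumeration
oracle on an exhaustive sweep of random ROIs up to 3 × 3 × 3 with up to 3
gray levels.

## Shape: mesh volume and surface area

Two estimators back the mesh quantities, chosen so that closed-form checks
hold for both sharp and smooth bodies:

* **Mesh volume** uses marching tetrahedra on the binary mask with midpoint
  vertex interpolation. For a linear field cut at the midpoint level, the
  inside fraction of a tetrahedron depends only on its number of inside
  corners (0, 1/8, 1/2, 7/8, 1), so the mesh volume reduces to a 256-entry
  lookup over 2 × 2 × 2 cell configurations — exact, fast and vectorizable.
* **Surface area** uses normal-weighted exposed voxel faces: each boundary
  face contributes its physical area times `|n·e|`, with the unit normal
  estimated from a Gaussian-smoothed (σ = 1 voxel) mask. For smooth
  surfaces the staircase face density per unit true area along axis `e` is
  exactly `|n·e|`, making the estimator consistent; on flat axis-aligned
  faces the weight is 1, making it exact. Plain marching-cubes areas fail
  both checks on binary masks (a 20³ cube comes out ≈ 3% low in area and a
  digitized ball plateaus near sphericity 0.91), which is why this
  construction was adopted. Crease handling: where the smoothed gradient
  magnitude drops below 0.75 × the flat-face reference — the two-plane
  cancellation value is cos 45° ≈ 0.71 — the face is treated as lying on an
  axis-aligned crease and keeps full weight, so sharp boxes are not eroded.
  The known cost is a few-percent overestimate for tightly curved surfaces
  (radius ≲ 5 voxels), a constant bias that does not affect repeatability.

Axis lengths come from the physical-coordinate inertia spectrum with the
voxel's own second moment (spacing²/12) added per axis, so a single-voxel
segment reports its physical extent instead of zero.

# Agreement statistics

The concordance correlation coefficient uses population (1/n) moments —
Lin's sample form with no bias-correction term, matching the defining
formula. Degenerate rules: identical constant vectors give CCC = 1; any
other zero-denominator pair is recorded as 0 and flagged. The normalized
dynamic range pools `Max/Min` over the union of test and retest values; a
zero-range feature has undefined NDR, is reported missing and fails the
stability call. A feature is **stable** iff CCC ≥ 0.85 *and* NDR ≥ 0.90,
boundaries inclusive; degenerate features are excluded from medians, never
imputed.

Open choices resolved here: the Bland–Altman reference band is the
equal-variance, zero-bias reduction — if both arms share variance `s²` and
bias is zero, CCC = `1 − var(d)/(2s²)`, so differences consistent with an
expected CCC of 0.85 lie within `±1.96 √(2 s²(1 − 0.85))` with `s²` the
pooled population variance (the cited construction is not printed in the
source; this reduction is our declared variant, and a Monte-Carlo test
confirms ≈95% coverage under its own assumptions). The reader ICC is the
two-way random-effects, absolute-agreement, single-measurement ICC(2,1),
the standard default when the variant is unstated. Class-versus-overall
comparisons use a two-sample rank test of the class subset against the full
pool — the class is part of the pool, a documented overlap caveat — with
Benjamini–Hochberg correction across the comparisons declared in one run.
The Jensen–Shannon divergence uses base-2 logarithms on a common equal-width
binning over the pooled range, so it is bounded by 1; the normalization
check reports the relative change (%) of mean per-segment JSD after
per-scan z-standardization over segmented voxels.

# The pipeline and its study conditions

`run_study()` is deterministic given one master seed, expanded into
per-scan noise seeds, per-pair perturbation seeds and per-experiment
phantom-texture seeds. The observation unit for CCC/NDR is the segment pair,
pooled across scans and concentrations within one experiment arm. Default
problem sizes are a desk-scale replica: 8 intrasession + 8 intersession
pairs per phantom (32 segment pairs per arm) and 2 in-vivo pairs; the
published-scale counts remain available through `study_config()` and
`manifest_config()` reproduces the full design's bookkeeping (194 scans,
772 segments). Stable sets are *intersected* across arms (the cross-arm core
is the intersection of all four phantom arms, then overlapped with the
in-vivo arm), not pooled; raw intensities are used for the main analysis and
the z-normalization variant only feeds the JSD check.

# Known limitations

* Texture repeatability depends on the declared heterogeneity model; the
  absolute stable fractions are not calibrated to any scanner, only the
  orderings (intra > inter; intensity > texture > shape under repositioning)
  are meaningful.
* The in-vivo arm has identical anatomy between arms by construction, so its
  shape features are nearly perfectly concordant — as in the emulated design,
  where in-vivo shape stability was also the highest class.
* The surface-area estimator's crease detector conflates creases with very
  high curvature (radius ≲ 5 voxels), giving small constant biases there.
* `compare_distributions()` delegates to standard tests (`shapiro.test`,
  `kruskal.test`, `wilcox.test`, `p.adjust`); it contributes contracts and
  family bookkeeping, not new statistics.
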