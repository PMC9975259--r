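---
title: "Quantifying 3D fiber architecture: model, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying 3D fiber architecture: model, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fiberarch)
```

`fiberarch` turns 3D grayscale stacks of fiber-like structures — second
harmonic generation imaging of collagen, two-photon autofluorescence of
elastin, or any comparable modality — into voxel-wise orientation fields,
three organizational metrics on the unit interval, per-sample feature
vectors, and a classification/statistics layer. This vignette explains
the model behind each stage, the parameters that matter and their
defaults, what the synthetic-data generator does and does not emulate,
and the design decisions taken where the problem was genuinely open.

## 1. Coordinates, units and containers

Stacks are indexed `(x, y, z)` with TIFF pages as z-slices. Every
geometric computation works in physical micrometres through the per-axis
voxel pitch; the default pitch `(0.402, 0.402, 0.295)` µm reproduces the
common multiphoton acquisition geometry of a 512 × 512 × 105 voxel stack
spanning 206 × 206 × 31 µm. Index-space shortcuts are never taken:
angles computed on an anisotropic grid without the pitch would be
systematically wrong, by up to `atan(0.402/0.295) − 45° ≈ 8.7°` for
diagonal fibers.

Fiber masks delimit the voxels on which metrics are defined. The default
rule keeps voxels at or above 10% of the maximum intensity after a
slice-wise 3×3 median filter; Otsu's threshold is available as an
alternative. The masking rule for real tissue is genuinely a free
parameter — published metric maps are shown on fiber regions without a
stated segmentation rule — so the applied rule is recorded in the mask
object (`threshold_rule`) and echoed into every downstream product.
Undefined voxels of a metric field are NaN, never a sentinel value
inside `[0, 1]`, so histograms stay honest.

## 2. Voxel-wise 3D orientation

Fibers are *axial* data: a fiber pointing along u is the same fiber as
one pointing along −u. All 2D plane angles therefore use the
doubled-angle representation standard in circular statistics, and all 3D
operations use dyadic (second-moment) tensors.

### Weighted vector summation

For a voxel p, every voxel q with `|q − p| ≤ R` (physically) contributes
the doubled-angle unit vector of the offset q − p, weighted by the
intensity `I(q)`. Half the angle of the resultant is the local
orientation estimate, and the normalized resultant length in `[0, 1]`
acts as a confidence: 0 on isotropic neighborhoods, approaching 1 along
an ideal straight fiber. The weight is the raw target-voxel intensity —
the simplest auditable choice; the window radius defaults to R = 2 µm
(about five lateral voxels at the default pitch), the same physical R
for all three planes so that support is comparable despite anisotropic
sampling.

Three plane angles are estimated: the azimuth θ from the xy-plane
projection (measured from +x), β from the zx-plane projection (from
+x), and γ from the yz-plane projection (measured from the −y axis and
reported in [0°, 180°)).

**Window support.** The plane angles are estimated by default from one
*spherical 3D window*, projecting each offset vector onto the three
planes (`support = "volume"`). The alternative of running the 2D
summation separately on the single slice through the voxel
(`support = "slice"`) is retained as a config option but is markedly
less accurate for oblique fibers: a fiber crossing a slice at 55° from
its normal leaves only a weakly elongated elliptical footprint (axis
ratio ≈ 1.7), and single-slice estimates carry ~10–15° errors where the
volumetric estimate is accurate to ~1–2°. The volumetric window uses
the full tubular neighborhood of the fiber in every plane.

### The polar angle

The polar angle φ is resolved from the auxiliary angles through
`tan²φ = 1/tan²γ + 1/tan²β`, which is an identity for exact
projections: with u = (x, y, z), `|tan β| = |z/x|` and
`|tan γ| = |z/y|`, so the right side is `(x² + y²)/z² = tan²φ`. The
squared tangents discard sign, so φ lives in [0°, 90°], consistent with
the canonical axial hemisphere (z ≥ 0, ties broken by y ≥ 0 then
x ≥ 0). The package validates this identity to 10⁻⁹ degrees on random
directions (in practice ~10⁻¹³).

Degenerate planes — a fiber seen end-on in some projection — are
excluded: a plane whose resultant falls below `conf_threshold` (default
0.05) does not enter the combination. If exactly one of β, γ is
defined, φ comes from it alone; if neither is, φ = 90° with zero
confidence. The combined per-voxel confidence is the geometric mean of
the three plane resultants.

### Assembling the axial vector

Two subtleties arise that the plane angles alone do not fix:

1. *Quarter-sphere coverage.* The pair (θ ∈ [0°, 180°), φ ∈ [0°, 90°])
   parameterizes only a quarter of the unit sphere: an axis and its
   xy-mirror image share the same θ and φ. The missing sign lives in β
   and γ (β < 90° exactly when z/x > 0), so the package picks the
   mirror candidate most consistent with the measured β and γ, weighted
   by their confidences. The map angle θ (what a color-coded azimuth map
   shows) stays in [0°, 180°); the disambiguated vector's true azimuth
   in [0°, 360°) is stored alongside as `azimuth` and is what the
   serialization and all downstream metrics use.
2. *Near-axial fibers.* For a fiber closer to z than to the xy plane
   (φ < 45°) the xy projection is a nearly isotropic blob and the
   direct θ estimate is noise. Because the three planes over-determine
   the axis, the azimuth is then reconstructed from the two
   well-conditioned planes via (x, y) ∝ (cot β, −cot γ) whenever the
   xy-plane confidence is the lowest of the three.

With both rules, ≥ 90% of fiber-core voxels of noise-free synthetic
straight fibers across a θ × φ grid are recovered within 5° of axial
error at 128³ (median error 1–2°); the residual tail sits at the volume
faces where the window is clipped.

## 3. The three metrics

All three metrics share a single dispersion functional. For a set of
axial unit vectors with (weighted) mean dyadic tensor T and largest
eigenvalue λ₁ ∈ [⅓, 1],

    dispersion = 1 − sqrt((3 λ₁ − 1) / 2)  ∈ [0, 1],

which is 0 for perfectly aligned axes and 1 under exact isotropy. Only
the *set over which T is taken* differs between metrics:

- **Directional variance** takes T over a spherical spatial window
  (default radius 5 µm), confidence-weighted, on-mask voxels only;
  windows holding fewer than 3 on-mask voxels are undefined.
- **Waviness** takes T along a path traced bidirectionally from each
  voxel through the orientation field (total length 10 µm by default,
  position steps of half the smallest pitch, nearest-voxel orientation
  lookup, sign chosen to minimize turning, stopping at mask exit);
  traces with fewer than 3 samples are undefined.
- **Local coverage** replaces T by a count: the fraction of on-mask
  voxels among the in-bounds voxels of the window (default radius
  5 µm). Windows are spherical in physical units; a cubic
  (Chebyshev-ball) window is available for exact box-window analytics.

One caveat worth knowing: the square root makes the functional sensitive
near isotropy. The top eigenvalue of the mean dyad of n random axes
exceeds ⅓ by O(n^−½), so even 10⁴ isotropic axes give a dispersion of
about 0.91 rather than 1.0. "Near 1" for real windows means ≈ 0.9.

The waviness tracer has a geometric operating range: the tube radius
should be comparable to or larger than the orientation window R so that
traces stay inside the mask near high-curvature crests (thin tubes lose
path samples there and bias waviness low), while very fat tubes
(radius ≫ R) degrade the orientation confidence in their interior.
Fibers two to five voxels across with crimp wavelengths well above R
are the comfortable regime — which is also the regime of the motivating
imaging application.

### 2D analysis mode

Every metric also runs on 2D images through a one-slice orientation
field with all vectors in the xy plane. This exists to quantify what
projection loses: two antiphase sinusoids whose oscillation lies along z
project onto the same straight line in an xy maximum-intensity
projection. The 3D analysis reports high variance (the two fibers cross
at up to ~115° locally) and high waviness; the 2D analysis of the
projection reports both as ≈ 0. The bundled `antiphase_pair_scenario()` generates
exactly this configuration — antiphase pair with amplitude 2 µm and
wavelength 8 µm (maximum tangent excursion ±57.6° from the axis),
radius 0.5 µm, surrounded by wavy background fibers outside the marked
ROI — and `compare_2d_3d()` runs both analyses side by side.

## 4. The synthetic-data generator

Fibers are parametric centerlines (straight, sinusoid, helix) with
anchor, unit axis, crimp amplitude A, wavelength λ_w, phase, oscillation
plane and radius ρ. Rasterization samples the centerline at half-voxel
steps and splats a Gaussian radial profile with σ = ρ/2 (smooth,
PSF-like edges that exercise thresholding realistically), combining
overlapping fibers by maximum; additive Gaussian noise is clipped at
zero and fully determined by the seed. The ground truth records each
voxel's nearest-centerline tangent (canonical axial), the fiber id, and
per-fiber arc/chord length ratio — a waviness proxy that is 1 for
straight fibers and strictly increasing in A/λ_w.

Orientation laws for random fields are uniform-on-the-sphere (isotropy
oracle) or von Mises–Fisher around a mean axis. Tissue-like presets
follow the organization reported for skin: dense concentrated collagen
(~55 fibers per field, κ = 30, small crimp) versus sparse elastin
(~8 fibers) in normal tissue; scar tissue lowers the concentration
(κ = 3), increases crimp (A up to 2.5 µm), thins the collagen and adds
elastin; the boundary ("adjacent") group is the most aligned and
straight with the sparsest elastin. The feature-level cohort simulator
(`simulate_feature_cohort()`) draws the six per-sample summaries
directly as truncated Gaussians around group means with the same effect
directions (scar: +variance and +waviness for both fiber types,
−collagen coverage, +elastin coverage; default separation 4 SD with
SD 0.05).

What the generator does *not* emulate: optical point-spread anisotropy,
photon (Poisson) noise, fiber branching and bundling hierarchies,
intensity heterogeneity along fibers, and spectral bleed-through between
channels. Tests passing on synthetic stacks therefore validate the
geometry and the estimators, not robustness to every imaging artifact.

## 5. The statistics layer

Per-sample scalarization of the six metric fields uses the mean by
default (median available); how voxel maps were reduced to specimen
values in comparable published analyses is typically unstated, so both
are first-class and the choice is recorded.

- *Two groups:* classical pooled-variance Student's t-test (Welch by
  flag). *Three groups:* one-way ANOVA with Tukey HSD post-hoc;
  significance stars at p < 0.05 / 0.01 / 0.001.
- *Collinearity screen:* full Pearson matrix, |r| ≥ 0.7 flagged,
  constant features reported as degenerate.
- *Linear discriminant:* pooled within-class covariance, equal priors
  (balanced designs), closed form. OCA is resubstitution accuracy; CVCA
  is leave-one-out with a full refit per fold. Features are z-scored
  first — LDA predictions are invariant to affine feature maps, so this
  only conditions the covariance. A singular pooled covariance gets a
  recorded ridge (ε = 10⁻⁶ of the mean diagonal, falling back to
  absolute 10⁻⁶ when the within-class scatter is exactly zero) plus a
  warning.
- *Logistic ROC/AUC:* ridge-regularized IRLS (λ = 10⁻³ on z-scored
  features, intercept unpenalized) so the fit — and the AUC — survives
  the complete separation that strongly separated cohorts produce. The
  ROC is swept over predicted probabilities with tied scores grouped;
  the trapezoidal AUC then equals the Mann–Whitney concordance with the
  half-tie convention exactly (tested to 10⁻¹²). Resubstitution scores
  are the default; `cv = TRUE` switches to leave-one-out scores, which
  is the right choice for chance baselines (resubstitution AUC of a
  six-feature logistic on 40 random labels centers near 0.72, not 0.5,
  by overfitting alone).
- *Subset search:* every subset of the six features in a size range is
  evaluated (LDA OCA/CVCA + logistic AUC) and ranked by CVCA, then AUC,
  then OCA, then smaller size, then enumeration order. The parsimony
  tie-break matters: at large effect sizes many subsets tie at
  CVCA = 100 and AUC = 1, and without it the reported "best subset"
  would be an arbitrary member of the tie class.
- *Embedding:* an exact (non-Barnes-Hut) t-SNE on z-scored features —
  perplexity-calibrated Gaussian similarities matched to a Student-t
  kernel in 2D by gradient descent with early exaggeration — entirely
  adequate for cohort-sized n and deterministic per seed.

## 6. Pipeline, provenance, determinism

`run_pipeline()` orchestrates simulate → orient → metrics → summarize →
classify → embed → report from a single config (R object, YAML or
JSON). Later stages reuse cached products keyed by an input-and-
parameter hash and fail loudly when an upstream product is missing.
Every run writes a manifest with the package version, the seed and an
md5 hash of the config (storage paths excluded, so the same analysis
hashes identically wherever it lands). Two runs with the same config
and seed produce byte-identical CSV/JSON outputs; the per-stage seeds
are derived from the global seed by stable string hashing so partial
reruns stay reproducible.

Orientation fields serialize as five float32 TIFF pages per z-slice
(θ, φ, confidence, valid mask, azimuth) plus a JSON sidecar. Metric
fields serialize as float32 pages with NaN for undefined voxels; the
float writer is a minimal uncompressed TIFF implementation included
because no installed R package writes IEEE-float TIFF pages (reading
uses the standard `tiff` package, which handles them natively).

## 7. Numerical choices and degenerate inputs

- Largest eigenvalues of 3×3 dyadic tensors use the closed-form
  trigonometric (Cardano) solution; the radicand of the dispersion
  functional is clipped at zero against rounding.
- Window memberships are decided in physical units with offsets clamped
  to the array extent; a window radius exceeding the volume simply
  means "whole volume".
- The tracer's nearest-voxel lookup uses `floor(x + 0.5)` consistently
  so that independent reimplementations reproduce it bitwise; the test
  suite's brute-force R loops match the C++ kernels to 10⁻¹⁰ (observed
  ~10⁻¹⁵).
- All-zero windows yield NaN angles with zero confidence; empty masks
  are errors; fibers entirely outside a volume are skipped with a
  warning.
- Histograms place a metric value of exactly 1 in the top bin.

## 8. Problem sizes used in validation

The shipped checks run synthetic volumes at 32³ (oracle equivalence),
64³–96³ (crimp calibration, scenario tests) and 128³ (orientation grid,
2D-vs-3D contrast, pipeline determinism), with cohort statistics at the
40–43-sample scale typical of tissue studies. These sizes keep the full
validation suite in the minutes range on one CPU while matching the
voxel budgets of real acquisitions.

## 9. Known limitations

- Orientation accuracy degrades within ~R of the volume faces (clipped,
  asymmetric windows); consider discarding a margin when summarizing.
- The method estimates one orientation per voxel: unresolved fiber
  crossings inside a window read as high variance, not as two
  populations.
- Waviness depends on the orientation field's quality inside fiber
  interiors; very thick fibers (radius ≫ R) have low-confidence cores.
- The logistic ridge and the LDA covariance ridge introduce a small,
  documented bias in exchange for defined results on separable or
  degenerate data.
- Channel registration is assumed; the package does not align the
  collagen and elastin stacks to each other.
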