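# fiberarch

Three-dimensional fiber architecture metrics for microscopy stacks.

Collagen and elastin fibers of the dermal extracellular matrix remodel
during hypertrophic scar formation: fibers become wavier, less aligned,
and their local density shifts in opposite directions for the two fiber
types. Multiphoton microscopy captures both networks label-free — second
harmonic generation (SHG) for collagen, two-photon excited fluorescence
(TPEF) for elastin — as 3D intensity stacks. `fiberarch` quantifies the
3D architecture of such stacks voxel by voxel and carries the results
through to group statistics and tissue classification. It is aimed at
microscopists and image analysts who have z-stacks of fibrous structures
and want reproducible, physically calibrated organization metrics.

## The method

**Voxel-wise 3D orientation.** Each voxel's axial orientation (fibers are
undirected, so u and −u are equivalent) is estimated by weighted vector
summation: every voxel q within a physical radius R of the voxel p
contributes the doubled-angle unit vector of the offset q − p, projected
onto the xy, zx and yz coordinate planes and weighted by its intensity
I(q). This yields three plane angles — the azimuth θ (projection on xy
vs the x axis), β (projection on zx vs the x axis) and γ (projection on
yz vs the −y axis) — each with a resultant length in [0, 1] that serves
as a confidence. The polar angle φ is resolved from the two auxiliary
angles through

    tan²φ = 1/tan²γ + 1/tan²β ,

with degenerate projections (a fiber seen end-on in some plane) excluded
by a confidence threshold. Anisotropic voxel pitch is handled throughout
by working in micrometres, never in index space.

**Three organizational metrics**, each voxel-wise on the fiber mask and
on [0, 1], built from one axial dispersion functional
`1 − sqrt((3λ₁ − 1)/2)` of a mean dyadic tensor (λ₁ its largest
eigenvalue; 0 = perfect alignment, → 1 = isotropy):

- **Directional variance** — dispersion of the orientation vectors in a
  spherical neighborhood; low for aligned fibers, high for random ones.
- **Waviness** — dispersion of the orientations sampled along a path
  traced through the orientation field from each voxel; 0 for straight
  fibers, higher for crimped ones.
- **Local coverage** — fraction of fiber-occupied voxels in the
  neighborhood; localized fiber density.

**Statistics and classification.** Per-sample summaries of the six
metrics (three per fiber channel) feed Student's t-tests, one-way ANOVA
with Tukey HSD, a Pearson |r| < 0.7 collinearity screen, a pooled-
covariance linear discriminant with resubstitution (OCA) and
leave-one-out (CVCA) accuracies, logistic ROC/AUC, an exhaustive
feature-subset search, and a t-SNE sample embedding.

**Synthetic fiber stacks.** A built-in simulator rasterizes straight,
sinusoidal and helical fibers with analytic ground-truth tangents —
including a scenario with two antiphase sinusoids whose crimp lives
entirely along z, so that a 2D projection analysis reads them as
straight parallel lines while the 3D analysis resolves their true
misalignment and crimp. Every stage of the package is testable against
this ground truth without any external data.

## A worked example

```r
library(fiberarch)

# a synthetic stack: two antiphase crimped fibers plus background
sc  <- antiphase_pair_scenario(shape = c(128, 128, 128))
cmp <- compare_2d_3d(sc$stack, sc$roi)
round(cmp$median_3d, 3)
#> variance waviness
#>    0.444    0.340
round(cmp$median_2d, 3)
#> variance waviness
#>        0        0
```

The 3D analysis reports high directional variance (0.444) and waviness
(0.340) for the antiphase pair, while the same metrics computed on the
xy maximum-intensity projection are indistinguishable from zero — the
crimp is invisible after projection.

```r
# feature-level cohort with scar-like effect directions, classified
tab <- simulate_feature_cohort(c(normal = 20, scar = 20), seed = 42)
lda_classify(tab)
#> <classification_report> lda on {variance_collagen, ..., coverage_elastin}
#>   OCA  100.0%
#>   CVCA 100.0%
#>   LOOCV confusion:
#>          predicted
#> truth    normal scar
#>   normal     20    0
#>   scar        0   20
```

Color-coded maps (`render_metric_map()`) and the full config-driven
pipeline (`run_pipeline()`, with a thin command-line wrapper in
`inst/cli/fiberarch.R`) write per-slice PNGs, float-TIFF metric fields,
a feature CSV, classification JSON and an embedding per run, with a
recorded config hash and seed.

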