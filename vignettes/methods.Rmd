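---
title: "Methods: segmentation, shape descriptors and the statistical battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation, shape descriptors and the statistical battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`histomorph` quantifies cell and tissue morphology in brightfield
immunohistochemistry of brain sections, where DAB (brown) marks
antibody-positive areas over a hematoxylin counterstain. This vignette
documents the model behind each stage, the conventions and tunable
parameters, the design choices that were genuinely open, and what the
synthetic validation does and does not establish.

## Segmentation model

A tile is an 8-bit RGB image. Transmitted light follows Beer–Lambert
absorption, so each channel is converted to optical density,
`OD_c = -log10(max(I_c, 1)/255)` (intensity 0 is clamped to 1, bounding OD
at `log10(255) ≈ 2.407`). Per pixel, the OD vector is a non-negative
mixture of stain-specific unit absorption vectors; solving the 3×3 linear
system (colour deconvolution in the Ruifrok–Johnston sense) yields
hematoxylin, DAB and residual concentrations. The default stain matrix is
the classical hematoxylin/DAB pair with an orthogonal residual; slides
with different chromogen batches can override it (`default_stain_vectors()`
documents the convention: rows are stains, unit Euclidean norm,
invertible).

The DAB concentration channel is thresholded by Otsu's method on a 256-bin
histogram over the observed range. Two conventions matter:

- **Tie-break.** Between two well-separated modes the between-class
  variance is flat across empty bins; the threshold is taken at the middle
  of the tied range, which centres it in the gap and makes the choice
  deterministic.
- **Degenerate tiles.** A constant channel has no separable classes; the
  tile is treated as all background rather than guessing.

Foreground is labelled with 8-connectivity (background holes use the dual
4-connectivity — the standard pairing that avoids topological paradoxes),
and objects smaller than `min_area` (default 4 px, a quantization-speck
filter) are removed. **No hole filling and no smoothing** are applied:
the Euler number is a reported descriptor and morphological clean-up would
destroy it. Declumping/watershed splitting of touching cells is out of
scope; the generator never places touching objects, and on real tiles a
merged clump is measured as one positive area — consistent with
"per positive area" semantics rather than per cell.

## The 16 shape descriptors

All coordinates are pixel centers (x = column, y = row increasing
downward); units are pixels or unitless.

- **area** — exact pixel count.
- **perimeter** — length of the closed outer boundary polygon from
  Moore-neighbour tracing through boundary pixel centers: axial steps count
  1, diagonal steps √2; hole boundaries are excluded; a single pixel is 4
  by convention. A 1-px-wide arm is traced out and back (both sides
  counted): a 1×9 line has perimeter 16. Chain-code perimeters
  underestimate smooth contours slightly (a radius-100 disk measures ≈ 0.90
  on form factor, see below), which is documented rather than corrected.
- **moment ellipse** — central second moments normalized by area give a
  2×2 covariance with eigenvalues λ₁ ≥ λ₂:
  `major = 4√λ₁`, `minor = 4√λ₂`, `eccentricity = √(1 − λ₂/λ₁)` (0 for a
  degenerate λ₁ = 0), `orientation = ½·atan2(2μ₁₁, μ₂₀ − μ₀₂)` in degrees
  from the horizontal axis, mapped to (−90°, 90°].
- **extent** — area over whole-pixel bounding-box area.
- **euler_number** — 1 minus the number of enclosed background holes,
  computed by the quad-count formula for 8-connected foreground (and
  independently cross-checked by flood fill in the tests).
- **form_factor** — `4π·area/perimeter²`; 1 for an ideal circle; may
  exceed 1 for very small objects under the chain-code perimeter.
- **max_feret / min_feret** — largest pairwise distance between pixel
  centers (via hull vertices) and minimum caliper width over hull-edge
  directions (rotating calipers). Collinear sets have `min_feret` 0.
- **max/mean/median_radius** — statistics of the exact Euclidean distance
  transform (distance of each object pixel to the nearest non-object pixel
  center, tile padded by background); the median is the lower median for
  even counts.
- **compactness** — `2π·E[d²]/area`, mean squared distance from the
  centroid; 1 for an ideal disk in the continuum limit, larger for
  elongated or ramified shapes. This normalization is chosen so reported
  values sit on a ≥ 1-ish scale for irregular astrocytic shapes. A single
  pixel scores 0 by convention.
- **solidity** — area over *rasterized* convex hull area: the hull area is
  the count of pixel centers inside or on the hull polygon, not the
  polygon's real area, so every convex digital shape scores exactly 1.

Tile (ROI) aggregation: `area_occupied`, `count` and `total_perimeter` are
totals; the 16 descriptors are unweighted means over objects — including
orientation, an arithmetic mean of angles (a documented caveat: angles
near the ±90° wrap can average misleadingly; medians of near-axial
populations remain interpretable). Empty tiles contribute occupancy zeros
but no descriptor means.

Every descriptor is validated two ways: against independent brute-force
oracles (exhaustive pairwise Feret, all-direction caliper widths,
ray-casting hull rasterization, boundary-candidate distance transforms,
flood-fill hole counting) on hundreds of random 8-connected blobs, to
1e-9 relative (integers exact); and against analytic limits of a
radius-100 disk (extent → π/4, compactness → 1, mean radius → R/3, median
radius → R(1−1/√2), Feret diameters → 2R).

## Region stratification and aggregation levels

Every tile belongs to the hemispheric analysis set; perilesional and SVZ
tiles are flagged subsets, so perilesional pooled vectors are sub-vectors
of hemispheric ones by construction. Group comparisons use **ROI-level
n** — each tile is one observation — matching the reporting convention of
high-content slide studies; the per-animal hierarchy is not modelled
(pseudo-replication is a known caveat of that convention, documented, not
"fixed"). Per-animal means of the 19 parameters are used only for the
cross-stain correlation analysis, where the animal is the natural unit.
Tiles with zero objects are excluded from descriptor-mean pooling (their
means are undefined) but kept for occupancy measures (zero coverage is
real signal).

## Statistical battery

- **Normality screen**: D'Agostino–Pearson omnibus K² (skewness +
  kurtosis Z transforms, χ² with 2 df), requiring n ≥ 8. It annotates;
  comparisons use the rank test regardless.
- **Mann–Whitney U**: U counts cross-group wins (+½ per tie) for the first
  group. When `choose(n1+n2, n1) ≤ 20,000` the two-sided p comes from
  exact enumeration of all labelings (ties handled exactly); otherwise
  from a normal approximation with tie-corrected variance and continuity
  correction. The method used is reported per comparison.
- **Welch's t** with Satterthwaite df tests PC scores. Degenerate inputs
  use explicit conventions: both groups constant and equal → p = 1;
  constant and unequal → p = 0 with a warning.
- **PCA**: parameters are z-scored pooled over both groups — the 19
  parameters mix pixel and unitless scales, and unscaled PCA would be
  dominated by `area_occupied`. Rows with missing descriptor means are
  dropped (logged), zero-variance columns are dropped with a warning
  (constant descriptors are real outcomes for disk-like stains). Loading
  signs follow the convention that each loading's largest-magnitude
  component is positive; three components are tested by default.
- **Correlation heatmaps**: Pearson r with two-sided p from the
  t-distribution (df = n − 2) per ordered parameter pair across animals,
  pairwise-complete; cells with fewer than 3 complete animals (or a
  constant margin) are flagged not computable and excluded from both the
  significant count and its denominator. Pearson is the default because
  the target analysis reports *linear* correlations; Spearman is available
  via `method = "spearman"`. With complete data the full design is
  19 × 19 × 3 stain pairs × 2 regions = 2,166 cells per group.
- **Significance policy**: α = 0.05 on raw p-values, matching
  per-parameter and per-cell reporting conventions; an optional
  Benjamini–Hochberg flag (`adjust = "BH"`) is provided for users who want
  family-wise control.
- **Lesion regression**: ordinary least squares of per-animal mean
  occupancy on corrected lesion volume, p from the F test on the slope.

## Edema-corrected lesion volume

`LVc = HVc + HVi − (HVc + HVi − LVu)·f` with `f = (HVc + HVi)/(2·HVc)`,
where HVc/HVi are contralateral/ipsilateral hemisphere volumes and LVu the
uncorrected lesion volume (cm³). The grouping of `f` is chosen as the
unique simple reading satisfying the no-edema identity `HVi = HVc ⇒
LVc = LVu`; the implementation evaluates the algebraically identical form
`(HVc+HVi)(1−f) + LVu·f` so that identity holds to the last bit. Extreme
swelling can drive LVc negative; it is returned with a warning, never
clipped, because silently clipping would bias group means. An alternate
grouping can be supplied via `factor_fun`.

## The synthetic-slide generator

`generate_study()` renders what the analysis assumes and nothing more:
DAB-positive objects of stain-specific shape families — ramified stars
(microglia/astrocyte analogues), disks (neuronal nuclei), ellipses
(neuroblasts), tubes (vessels), annuli (for topology tests) — placed by
rejection sampling with a ≥ 2 px gap (so segmentation ground truth is
unambiguous), over a uniform hematoxylin background (OD 0.25), mixed by
Beer–Lambert with unit-norm stain vectors, quantized by round-half-up to
8 bits, with additive Gaussian intensity noise (sd 2 of 255 by default)
clipped to [0, 255]. Identical config + seed reproduces the dataset byte
for byte.

Group differences are planted in the stroke direction for each stain
analogue: microglia become ameboid (large body, short stubs: solidity up,
eccentricity down, coverage up), astrocytes sprawl (longer processes:
major axis up, solidity down), neuronal coverage falls, vessels become
more numerous but smaller, neuroblasts smaller and rounder. Default
densities (5–14 objects per 72 px tile) and effect sizes are free
parameters — no density figures exist for the source preparation — chosen
once at magnitudes a histologist would call a clear but not caricatured
group difference, and validated by the recovery tests (all ten planted
directions significant with the planted sign).

What the generator does **not** emulate: tissue texture, stain gradients
and batch variation, touching/overlapping cells, anisotropic illumination,
section artefacts, or spatial autocorrelation of morphology with distance
from the lesion. Passing tests therefore establish correctness of the
measurement and statistics chain on well-posed images — not robustness to
the full messiness of real slides, where thresholding and declumping
choices would dominate.

Volumetry is sampled per animal: hemisphere volumes around 30 cm³,
stroke-group swelling factors 1.04–1.14, and uncorrected lesion volumes
around a 5.36 ± 3.68 cm³ scale truncated to [0.5, 12] cm³.

## Problem sizes and numerical choices

The default synthetic study is 5 vs 5 animals × 10×10 tiles × 5 stains at
72 px tiles (≈ 100 ROIs per animal, with a 20-tile perilesional block at
identical grid coordinates in both groups and a 2-tile SVZ block) — a
desk-scale design that keeps a full generate-segment-measure-analyze cycle
in minutes while leaving every statistical pathway (exact and approximate
rank tests, PCA, per-animal correlation) exercised at realistic n. The
test suite's calibration study uses 20 replicates of a 4 vs 4 × 3×3-tile
single-stain design with identical group distributions; its type-I
fraction is required to fall in [0.01, 0.12] at α = 0.05, and the
correlation false-positive rate (on directly simulated 8-animal feature
matrices, 50 replicates) within binomial 99% bounds of 0.05.

Other numerical conventions: oracle comparisons at 1e-9 relative
(integers exact); PCA orthonormality and reconstruction at 1e-8;
deconvolution is an exact linear solve (reconstruction < 1e-9 before
clipping; negative concentrations clipped to 0 afterwards); Otsu tie-break
as above; labels are contiguous integers in column-major first-pixel
order; seeds derived from the master seed stay below 2³¹.

## Known limitations

Two-dimensional analysis only; chain-code perimeter bias on smooth small
objects (documented band on form factor); arithmetic orientation means
near the angular wrap; ROI-level n ignores the animal hierarchy (use the
per-animal matrices and a mixed model externally if that matters for your
design); no stain normalization across slides; the Otsu-on-DAB
segmentation is a stated stand-in for the original study's undisclosed
pipeline settings, not a reconstruction of them.
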