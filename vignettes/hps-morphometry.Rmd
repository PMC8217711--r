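---
title: "Quantifying Purkinje network density in whole-mount fluorescence images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying Purkinje network density in whole-mount fluorescence images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hpsmorph)
```

## The measurement problem

The His–Purkinje system (HPS) is the fast-conducting fiber network of
the ventricles. In reporter mice whose conduction system fluoresces, the
left HPS can be photographed as a whole-mount: the ventricular free wall
is opened and pinned, exposing the septal Purkinje network as bright
ramifying fibers on a darker myocardial background. Conduction
phenotypes — slowed ventricular activation on ECG — can have a
structural correlate in this network: fewer fibers, fewer branch
points, less intercrossing, often with a regional bias toward the mid
and apical ventricle. Quantifying that hypoplasia requires an image
pipeline that is robust to the two dominant nuisances of whole-mount
fluorescence: smooth uneven illumination/autofluorescence, and the
arbitrary intensity scale of each acquisition session.

`hpsmorph` measures three densities per heart, each "per unit of masked
region" (the manually drawn region of interest), in three bands (base,
mid, apex) and in total:

* **foreground density** — GFP-positive pixels / masked area,
* **skeleton density** — one-pixel network-trace pixels / masked area,
* **branch-point density** — junction pixels / masked area,

and compares WT against KO hearts with a two-tailed Student's t-test per
metric and region, reporting the percent change of the KO mean.

## Pipeline stages and their assumptions

**Top-hat filtering.** `tophat(img, radius)` subtracts the grayscale
opening by a flat disk. The single assumption is a scale separation:
fibers are *narrower* than the disk and background varies on scales
*broader* than the disk. Under it, a smooth background is removed almost
exactly (for a locally linear background the opening reproduces it, so
the residual is second order, plus an edge wedge of about
`slope × radius` at the image border), while any fiber narrower than the
disk keeps its full contrast against the local background. The default
radius is 15 px, roughly three times the fiber-width estimate for the
fixtures; it is the first parameter to revisit for images at other
magnifications.

**Otsu binarization within the ROI.** `binarize_otsu()` histograms
intensities over 256 equal-width bins on [0, 1] — the classical
formulation, regardless of source bit depth — *restricted to the ROI*,
so that the large dark area outside the heart cannot drag the threshold
down. The threshold maximizes the between-class variance; candidate
thresholds are bin upper edges, ties break to the smallest maximizer,
and foreground is strictly greater than the threshold. These three
conventions fix every boundary case deterministically. Otsu assumes a
roughly bimodal ROI histogram, which the top-hat output provides
(background compressed near zero, fibers well above). A constant ROI is
degenerate by decision: empty foreground plus a warning, because a blank
image is a valid, if useless, observation — not an error.

The stage order follows the whole-mount protocol this package
re-implements: the threshold is *estimated* within the ROI, binarization
is applied to the image, and the explicit mask AND is retained as its
own stage afterwards. Estimating within the ROI avoids off-tissue
histogram bias while preserving the stated stage order.

**Skeletonization.** `skeletonize()` is two-subiteration Guo–Hall
homotopic thinning iterated to convergence: a one-pixel-wide,
8-connected trace that preserves the number of connected components. No
spur pruning is applied — pruning would silently delete short true
branches, and the density metrics are meant to be raw. The classical
caveat applies: thinning absorbs fiber crossings into shared paths, so
skeleton pixel counts slightly underestimate total fiber length in dense
networks (see the bias note below).

**Branch points.** A branch point is a skeleton pixel with at least
three skeleton neighbors among its eight neighbors. Adjacent qualifying
pixels are *not* merged by default: around a crossing, the four arm
pixels diagonal to the junction also qualify — this is a geometric
consequence of the definition on a unit-width 8-connected trace, not an
artifact, and it is what brute-force neighbor counting yields. When one
junction should count once, `branch_points(sk, merge = TRUE)` collapses
each 8-connected cluster of qualifying pixels to a single
representative.

**Banding.** `partition_regions()` splits the ROI bounding box along the
declared base-to-apex axis (default: image rows, base at top) into equal
extents; a pixel exactly on a boundary belongs to the band nearer the
base. Equal-extent thirds of the bounding box is the simplest
reproducible rule; nothing anatomical pins the band borders, so an
equal-area variant would be equally defensible — the choice is exposed
(`n_regions`, axis) and recorded in every run log. Band areas sum to the
ROI area exactly, total counts to band counts exactly, and the total
density is the area-weighted mean of band densities by construction.

**Group statistics.** `compare_groups()` uses the pooled-variance
Student's t-test (df = n₁ + n₂ − 2) because that is the stated test of
the protocol being reproduced; Welch is available behind a flag. No
multiple-testing correction is applied across the 3 metrics × 4 regions
by default (per-comparison α = 0.05, again matching the protocol);
`compare_all(..., bonferroni = TRUE)` adds adjusted p-values. Identical
constant groups are reported as t = 0, p = 1; a zero WT mean makes the
percent change undefined (`NA`). Which density a reported "GFP signal"
reduction refers to is ambiguous in this assay family — pixel density
and skeleton density are both in use — so the pipeline always reports
all three metrics rather than presuming one.

## The simulator: what it emulates, and what it does not

`simulate_network()` grows seeded stochastic trees inside a polygonal
ROI shaped like an opened septal face. Each active tip advances by
steps of mean `step_length`, jittered in heading by `angle_sigma`;
bifurcates with probability `branch_rate ×` (band multiplier);
and terminates on leaving the ROI or on failing a per-step survival
draw. Several independent trees (`crossing_trees`) start along the
basal edge and interleave, producing fiber crossings. The generator
returns exact ground truth: per-band skeleton length (segments clipped
at band boundaries), bifurcation counts, rasterized foreground area,
and ROI area — so the quantities the pipeline estimates exist as exact
references.

Default study conditions (chosen once as a realistic whole-mount
regime, then frozen):

| parameter | default | reading |
|---|---|---|
| `domain_shape` | 384 × 384 px | ≈ 20 µm/px for an ~8 mm septal face |
| `crossing_trees` | 12 | major trunks entering at the base |
| `step_length` | 9 px | ≈ 180 µm between direction changes |
| `angle_sigma` | 0.16 rad | gentle meandering |
| `branch_rate` | 0.04 / step | tens of bifurcations per heart |
| `step_survival` | 0.995 | termination dominated by ROI exit |
| `fiber_width` | 2 px | ≈ 40 µm bundles |
| `psf_sigma` | 0.8 px | slight optical blur |
| `background_amplitude` | 0.15 | uneven illumination, sub-signal |
| `noise_poisson_scale` | 200 | photon noise at full scale |
| `noise_gaussian_sigma` | 0.01 | read noise |

Survival close to 1 matters: every specimen of a real whole-mount shows
a network spanning base to apex, so between-heart variation should come
from branching and meandering, not from trunks dying at random — a
regime with substantial per-step death produces heavy-tailed network
sizes unlike real hearts. Knockout lesions are planted with
`apply_ko_effect()`, which multiplies per-band branch and/or survival
rates; the validation suite plants `c(1, 0.5, 0.5)` — branch rate halved
in mid and apex, base untouched.

The render model is deliberately simple where simplicity is safe: the
background field is a *fixed* smooth function scaled by
`background_amplitude`, so the noise-free expectation of an image
depends only on the segments (seeds drive only Poisson/Gaussian noise).
The simulator does **not** emulate: three-dimensional fiber depth and
defocus, fiber-width variation and tapering, tissue autofluorescence
texture at fiber scale, vignetting tied to the optical axis, or
specimen-to-specimen ROI shape variation (every heart of a cohort shares
the ROI polygon, standing in for per-heart hand-drawn masks). Passing
recovery tests therefore shows the pipeline is correct and calibrated
*for networks of this geometry under this camera model* — it does not
certify accuracy on real tissue, where mask drawing and depth effects
add variance the tests cannot see.

A known, measured bias follows from the skeleton-vs-length distinction:
skeleton pixel counts run below geometric fiber length (diagonal steps
cover √2 length per pixel; crossings share pixels), and the shortfall
grows slightly with network density. In WT-vs-KO percent changes this
mostly cancels, leaving a small compression of the recovered effect
(a few percentage points for the default conditions) — the validation
suite bounds it at eight points against ground truth computed from the
same simulated hearts.

## Numerical and reproducibility choices

* All randomness flows from integer seeds; cohort members get per-heart
  seeds via a documented linear derivation (`derive_seed`), so a cohort
  is byte-reproducible from one master seed.
* Coordinates in R interfaces are 1-based (row, col); serialized audit
  JSON uses 0-based coordinates.
* Images are read by dividing by the bit-depth maximum (8- or 16-bit
  TIFF/PNG); cohort images are written as 16-bit TIFF, masks as 8-bit
  PNG (nonzero = true).
* The quantification path contains no RNG: repeated `run_pipeline()`
  calls produce byte-identical CSVs, which the test suite checks by
  checksum.
* Degenerate inputs are contracts, not crashes: constant ROI histogram →
  empty foreground + warning; empty band → `NA` densities for that band;
  fewer than two hearts per group → error; one-group sample sheet →
  error.

## Validation problem sizes

The test suite validates each stage against an independent oracle:
exhaustive between-class-variance search (100 random 32×32 images),
brute-force neighbor counting (100 random thinned masks plus crossing
and T-junction instances), a looped erosion/dilation opening on the
ramp-plus-line instance, and closed-form pooled-t values frozen from
fixed lists. Statistical calibration uses 200 null cohorts of 4 + 4
hearts (ground-truth densities; empirical type-I rate checked against
the exact binomial band around 0.05), and effect recovery uses 36 + 36
rendered hearts per multiplier level in {1.0, 0.75, 0.5}, compared
against ground truth of the same hearts and checked for monotonicity.
These sizes keep the full suite in the minutes range on one CPU while
leaving the stochastic checks with comfortable margins.

## Limitations

* Masks are inputs: the package does not segment the heart or the
  septum, mirroring protocols with manually drawn ROIs.
* Band placement is geometric (bounding-box thirds), not anatomical.
* One image per heart is assumed; repeated images of one heart would
  need a hierarchical model outside this package's scope.
* Branch-point counts index ramification but, without merging, scale
  with junction multiplicity; use `merge = TRUE` when a per-junction
  count is wanted.
* The simulator is two-dimensional and its realism bounds what the
  recovery tests certify (see above).
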