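---
title: "Methods: single-cell quantification of 3D spheroid drug response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell quantification of 3D spheroid drug response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(spheroidquant)
```

# Scope and data model

`spheroidquant` quantifies cell-type specific drug effects in 3D spheroid
cultures from two inputs: a multi-channel fluorescence z-stack
(`multichannel_volume`) and a nuclei instance segmentation mask
(`label_volume`) produced by any external network. Both live on a common
(z, y, x) voxel grid with explicit physical spacing in µm; all reported
quantities are physical (µm, µm³). Axis order is (z, y, x) everywhere,
matching how confocal stacks are acquired plane by plane.

The segmentation itself is deliberately out of scope: masks are an input,
which keeps the package interoperable with any instance segmentation tool.

# Isotropic rescaling

Confocal stacks have a z-step (typically 1 µm) coarser than the lateral
pixel size, while every geometric step downstream (voxel-count volumes,
moment-based morphology, binary morphology with a symmetric structuring
element, Euclidean distances) assumes isotropic voxels.
`rescale_to_isotropic()` resamples to the finer of (dy, dx), i.e. it
upsamples z rather than degrading lateral detail. Intensities are linearly
interpolated; labels use nearest-neighbour so interpolation can never
invent new ids. The volume filter runs *after* rescaling, so the filter
bounds always refer to well-defined physical volumes on the analysis grid;
nuclei exactly at a bound may therefore sit on a different side than they
would on the raw anisotropic grid — a documented consequence of rescaling
first.

Lateral pixel size cannot be trusted from microscope TIFF metadata, so
spacing always comes from the user configuration.

# Nuclear volume filter

Segmented objects smaller than 300 µm³ or larger than 3000 µm³ are debris
or segmentation errors and are removed. The bounds are read strictly:
exactly 300 or 3000 µm³ survives. Volumes are voxel count × voxel volume.
The exclusion list (id, volume, reason) is part of the result bundle so
filtering is auditable; retained ∪ excluded always partitions the input
ids.

# Masked Gaussian smoothing

Intensity features are computed on the raw image and on a smoothed image
in which only foreground voxels contribute. Plain Gaussian filtering would
drag nuclear signal toward the background level at every boundary; instead
we use normalized convolution,

$$S = \frac{G_\sigma * (I \cdot M)}{G_\sigma * M}, \qquad M = 1[I > t],$$

which averages only over foreground support and has the clean identity
that a constant foreground image is a fixed point. Voxels with no
foreground support anywhere in their (4σ-truncated) neighbourhood are 0.
The threshold $t$ is per channel: user-configured, or a volume-wide Otsu
threshold by default (the histogram split maximising between-class
variance, computed over the whole 3D volume rather than per 2D plane —
thresholds on a slice-by-slice basis would wobble with local content).
The default σ is 1 voxel, the same value used for the CellTracker signal;
features can be switched to raw intensities in the configuration.

# Per-nucleus features

For each surviving nucleus the cell table records morphology — volume,
centroid, ellipsoid-equivalent axis lengths $2\sqrt{5\lambda_i}$ from the
eigenvalues $\lambda_i$ of the voxel-coordinate covariance (population
covariance; for a solid ellipsoid the variance along a semi-axis $a$ is
$a^2/5$), elongation = major/minor axis ratio — and, per channel × {raw,
smoothed} × {nucleus, outer region}: mean, median, max, 95th percentile
and SD. Percentiles use linear interpolation (R's default type 7); SDs
are population SDs because a nucleus's voxels are the complete population
of the region, not a sample. The *proximate outer region* is four binary
dilations of the nucleus with a 6-connected (connectivity-1) structuring
element, minus the nucleus itself and minus every other nucleus; it can be
empty in extreme crowding, in which case outer features are 0 and the row
is flagged (`outer_empty`).

# Marker gating and the Cas3 index

Ki-67 and Live-or-Dye localize in nuclei, so gating is a per-nucleus
classification. Feature vectors (fixed order):

* Ki-67: mean nuclear-stain intensity in the nucleus, mean Ki-67 in the
  nucleus, mean Ki-67 in the outer region (the outer term captures
  spill-over context);
* Live-or-Dye: mean nuclear-stain and Live-or-Dye intensities in the
  nucleus.

Classifiers are support vector machines with a linear kernel and C = 1 on
standardized features (training mean/SD). Linear + C = 1 is chosen for all
gates for determinism and because the feature spaces are 1–3 dimensional;
the fitted decision function (weights, offset) is stored explicitly, so
models serialize to plain YAML (`write_model()`) and predictions are exact
linear algebra — applying a model to its own training set reproduces the
training-time predictions bit for bit. Positive fractions always divide by
the total number of surviving nuclei.

Cleaved caspase-3 marks late-apoptotic cells that clump; per-cell
attribution is unreliable, so the package reports the aggregate index
(sum of above-threshold Cas3 intensity) / (nucleus count), reusing the
channel's foreground threshold.

# Spheroid mask, morphometry and shells

The whole-spheroid mask is built from the nuclei by a morphological
closure: 40 binary dilations followed by 40 erosions (connectivity 1),
which closes inter-nuclear gaps without net growth; remaining interior
voids are filled (background flood from the image border; anything not
reached is interior) and only the largest 6-connected component is kept
(detached fragments are excluded; on an exact tie the first-labelled
component wins, a deterministic tie-break). The working array is padded by
`n_iter + 1` voxels so dilation never clips at the boundary.

From mask and labels: volume; void fraction (mask voxels not occupied by
nuclei, over mask voxels); nuclei density (count / volume, nuclei/µm³);
largest equivalent xy diameter ($\max_z 2\sqrt{A_z/\pi}$); per-nucleus
distance to the mask's center of mass and to the nearest surface voxel.
"Hull" means the segmented surface, not a convex hull — the closed mask is
generally non-convex and the biological question (depth below the surface,
the nutrient/drug penetration axis) refers to the actual surface.

Shell analysis partitions the mask into three equi-volumetric shells by
sequential erosion: the first eroded state with volume ≤ 2/3 of the
original bounds the outer shell, the first ≤ 1/3 bounds the middle; the
remainder is the core. Erosion removes whole one-voxel rings, so the
achieved fractions can overshoot the targets by up to one ring; the
first-at-or-below stop rule is deterministic and the achieved fractions
and erosion depths are always reported. Because erosion follows the true
surface, shells track hull geometry rather than a spherical
approximation. Nuclei are assigned to shells by centroid (consistent with
the centroid-based distance definitions; a centroid that rounds outside
every shell goes to the outer shell and is logged). Marker distributions
per shell are percentages of marker-positive cells summing to 100 across
shells.

# Tumor/fibroblast discrimination and corrected counts

Fibroblast nuclei are smaller (volume mode ≈ 500 µm³) and elongated;
tumor nuclei are larger (≈ 1200 µm³) and rounder. Volume alone is biased —
late-mitotic tumor nuclei are small and can be round-to-elongated — so the
classifier also uses collagen-1 context, which only fibroblasts secrete.
Features: volume, elongation, mean collagen-1 in the outer region, mean
collagen-1 in the nucleus. The default classifier is a standardized
linear SVM on these four features. A 3D CNN classifier head (U-Net
encoder + 120/84/2 fully connected layers on 48×64×64 three-channel crops)
is the natural deep-learning alternative; this package ships the crop
builder (`crop_for_cnn()`, channels: nuclei, collagen-1, focal-nucleus
mask, zero-padded at image borders, built on the isotropic grid so the
window has fixed physical meaning) but not a training loop, which would
require a deep-learning backend; the feature SVM is the default and fully
covers the same information sources (size, shape, collagen context).

Training labels come from CellTracker-labeled fibroblasts: a one-feature
linear SVM on the σ = 1 smoothed mean CellTracker intensity expands a
small manual annotation to all nuclei (`celltracker_svm()`,
`expand_labels_with_celltracker()`). Corrected counts then decompose
co-culture totals: predicted fibroblasts are subtracted from the total to
give the corrected tumor count, so the two always sum to the total.
Ties cannot occur in a linear decision function except on a measure-zero
boundary; the decision is the sign of the decision value.

# Segmentation quality: SEG and DET

`seg_score()` implements the benchmark segmentation measure: a predicted
object matches a ground-truth object if it covers more than half of its
voxels (at most one such object can exist); SEG is the mean Jaccard index
over ground-truth objects, 0 for unmatched. `det_score()` uses the same
matching to build the detection edit cost
$AOGM_D = 10\,FN + 1\,FP + 5\,NS$ (weights frozen from the benchmark
definition: false negatives = unmatched ground-truth objects, false
positives = predicted objects that are no object's majority cover, NS =
ground-truth objects overlapped by ≥ 2 matched predicted objects) and
normalizes by the from-scratch cost $AOGM_{D0} = 10\,n_{GT}$:
$DET = 1 - \min(AOGM_D, AOGM_{D0})/AOGM_{D0}$. Both are verified in the
test suite against an independent brute-force voxel-set implementation.

# Condition tables and z-scores

`build_condition_table()` aggregates replicate spheroids into
condition-level means ± SD and records a reference condition.
`z_score_normalize()` applies the heatmap normalization
$(x - \bar x)/s$ per metric with the *sample* SD (ddof 1, the
spreadsheet/statistics-package convention). Whether the reference row is
subtracted before z-scoring is genuinely ambiguous in practice; both
orders are exposed (`condition_zscores(subtract_reference =)`) with the
default being a plain per-metric z-score over all conditions. Hypothesis
testing (ANOVA with multiplicity correction) is intentionally not
re-implemented: the package exports replicate-resolved tables that any
statistics tool can consume.

# The synthetic generator

`generate_scene()` is first-class, tested code, not a fixture: it is the
package's study-condition model. It emulates the features downstream
stages rely on:

* two nuclear populations — tumor (lognormal volume, mode 1200 µm³,
  geometric SD 1.3, axis ratio 1.2) and fibroblast (mode 500 µm³,
  geometric SD 1.3, axis ratio 2.5) — as ellipsoids with random
  orientation, packed without voxel overlap into a sphere by rejection
  sampling (larger nuclei placed first; a packing that cannot be completed
  within the attempt budget errors with the achieved count);
* default counts 50 tumor : 150 fibroblast, the 1:3 co-culture seeding
  ratio; marker positivity drawn per type (defaults: Ki-67 0.6/0.05,
  reflecting highly proliferative tumor cells vs barely proliferating
  fibroblasts; Live-or-Dye and Cas3 at low fractions);
* rendered channels: nuclear stain with mild per-nucleus brightness
  variation, marker channels elevated only inside positive nuclei,
  CellTracker inside fibroblast nuclei, and collagen-1 as an additive
  Gaussian-profile shell of width 3 µm *outside* fibroblast nuclei only
  (collagen is secreted and extracellular, so it must be visible to the
  outer-region features and not the nuclear mask);
* additive Gaussian noise (default SD 2 a.u. against a background of 10
  and marker amplitudes of 25), optional blur and optional exponential
  depth attenuation (off by default — stacks are assumed acquired with
  z-compensation).

All randomness flows from one integer seed; identical parameters
reproduce identical scenes byte for byte. The lognormal law is
parameterized by mode $m$ and geometric SD $g$:
$\sigma = \log g,\ \mu = \log m + \sigma^2$ (so the mode is exactly $m$).

What the generator does **not** model: realistic optics (PSF, spherical
aberration, refractive-index mismatch), chromatic effects, mitotic or
apoptotic nuclear morphologies, touching/overlapping nuclei, or
segmentation errors in the input mask. Passing tests therefore demonstrate
that the *quantification* is correct given a faithful segmentation and
reasonably contrasted stains; they do not certify performance on real
microscopy with imperfect segmentation, which should be assessed with
`evaluate_segmentation()` against expert annotation.

# Numerical choices and problem sizes

* 6-connected (connectivity 1) structuring element for every dilation,
  erosion, component search and hole fill; hole filling floods background
  from the image border with the same connectivity.
* Gaussian kernels truncated at 4σ; separable implementation.
* Percentiles: linear interpolation (type 7). SDs over voxel sets:
  population SD. Z-score SDs: sample SD (ddof 1).
* Degenerate morphology (single-voxel or coplanar nuclei) yields
  elongation NA rather than an arbitrary value; such nuclei cannot pass
  the volume filter under realistic spacings.
* The test suite and the acceptance script run on deliberately desk-scale
  scenes — spheroid radii 35–55 µm with 60–200 nuclei at 1 µm isotropic
  spacing, a radius-104 µm scene with 1000 nuclei for the volume-histogram
  check, and radius-30–60-voxel digital balls for geometry checks — sizes
  chosen so the whole suite completes in minutes while every code path
  (packing, rendering, filtering, smoothing, morphometry, shells, gating,
  discrimination, scoring) is exercised end to end.

# Known limitations

* Label TIFF export is 16-bit (≤ 65535 instances per stack).
* The CNN discrimination path requires an external deep-learning backend;
  only the crop builder ships here.
* Shell membership by centroid means a nucleus straddling a shell
  boundary is counted wholly in its centroid's shell.
* `largest_equivalent_xy_diameter()` assumes dy = dx within each plane
  (true after isotropic rescaling).
* The generator's rejection packing saturates near ~25 % volume fraction;
  denser aggregates need a larger radius or fewer/smaller nuclei.
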