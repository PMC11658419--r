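# spheroidquant

Single-cell quantification of drug response in 3D spheroid cultures.

Tumor spheroids — self-assembled 3D cell aggregates, often co-cultured with
fibroblasts — are a standard in-vitro model for testing cytostatic drugs.
After whole-mount staining, optical clearing and confocal 3D imaging, every
nucleus in the spheroid can be segmented by a deep-learning network. What is
then needed, and what this package provides, is the *downstream* analysis
that turns a multi-channel volumetric stack plus a nuclei instance mask into
cell-level and spheroid-level biology:

- **Per-nucleus features** — isotropic rescaling, a 300–3000 µm³ volume
  filter against debris and segmentation errors, morphology from voxel
  moments (volume, centroid, principal axes, elongation), and intensity
  statistics (mean, median, max, 95th percentile, population SD) of every
  channel, raw and after foreground-masked Gaussian smoothing, over the
  nucleus and over its *proximate outer region* (4 binary dilations with a
  connectivity-1 structuring element, all nuclei excluded).
- **Marker gating** — linear-kernel SVM classifiers decide Ki-67
  (proliferation) and Live-or-Dye (necrosis) positivity per nucleus; the
  positive fraction uses the total nucleus count as denominator. Cleaved
  caspase-3, which clusters too densely for per-cell attribution, is
  reported as an aggregate index: above-threshold Cas3 intensity summed over
  the image, divided by the nucleus count.
- **Spheroid morphometry** — the whole-spheroid mask is the morphological
  closure of the nuclei (40 dilations + 40 erosions, connectivity 1), with
  interior voids filled and only the largest connected structure kept; from
  it: volume, void fraction, nuclei density, largest equivalent xy diameter
  `2·sqrt(A/π)`, and per-nucleus distances to the spheroid center and hull.
- **Equi-volumetric 3D shells** — sequential binary erosion until the
  remaining volume first reaches 2/3 and 1/3 of the original partitions the
  spheroid into outer/middle/inner shells of equal volume that follow the
  actual hull geometry; per-shell nucleus counts, densities, mean nuclear
  volumes and marker distributions quantify spatial gradients.
- **Tumor/fibroblast discrimination** — fibroblast nuclei are small
  (volume mode ≈ 500 µm³) and elongated, tumor nuclei large (≈ 1200 µm³)
  and round, but late-mitotic tumor nuclei mimic fibroblasts, so the
  classifier combines nuclear volume, elongation and collagen-1 context
  (fibroblasts secrete collagen-1). Training labels are expanded from a
  small CellTracker annotation by a one-feature linear SVM (σ = 1 smoothed
  CellTracker intensity). Corrected counts decompose co-culture totals:
  `tumor = total − predicted fibroblasts`.
- **Segmentation quality** — cell-tracking-challenge SEG (mean matched
  Jaccard under the >50 % coverage rule) and DET (normalized detection
  graph edit cost, `AOGM_D = 10·FN + 1·FP + 5·NS`) scores for comparing
  instance segmentations against ground truth.
- **A synthetic spheroid generator** — seeded, ground-truthed scenes
  (ellipsoidal nuclei packed in a sphere, marker states, collagen halos,
  noise/blur) that make every stage testable end to end without microscopy
  data.

Tabular results are tibbles throughout; fitted models support
`tidy()`/`glance()`, and results have `autoplot()`/`plot_*()` companions.

## Worked example

```r
library(spheroidquant)

# simulate a 1:3 tumor:fibroblast co-culture spheroid with ground truth
params <- scene_params(radius_um = 48, n_tumor = 20, n_fibroblast = 60,
                       noise_sd = 2, seed = 42)
scene  <- generate_scene(params)
#> <synthetic_scene> 80 nuclei (20 tumor, 60 fibroblast), seed 42

# quantify it: volume filter, features, morphometry, shells
cfg <- analysis_config(seed = 42)
res <- run_pipeline(cfg, scene$volume, scene$labels)
#> <pipeline_result> 80 nuclei, 0 excluded
#>   volume_um3 n_nuclei void_fraction density_per_um3 equivalent_xy_diameter_um
#> 1     209549       80     0.7122487    0.0003817723                  72.43632
#>   center_z_um center_y_um center_x_um cas3_index
#> 1    50.97861    49.96333    49.50525   70820.33

res$shells$fractions
#> # A tibble: 3 × 5
#>   shell  target_fraction achieved_fraction volume_um3 erosion_depth
#> 1 outer            0.333             0.350      73409             0
#> 2 middle           0.333             0.335      70183             5
#> 3 inner            0.333             0.315      65957            12

# train a Ki-67 gate on the scene's ground truth and apply it
truth <- scene$truth[match(res$cell_table$id, scene$truth$id), ]
gate <- train_marker_svm(ki67_features(res$cell_table), truth$ki67,
                         seed = 42, marker = "ki67")
predict_marker(gate, res$cell_table)
#> <gate_result> ki67: 18/80 positive (22.5%)
```

Reading: the 80 simulated nuclei all pass the 300–3000 µm³ filter; the
closed spheroid mask holds ≈ 2.1 × 10⁵ µm³ of which 71 % is inter-nuclear
void; the three shells deviate from the ideal third by at most ~2
percentage points (erosion proceeds in whole voxel rings, so a small
overshoot is expected); and the SVM gate calls 18/80 nuclei Ki-67⁺ — the
scene's generated positivity.

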