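# amyseg

Automated volumetric segmentation of the amygdala (or any pair of small
lateralized subcortical structures) from T1-weighted-like 3D images, using
multi-atlas diffeomorphic registration, locally similarity-weighted label
fusion, and AdaBoost-based correction of systematic segmentation errors.

Hand-tracing the amygdala takes an expert roughly two hours per hemisphere
per scan; at modern sample sizes that is untenable, while the widely
available automated tools correlate poorly with careful manual tracing.
The approach implemented here transfers trusted manual segmentations from
a set of *atlas* (training) subjects onto new scans: every atlas image is
deformably warped onto the test image, its label map is carried along, and
the warped labels vote voxel by voxel, with each atlas weighted locally by
how well its warped image matches the test image. A second-stage
classifier, trained by leave-one-out cross-validation on the atlas set,
learns where this fusion systematically disagrees with the manual truth
and flips those voxels.

The package is exercised end-to-end on seeded synthetic phantom cohorts
with known ground truth (no data download required): smoothly deformed
multi-tissue ellipsoid "heads" carrying two mirrored target structures,
multiplicative bias fields and noise.

## The model in brief

* **Registration.** Greedy diffeomorphic demons: per iteration the force
  `u = (F − M∘φ) ∇(M∘φ) / (‖∇(M∘φ)‖² + κ (F − M∘φ)²)` is smoothed (fluid
  regularization), capped at 0.4 voxel, composed into the running field φ,
  which is itself smoothed (diffusion regularization). Levels follow the
  coarse/middle/fine schedule (max 80 iterations at 4× subsampling, 80 at
  2×, 30 at full resolution). Every emitted field has a strictly positive
  Jacobian determinant.
* **Template.** Iterative averaging with diffeomorphic warping and a
  mean-displacement unbiasing step; manual labels are warped into template
  space, averaged, and smoothed with a 1 mm Gaussian to give per-hemisphere
  probability maps, from which rectangular search regions (ROIs) are cut.
* **Normalization.** 3-class intensity clustering; the image is scaled so
  the white-matter histogram mode sits at 80% of the 16-bit range
  (0.8 × 65535 = 52428), intensities are squared for peak separation, and
  the contrast adjustment is repeated on the squared image.
* **Fusion.** Per voxel, atlas *i* votes with weight
  `w_i(x) = (ε + Σ_patch (I_test − I_i)²)^(−β)` (patch radius 2, β = 2);
  the structure is assigned where the weighted vote fraction ≥ 0.5.
* **Correction.** Discrete AdaBoost over decision stumps on appearance,
  contextual and spatial features, trained on the leave-one-out fusion
  errors of the atlas set inside a dilated "bias region"; flagged voxels
  have their label flipped.
* **Evaluation.** Dice `2|A∩B|/(|A|+|B|)`, Jaccard `|A∩B|/|A∪B|`
  (J = D/(2−D)), Pearson r of volumes, and two-way single-measures
  intraclass correlations (consistency and absolute agreement).

## Worked example

```r
library(amyseg)
co  <- demo_cohort(seed = 7)          # 5 atlas + 2 test subjects, 48^3, 1 mm
res <- run_pipeline(co$train, co$test, pipeline_config())
print(res$report)
```

On one CPU this takes about a minute and prints:

```
Segmentation agreement report
  left   Dice 0.782 +- 0.051  Jaccard 0.644 +- 0.069
  right  Dice 0.792 +- 0.041  Jaccard 0.657 +- 0.057
```

i.e. the automated segmentations of the two held-out test subjects overlap
their ground-truth labels with mean Dice ≈ 0.78–0.79 per hemisphere, using
only five atlases on a 48³ phantom whose target structures span ~330
voxels. (Cohort-level Pearson/ICC summaries appear once a test cohort has
≥ 3 subjects with varying volumes.) The run manifest records the warp
bookkeeping — `n_atlases × 3` pyramid levels per test hemisphere:

```r
res$manifest$subjects[[1]]$warps_per_hemisphere   # 15 = 5 atlases x 3 levels
```

Every stage is also available separately: `simulate_cohort()`,
`normalize_intensity()`, `rigid_register()`, `diffeo_register()`,
`build_template()`, `weighted_vote()` / `fuse_segmentation()`,
`train_adaboost()` / `correct_segmentation()`, `evaluate_cohort()`; and as
CLI subcommands via `exec/amyseg` (`simulate`, `normalize`,
`build-template`, `register`, `segment`, `train-corrector`, `correct`,
`evaluate`, `run`).

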