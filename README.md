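# dropletrim

Quantification of ordered perilipin recruitment to intestinal lipid droplets
from two-channel fluorescence micrographs.

When an animal eats a high-fat meal, its enterocytes store dietary lipid in
cytoplasmic lipid droplets. Two perilipin coats succeed each other on the
droplet surface: a Plin3-like protein (present in the cytosol beforehand,
binds nascent droplets immediately, leaves early) and a Plin2-like protein
(synthesized after the meal, arrives with a delay, stays until the droplets
are gone). Establishing that order is an image-quantification problem, and
`dropletrim` implements the full measurement chain for researchers doing
this kind of organelle-surface-recruitment imaging:

* **Droplet segmentation** from a lipid-dye channel with a trainable pixel
  classifier (random forest over a 34-plane multi-scale Gaussian feature
  bank: smoothed intensity at σ 1.6–5.0 px, edge/texture features at
  σ 0.07–5.0 px), probability-map thresholding, and small-object removal.
* **Rim-mask quantification**: all droplets unified into one mask, expanded
  by 3 px (360 nm at 120 nm/px), applied to the protein channel; reports
  `mean_ld` (droplet-associated) and `mean_cyto` (cytoplasmic) mean
  fluorescence per image, with the exact identity
  `area_ld·mean_ld + area_cyto·mean_cyto = Σ(ROI)`.
* **Colocalization**: Costes automatic thresholding (orthogonal regression
  on standardized intensities; threshold pair lowered until the
  below-threshold Pearson r ≤ 0) and thresholded Manders coefficients
  tM1/tM2, ROI-restricted.
* **Time-course statistics**: raw integrated density, wild-type sibling
  autofluorescence correction (exactly mean-zero on wild types per
  time-point), windowed least-squares fits reporting the signed correlation
  coefficient R, per-genotype normalization by the overall mean of all
  individual data points, and LOWESS smoothing for display.
* **Synthetic scene generation** with recorded ground truth (droplet
  geometry, rim/cytoplasm intensity schedules over 0–30 h, Poisson +
  Gaussian noise, 12-bit quantization), so the whole pipeline is testable by
  parameter recovery without any acquired data.

I/O is deliberately plain: grayscale TIFF images and masks, CSV polygon
ROIs and measurement tables, YAML run configuration.

## Worked example

Simulate one two-channel scene at 6 h post-meal, train the classifier on
sparse labels, segment, and quantify the rim compartment:

```r
library(dropletrim)

sp <- scene_params(seed = 42)                       # 128x128, 12-bit, 25 droplets
sc <- make_droplet_scene(sp, protein_schedule("plin2_like"), time_hr = 6)
sc$dye
#> <micrograph> 128 x 128 px, 120 nm/px, 12-bit, channel=lipid_dye
#>   subject=scene1 genotype=plin2_like t=6 hr, intensity range [73, 553]

set.seed(1)                                        # sparse annotator labels
labels <- matrix(NA_character_, 128, 128)
labels[sample(which(sc$truth$droplet_mask), 400)] <- "droplet"
labels[sample(which(!sc$truth$droplet_mask), 400)] <- "background"
model <- train_pixel_classifier(compute_feature_bank(sc$dye), labels, seed = 1)
model
#> <pixel_classifier> 100 trees, 34 features, hold-out accuracy 0.994

seg <- segment_image(model, sc$dye)                # probability map -> mask
mask_iou(seg$droplet_mask, sc$truth$droplet_mask)
#> [1] 0.968

rim <- dilate_mask(seg$droplet_mask, rim_params(3, pixel_size_nm = 120))
compartment_means(sc$protein, rim, sc$truth$roi)
#>   subject_id genotype_label time_hr  mean_ld mean_cyto area_ld_px area_roi_px
#> 1     scene1     plin2_like       6 143.7838  70.67674       5832       16384

coloc_analysis(sc$dye, sc$protein, sc$truth$roi)[c("threshold_ch1", "tM1", "converged")]
#>   threshold_ch1       tM1 converged
#> 1           473 0.2003269      TRUE
```

Reading the numbers: the generator's truth for this scene is a rim intensity
of 405.8 and a cytoplasm of 70.6. The measured `mean_cyto` (70.68) recovers
the cytoplasm within noise; `mean_ld` (143.8) is the rim signal diluted by
the mask geometry — the expanded mask contains droplet interiors and a 3 px
halo, of which the 2 px rim shell is only ~20%, so
`mean_ld ≈ cyto + 0.2·rim`. That dilution is shared by measured and real
data alike; the time-course *signs* (rising, falling, flat) are what carry
the biology.

The numbered scripts under `analysis/` run the full study-scale workflow
(192 scenes, 16 time-points, two reporter schedules) and print the windowed
fits whose sign pattern shows the coat transition — plin3-like declining on
droplets over 0.75–8.5 h while plin2-like rises, and plin2-like declining
over 16–30 h:

```sh
Rscript analysis/01_simulate.R     # scenes + ground truth
Rscript analysis/02_segment.R      # classifier training + IoU vs truth
Rscript analysis/03_quantify.R     # rim-mask compartment means
Rscript analysis/04_coloc.R        # Costes/Manders per scene
Rscript analysis/05_timecourse.R   # windowed fits, normalization, whole-mount arm
```

Tables land under `results/pipeline_run/` with a checksum manifest; re-runs
are bit-identical.

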