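---
title: "Quantifying ordered perilipin recruitment to intestinal lipid droplets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ordered perilipin recruitment to intestinal lipid droplets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

After a high-fat meal, enterocytes store dietary lipid in cytoplasmic lipid
droplets whose surface is coated by perilipins. Two coats succeed each other:
a Plin3-like protein that is already present diffusely in the cytosol and
associates with nascent droplets immediately, and a Plin2-like protein that
must first be synthesized, decorates the droplets with a delay, and stays
with them until they are degraded. The evidence for this order is an imaging
measurement: in two-channel micrographs (a lipophilic dye marking the
droplets, a fluorescent protein fusion marking the perilipin), the mean
protein fluorescence *on* the droplets is compared with the mean fluorescence
in the surrounding cytoplasm, across a 0.75–30 h post-meal time course.

`dropletrim` implements that measurement chain as a reusable, testable
pipeline:

1. **Segmentation** — a trainable pixel classifier over a multi-scale
   feature bank turns the dye channel into a droplet probability map, which
   is thresholded into a binary droplet mask.
2. **Rim quantification** — all droplets are unified into one object mask,
   expanded by 3 px (360 nm at the default 120 nm/px) so it covers the
   droplet surface, and applied to the protein channel; mean intensity
   inside the expanded mask (`mean_ld`) and outside it (`mean_cyto`) are
   reported per image.
3. **Colocalization** — Costes automatic thresholding and thresholded
   Manders coefficients for two-channel pairs, ROI-restricted.
4. **Time-course statistics** — whole-organ integrated density with
   wild-type sibling autofluorescence correction, per-genotype mean
   normalization, windowed least-squares fits reporting the signed
   correlation coefficient R, and LOWESS smoothing for display.
5. **Synthetic scenes** — a generator that renders all of the above with
   known ground truth, so every stage is tested by parameter recovery.

No imaging data ships with the package; the synthetic generator *is* the
study-conditions fixture.

## The synthetic scenes

A scene is a pair of 12-bit 128×128 micrographs at 120 nm/px. The dye
channel is piecewise constant by compartment — background outside the tissue
ROI (20 counts), cytoplasm (120), a central lumen band (250, 15% of the ROI
height, droplet-free), and droplet cores (480, i.e. 4× cytoplasm contrast,
matching puncta that are distinctly brighter than the surrounding
cytoplasm). Droplets are non-overlapping disks with radii uniform in 3–7 px;
25 per scene early, declining linearly to 8 between 10 h and 30 h, because
droplet numbers fall late in the chase. The protein channel carries the
schedule value `cyto(t)` everywhere in the ROI plus `rim(t)` on each
droplet's 2 px rim shell — droplet coats appear as rings in a single
confocal plane.

Both channels then pass through a standard confocal noise model: per-pixel
Poisson photon noise, Gaussian read noise (sd 3 counts), clamping to
`[0, 4095]`, and rounding. One seeded RNG stream drives placement and both
channels of a scene, so distinct scene seeds give independent scenes; the
intensity levels are free parameters chosen for testability, not biological
claims.

Protein schedules are parametric (delayed saturating rise × exponential
decline), not mechanistic binding kinetics — the pipeline's job is to
recover rendered intensities, not to infer kinetics:

* `plin3_like`: `cyto` constant at 150; `rim` peaks at the first imaging
  time (180 + 260 × rise(τ = 0.3 h) × decay from 0.75 h, τ = 2 h), then
  settles to a flat plateau of 180 — early decline, late flatness.
* `plin2_like`: `rim` is exactly 0 until a 2 h onset, rises with τ = 2.5 h
  to an amplitude of 420, and declines after 10 h with τ = 10 h; `cyto`
  rises modestly from 30 to 80.
* `overexpressed_like`: as `plin2_like` but with no onset delay (the mRNA is
  already present), amplitude 380, decline after 12 h.

The whole-organ generator is simpler: reporter fish carry
`organ_signal(t) + autofluorescence` in a fixed organ region, wild-type
siblings carry autofluorescence only, and a lognormal per-fish factor
(sdlog 0.2) on the signal emulates variability in the amount of lipid
consumed.

## Segmentation: feature bank and classifier

The feature bank mirrors interactive pixel-classification tools: smoothed
intensity at σ ∈ {1.6, 2.3, 3.5, 5.0} px, and edge/texture features —
gradient magnitude, Laplacian of Gaussian, both Hessian eigenvalues, both
structure-tensor eigenvalues — at σ ∈ {0.07, 0.7, 1.6, 3.5, 5.0} px
(34 planes). Convolution is separable with symmetric (reflective) boundary
handling, so smoothing conserves total intensity. Two numerical choices
matter at the extremes of the σ grid:

* Sampled Gaussian derivative kernels degenerate below σ ≈ 0.5 px (the
  sampled derivative is numerically zero), so sub-pixel σ uses the
  finite-difference stencils `(0.5, 0, −0.5)` and `(1, −2, 1)` instead.
* First-derivative kernels are normalized to unit response on a unit ramp,
  so gradient magnitudes are comparable across σ.

The classifier is a 100-tree probability random forest (`ranger`, one
thread, fixed seed — deterministic and serializable; a reloaded model
reproduces probability maps bit-identically). Training uses sparse labels
only, with a stratified 20% hold-out reporting accuracy. Probability maps
are thresholded at 0.5 by default — the original workflow adjusted this
per image, so it is a per-call parameter — and 8-connected components below
4 px are removed as speckle (single-pixel noise suppression; no size filter
is part of the original method). Raising the threshold can only remove
pixels, never add them.

On these study conditions the acceptance suite measures mean
intersection-over-union against truth masks of ≈ 0.99 with default noise
(the stated acceptance floor is 0.70) and 1.0 on noiseless scenes (floor
0.90).

## Rim quantification

The unified droplet mask is expanded with iterated 3×3 (Chebyshev) dilation,
matching the behavior of the binary Dilate operation in common image-analysis
software; a Euclidean-disk alternative is provided because "360 nm in all
directions" suggests isotropic physical intent. Both are verified against a
brute-force distance oracle.

`mean_cyto` is computed by subtracting the mask's intensity *sum* and *area*
from the ROI totals — "subtracting the droplet fluorescence from the total"
is read as a sum-and-area subtraction, which yields a true cytoplasmic pixel
mean; subtracting means would be dimensionally inconsistent. The weighted
identity `area_ld·mean_ld + area_cyto·mean_cyto = sum(ROI)` holds exactly
for every row emitted. Degenerate compartments (empty mask, or mask filling
the ROI) are reported as missing, never zero, so regressions downstream are
not biased. The measurement mask is the *filled* expanded mask, as in the
original workflow; a rim-shell-only variant is available but not default.

Because the mask includes droplet interiors and a 3 px halo, `mean_ld` is a
diluted version of the true rim intensity:
`mean_ld ≈ cyto + α·rim`, with α the rim-shell fraction of the mask
(≈ 0.2 under the default geometry). One genuine finding from the synthetic
ground truth: **α depends on droplet crowding**, because the 3 px expansion
halos of adjacent droplets merge. When droplet numbers decline over the late
chase, α drifts down slightly (≈ 0.5% of `mean_ld` across 16–30 h). With
scene-to-scene variation limited to photon noise, this geometric drift
dominates the late-window correlation for a flat schedule: the pipeline's
plin3-like late-window R comes out at ≈ −0.3 to −0.6 rather than the ≈ 0 a
truly flat readout would give. Real specimens carry per-fish variability far
larger than this bias, which is why flat late-window R values are observed
in practice; the generator deliberately does not include such a variability
term, so this limitation is documented rather than masked.

## Colocalization

Costes automatic thresholding regresses channel 2 on channel 1 and walks a
linked threshold pair down the distinct channel-1 intensities from the
maximum, stopping at the largest threshold whose below-threshold pixels
(both channels below their linked values) have Pearson r ≤ 0; thresholded
Manders coefficients tM1/tM2 then report each channel's intensity fraction
on pixels where the *other* channel exceeds its threshold. Design choices,
since common implementations differ:

* The regression is orthogonal regression on *standardized* intensities
  (reduced major axis, slope = sign(cov)·sd(y)/sd(x)). Unlike raw total
  least squares this is equivariant under per-channel rescaling: scaling a
  channel by k scales its threshold by k and the slope by 1/k, leaving
  tM1/tM2 unchanged — a property the package asserts numerically.
* Threshold candidates are the distinct observed intensities, not fixed-width
  bins; fewer than 10 below-threshold pairs (or zero variance) end the
  search with `converged = FALSE` and the Pearson value flagged missing.
* The iterative search is verified against exhaustive enumeration of every
  candidate threshold on fully enumerable instances.

Two behaviors of this metric on droplet scenes are worth knowing, both
surfaced by the `pearson_below`, `converged`, and threshold columns rather
than corrected. On a rim-free early scene the protein channel is
structureless, the regression slope sign is the sign of a near-zero
covariance, and the linked threshold is bistable — tM1 lands near 0 or near
1 depending on that coin flip. Between two rim-occupied times, the automatic
threshold scales with rim brightness and selects the same rim pixels, so tM1
is nearly invariant to recruitment amplitude: it measures rim geometry. A
cytosolic protein will always colocalize with droplet-bound signal unless
the cytoplasmic level is thresholded away, and the automatic threshold only
partially compensates — which is exactly why the rim-mask compartment
measurement, not colocalization, is the pipeline's primary readout.

## Time-course statistics

Whole-organ fluorescence is summed over the ROI as raw integrated density.
Autofluorescence correction subtracts the per-time-point wild-type sibling
mean from every measurement at that time, so wild-type corrected values
average exactly zero per time-point and reporter values may legitimately go
negative (noise around zero is preserved). The correction warns, but
proceeds, below three wild-type fish at a time-point. Windowed fits
(defaults 0.75–8.5 h and 16–30 h) are ordinary least squares; the reported R
is the signed Pearson coefficient, not R². Per-genotype normalization
divides by the overall mean of all individual data points of that genotype —
pooled across compartments and time-points — making group means exactly 1 so
reporters of very different absolute brightness can be overlaid. LOWESS
(tricube locally weighted regression, span 0.35, 2 robustness iterations) is
attached for visualization only and never feeds a fit. Hypothesis tests
(ANOVA, Kruskal–Wallis) are deliberately out of scope; the tidy per-subject
tables are shaped for external statistical software.

## Reproducibility and problem sizes

Every stochastic component takes an explicit seed; `run_pipeline()` echoes
its configuration, writes a checksum manifest, and reproduces bit-identical
tables for identical configurations. The packaged study conditions use
128×128 scenes, 16 time-points (8 per window), two schedules, and six scenes
per point — 192 scenes end to end — which the package processes in about two
minutes; these sizes are the package's own choice of a desk-scale replica of
the experimental design (the real study imaged 3–23 fish per time-point).

## Known limitations

* Scenes are 2D single planes; droplets are circles, rims are annuli. No
  point-spread-function blur, no 3D, no droplet growth within a scene.
* Generator intensities are plausible but uncalibrated; tests demonstrate
  recovery of rendered truth, not agreement with any instrument.
* Scene-to-scene variation is photon/read noise only — no per-fish
  biological variability in the droplet scenes (see the α-drift discussion
  above for what this exposes).
* The colocalization stage reproduces the method as used, including its
  documented unsuitability for cytosolic + droplet-bound protein pairs.
* Droplets are quantified as one pooled object; there is no per-droplet
  sizing, counting, or tracking.
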