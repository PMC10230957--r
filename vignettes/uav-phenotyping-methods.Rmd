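---
title: "Methods: from multiband nadir imagery to per-plant traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from multiband nadir imagery to per-plant traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`uavpheno` estimates per-plant canopy width, length and relative chlorophyll
content (SPAD) of row-planted rosette crops from nadir multiband imagery.
This vignette explains the models and procedures behind each stage, the
parameters that matter and their defaults, what the synthetic scene
generator does and does not emulate, and the numerical and design choices
made where the design was genuinely open.

## Photogrammetric scale model

A nadir camera at height $H$ with pixel pitch $a$ and focal length $f$
images the ground at a ground sampling distance (GSD)

$$\mathrm{GSD} = \frac{H \, a}{f} \quad [\mathrm{m/px}],$$

so a frame of $1600 \times 1300$ px covers $1600\,\mathrm{GSD} \times
1300\,\mathrm{GSD}$ metres on the ground. The default `camera_model()`
(10 m flight, 3 µm pitch, 5.74 mm lens) gives GSD ≈ 5.23 mm/px, a frame
footprint of ≈ 8.36 m × 6.79 m, and a 608-px tile extent of ≈ 3.18 m.
Constructors accept the mixed units these constants are conventionally
quoted in (m, µm, mm) and convert to metres on entry, because a single
canonical unit prevents silent factor-of-1000 errors. The model assumes
flat terrain and true nadir geometry; lens distortion, relief and
georeferencing are out of scope. (The platform's quoted imaging angle is
metadata only; it enters no equation.)

Super-resolution changes pixel density, not ground coverage: a mask
measured on $s\times$-enhanced imagery has $s$ times more pixels per metre,
so `ground_scale(gsd, sr_factor = s)` divides pixel counts by `sr_factor`
in `px_to_length()`. Keeping `sr_factor` in the scale object rather than
the camera lets one camera serve native and enhanced pipelines; the
division is made explicit here because it is easy to get silently wrong.
Reported tables print lengths in centimetres (plants are ~20–60 cm); the
API returns metres.

## Synthetic scenes and their ground truth

No field imagery is distributed with the package, so every downstream
stage is exercised on synthetic "stitched fields" with exact ground truth:

* **Soil** is a per-band mean reflectance plus smoothed Gaussian texture
  (sd 0.02 by default) — a brownish, non-flat background.
* **Plants** are filled ellipses (semi-axes 18–30 px ≈ 19–31 cm diameter
  at the default GSD, small random rotation) arranged in `n_rows` rows
  96 px (~50 cm) apart — wide inter-row spacing, as for a row-planted
  heading crop — with 80 px within-row pitch, positional jitter, and a
  10% chance that a neighbouring pair is pulled together until canopies
  overlap. Overlap is the documented failure mode of within-row
  segmentation, so the generator must produce it. Contested pixels go to
  the plant whose normalised elliptical radius is smaller.
* **Spectra.** Each plant draws R, G, B, red-edge and NIR channel means
  from realistic reflectance ranges; vegetation NIR/red-edge are well
  above soil, the visible bands well below. Canopy texture is
  multiplicative smoothed noise renormalised per plant, so each region's
  channel mean stays exactly its nominal value while the image is
  non-flat — the segmenter has texture to learn, and the SPAD coupling
  stays exact in expectation.
* **SPAD.** The field relationship between reflectance and SPAD is not
  known in functional form; the linear generative model
  $\mathrm{SPAD} = b_0 + b_R \bar R + b_G \bar G + b_B \bar B +
  \varepsilon$, $\varepsilon \sim N(0, 1.5)$, is the assumption that makes
  a multiple linear regression on channel means well-posed, and it is
  stated as such. Defaults $(75, -60, -120, -40)$ induce SPAD ≈ 38–60,
  typical of a heading brassica, with darker/greener canopies scoring
  higher. Channel means are sampled independently so the regression
  design has full rank.

Truth extents are measured from the final rasterised instance mask (after
overlap resolution) and converted with the scene's own GSD, with
`length ≥ width` by the same orientation-free max/min bounding-box
convention trait extraction uses. This closes the loop exactly: perfect
masks through trait extraction recover every plant's recorded size to
within one pixel of ground distance. What passing such tests shows is that
the geometric bookkeeping (bounding boxes, half-open conventions, GSD and
`sr_factor` arithmetic) is consistent end to end — not that the pipeline
would meet any particular accuracy on real orthomosaics, which have
stitching seams, shadows, wind blur and soil heterogeneity the generator
deliberately omits.

A single scene seed fans out to independent substreams (layout, spectra,
texture, degradation noise), so scenes are bit-reproducible and
component-level changes do not perturb unrelated draws.

## Tiling, augmentation and splitting

Scenes are cropped to fixed square tiles on a zero-overlap grid in reading
order; ragged edges are dropped rather than padded, because padding
distorts labels at the border. The instance mask is reduced to a semantic
plant/background mask at this point — the segmenter is semantic, and
instances are recovered downstream by connected components. Tiles split
8:1:1 into train/test/validation by seeded shuffle with largest-remainder
rounding. The training partition (only) is expanded by the minimal closed
operator set {identity, horizontal flip, vertical flip, transpose},
i.e. a fixed 4× factor; augmented views inherit their parent's partition,
so no augmented view of a held-out tile can leak into training. The
paper-scale tile is 608 px; the package default is 96 px so that training
runs on one CPU — tile size only changes how much context the network
sees, not any physical convention.

## Super-resolution stage

The enhancement network is an SRGAN-style pair: a fully convolutional
generator (3×3 convs, `n_residual_blocks` two-conv residual blocks, two
sub-pixel/pixel-shuffle ×2 stages for the 4× upscale) and a small
convolutional discriminator, trained alternately — discriminator first,
then generator — on (low, high)-resolution pairs manufactured by
`degrade_image()` (Gaussian blur, block-mean 4× decimation, additive
noise). Three deliberate departures from the published recipe, made for
small-data CPU training from scratch:

* **No batch normalisation** in the residual blocks: with effective batch
  size 1 and from-scratch weights, BN statistics are ill-posed and
  destabilise training.
* **Global residual over nearest-neighbour upsampling** with a
  near-zero-initialised output convolution: the untrained generator
  reproduces nearest-neighbour upsampling exactly, so training starts at
  that baseline and learns corrections (deblurring, denoising) on top of
  it. Without this, a small generator cannot even reach the baseline
  within a desk-scale epoch budget.
* **Adversarial weight 1e-4** (not the conventional 1e-3): on
  reflectance-domain images the pixel MSE is of order 1e-4–1e-3, so a
  1e-3 adversarial weight dominates the content term and demonstrably
  drags PSNR below the nearest-neighbour baseline; 1e-4 restores the
  intended proportion between the terms.

The perceptual (content) loss defaults to pixel MSE; a feature-space MSE
over a fixed random convolutional extractor is available
(`perceptual_source = "feature_net"`). A pretrained VGG extractor is not
bundled: it would require a weights download, and a fixed random
projection already provides a feature-space comparison.

Quality is reported as PSNR ($10 \log_{10}(\mathrm{MAX}^2/\mathrm{MSE})$,
`Inf` for identical images) and windowed SSIM (Gaussian window sd 1.5,
standard stabilising constants). `max_val` follows the stored image
domain — 1 for reflectance, 255 for 8-bit exports — and must be stated,
because mixing the two silently offsets PSNR by ~48 dB. Enhancement
applies to the RGB bands only; multispectral imagery is never enhanced,
mirroring the three-variant study design.

## Segmentation stage

The segmenter is a UNet: double-conv encoder blocks with 2×2 max pooling,
a double-conv bridge, nearest-neighbour upsampling with skip
concatenation, and a 1×1 softmax head, trained from scratch with
categorical cross-entropy on one-hot targets. The printed budget of 10
convolution layers is realised as two encoder/decoder levels
(4 + 4 convs) plus the 2-conv bridge; the head is not counted. Depth is
configurable through `conv_layer_count` (6, 10, 14 → 1, 2, 3 levels).
The optimiser is Adam — the source names none, and Adam is the Keras-era
default — with the learning rate recorded in the config for auditability.
Inputs are reflectances already in [0, 1]; no dataset-level
standardisation is applied. Per-epoch accuracy and loss are recorded on
the training and validation partitions, and the weights with the best
validation loss are kept (validation-based model selection). Prediction
is per-pixel argmax with ties broken toward the lower class index, so
results are deterministic.

Paper-scale defaults (`unet_config()`: batch 2, learning rate 1e-5, 120
epochs) document the published regime; the desk-scale runs in the tests
use 96-px tiles, 8 base filters, learning rate 1e-3 and ≤5 epochs, which
reach >0.99 held-out pixel accuracy on synthetic scenes in minutes on one
CPU — the synthetic plant/soil contrast makes the task much easier than
field imagery, which is exactly why those accuracies say nothing about
the 94%-level accuracy reported on real mosaics.

## Trait extraction and evaluation

Predicted masks become plant instances by 8-connected component labelling
(hand-implemented; the connectivity is part of the contract), with
components under `min_area_px` (default 30 px) discarded as speckle and
regions numbered in reading order of their top-left bounding-box corner.
All coordinates are 0-based with half-open bounding boxes — one
convention, applied everywhere. Each region reports:

* `length_px`/`width_px`: max/min bounding-box extents. The source never
  defines which image axis is "length"; the orientation-free max/min
  convention is deterministic and matches how rosette diameter pairs are
  measured in the field.
* Channel means over the region's own pixels only (background removed),
  matching the single-plant-after-background-removal convention.
* Physical sizes via `px_to_length()` with the variant's `ground_scale`.

Regions are paired with ground truth by greedy mutual-nearest centroid
matching within `max_match_dist_px` (ties break in reading order);
unmatched regions are false positives, unmatched truths are misses. The
matching procedure between field plants and image regions is not
specified by the source; greedy centroid matching is this package's
stand-in.

SPAD is predicted by ordinary least squares (`stats::lm`) of observed
SPAD on channel means — G alone or R, G, B (`mode`), raw and unscaled, as
no rescaling is stated. Rank-deficient designs error with the collinear
columns named. Predictions are not clipped; values outside the
instrument's 0–99 range are flagged, not altered.

Evaluation reports three statistics:

* $R^2 = \sum(\hat y_i - \bar y)^2 / \sum(y_i - \bar y)^2$ — the
  explained-variance form exactly as printed in the source, which is not
  bounded by 1 (the test suite pins $R^2 = 2.5$ on a worked example).
  The conventional $1 - \mathrm{SSE}/\mathrm{SST}$ is always reported
  alongside as `r2_residual`.
* RMSPE $= \sqrt{\tfrac1n \sum ((y_i - \hat y_i)/y_i)^2}$. The printed
  formula's typography is ambiguous (the square may or may not cover the
  denominator); the relative-error reading is adopted, tested against
  hand-computed cases, and noted here as a decision.
* RMSE $= \sqrt{\tfrac1n \sum (y_i - \hat y_i)^2}$.

$R^2$ requires variance in the actuals; RMSPE requires all actuals
non-zero; both are errors, not NaNs.

## The experiment runner

`run_experiment()` realises the three-variant study design —
multispectral (5 bands), RGB, and RGB with super-resolution — on a shared
pair of scenes: a training scene (tiled, split, used for segmentation
training and SPAD calibration) and a held-out evaluation scene. Sharing
scenes, tiling and split across variants makes the comparison paired;
only input bands and the enhancement step differ. For the SR variant, the
4×-degraded imagery is treated as the native input (the source does not
state how low-resolution inputs arise from a single flight height, so the
degradation model is the declared stand-in) and enhancement recovers the
original grid; its ground scale is `ground_scale(4·gsd, sr_factor = 4)`,
which is numerically the native scale reached through the explicit
super-resolution bookkeeping. Every stage persists its artifact under
`output_dir/stages` and is reused on re-run, so a run is resumable per
stage; all randomness derives from one global seed through tagged
sub-seeds. `compare_variants()` ranks variants per trait by $R^2$ with
RMSE tie-breaks.

Desk-scale problem sizes used throughout the test suite, chosen so the
full suite trains every model on one CPU: 288–672 px scenes, 96 px tiles,
8–16 base filters, ≤5 segmentation epochs, ≤40 SRGAN epochs on ≤16 pairs.

## Known limitations

* The generator omits shadows, wind blur, stitching seams, radiometric
  drift and real soil heterogeneity; accuracies on synthetic scenes are
  upper bounds with respect to these nuisances.
* Only canopy width/length and SPAD are estimated — not height, biomass
  or leaf counts.
* The SPAD model is linear by construction and by assumption; on real
  data the linearity is an empirical question.
* Networks are deliberately small; nothing here is sized for GPU-scale
  training of the published models.

```{r, eval = FALSE}
# A complete desk-scale run:
cfg <- read_experiment_config(
  system.file("extdata", "example_config.yml", package = "uavpheno"),
  output_dir = "uavpheno_run")
report <- run_experiment(cfg)
compare_variants(report)
```
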