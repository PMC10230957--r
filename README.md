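# uavpheno

Per-plant phenotyping of row-planted rosette crops (e.g. heading Chinese
cabbage) from nadir UAV imagery: canopy **width** and **length** in physical
units, and relative chlorophyll content (**SPAD**) from RGB channel means.
The package is aimed at plant-phenotyping researchers who want a tested,
CPU-scale, fully reproducible implementation of this pipeline — from raster
to trait table — without field data or GPUs.

## What it computes

**Photogrammetric scale.** A nadir camera at height *H* with sensor pixel
pitch *a* and focal length *f* resolves the ground at

    GSD = H · a / f        [m per pixel]

so a mask extent of *n* pixels corresponds to `n · GSD / s` metres, where
*s* ≥ 1 is the super-resolution factor of the imagery the mask was measured
on. With the default platform (H = 10 m, a = 3 µm, f = 5.74 mm, 1600 × 1300
px frames): GSD ≈ 5.23 mm/px, frame footprint ≈ 8.36 m × 6.79 m, 608-px
tile ≈ 3.18 m.

**Pipeline.** A synthetic field-scene generator (textured soil, elliptical
canopies in rows, 5 reflectance bands R/G/B/RedEdge/NIR, exact per-plant
ground truth) feeds three model variants compared on shared scenes:

1. *multispectral* — 5-band UNet segmentation;
2. *rgb* — 3-band UNet;
3. *rgb_sr* — RGB imagery passed through an SRGAN-style 4× super-resolution
   generator before segmentation.

Plant instances come from 8-connected components of the predicted mask
(regionprops-style: bounding box, area, centroid, channel means), physical
sizes from the GSD, and SPAD from an ordinary least-squares regression of
observed SPAD on per-plant channel means (G alone, or R, G, B). Predictions
are scored with the explained-variance R² = Σ(ŷᵢ − ȳ)² / Σ(yᵢ − ȳ)² (as
printed in the source study; may exceed 1 — the conventional 1 − SSE/SST is
reported alongside), RMSPE = √(1/n Σ((yᵢ − ŷᵢ)/yᵢ)²) and
RMSE = √(1/n Σ(yᵢ − ŷᵢ)²).

All network training (conv2d forward/backward in Rcpp/Armadillo, Adam,
UNet, SRGAN) is implemented in the package and is single-threaded and
deterministic given a seed.

## Worked example

```r
library(uavpheno)

# photogrammetry
cam <- camera_model()           # 10 m, 3 um, 5.74 mm, 1600 x 1300 px
compute_gsd(cam) * 1000         # 5.226481  (mm per pixel)
image_footprint(cam)$length     # 8.362369  (m)
px_to_length(608, ground_scale(compute_gsd(cam)))  # 3.1777  (m)

# full three-variant experiment at desk scale (~1 minute)
cfg <- read_experiment_config(
  system.file("extdata", "example_config.yml", package = "uavpheno"),
  output_dir = "uavpheno_run")
report <- run_experiment(cfg, quiet = TRUE)
print(report)
compare_variants(report)
```

Output of that run (seed 1, 384-px scene, 12 plants per scene):

```
<comparison_report>
 segmentation accuracy:
   multispectral 0.9958
   rgb           0.9916
   rgb_sr        0.9894
 trait evaluation (eval scene):
       variant  trait        r2 r2_residual      rmspe      rmse  n
 multispectral length 0.8127544   0.9430122 0.02184707 0.5645245 12
 multispectral  width 1.1580381   0.9645777 0.02213649 0.5439894 12
 multispectral   spad 0.9549609   0.8092379 0.02586210 1.2271097 12
           rgb length 0.7693351   0.8493894 0.03686195 0.9177399 12
           rgb  width 1.2070845   0.9400545 0.02928843 0.7076689 12
           rgb   spad 1.0713975   0.8033587 0.02629420 1.2458757 12
        rgb_sr length 0.8887381   0.7313433 0.04805895 1.2257184 12
        rgb_sr  width 1.0762943   0.9019074 0.04060915 0.9052530 12
        rgb_sr   spad 1.1103687   0.7845529 0.02799155 1.3040902 12

Overall (mean rank, best first):
       variant mean_rank
        rgb_sr  1.666667
           rgb  2.000000
 multispectral  2.333333
```

Reading this: all three segmenters exceed 99% pixel accuracy on the held-out
scene (synthetic plant/soil contrast is strong); lengths and widths are
recovered to ~0.5–1.2 cm RMSE on ~20–30 cm plants; SPAD to ~1.2–1.3 SPAD
units at a generative noise sd of 1.5. R² here is the explained-variance
form, so values straddle 1; `r2_residual` is the familiar bounded form.
Per-plant tables (`traits_<variant>.csv`) and the evaluation table land in
`output_dir`, and each pipeline stage caches its artifact there, so
interrupted runs resume per stage.

A thin CLI over the same functions lives at `inst/cli/uavpheno.R`
(`generate`, `tile`, `train-sr`, `train-seg`, `run-all`, `compare`, …):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/uavpheno.R", package="uavpheno"))')" \
    run-all --config inst/extdata/example_config.yml --output run1 --seed 1
```

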