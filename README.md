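# octez — outer-retina ellipsoid-zone analysis for SD-OCT

`octez` is an R toolkit for quantifying the **ellipsoid zone (EZ)** — the
outer-retinal band whose integrity tracks photoreceptor health — in
spectral-domain optical coherence tomography (SD-OCT) B-scans, aimed at
inherited retinal degenerations (e.g. *RPE65*-associated disease) where the
EZ attenuates, thins and shortens. It provides the full chain:

* **Phantoms** — synthetic Spectralis-like B-scans and volume scans with
  exact ground-truth layer masks, a foveal pit, multiplicative speckle, and
  disease-style EZ attenuation/shortening (`phantom_spec()`,
  `generate_bscan()`, `generate_volume()`).
* **Segmentation** — a modified four-level U-Net (double 5×5 conv blocks,
  batch norm + leaky-ReLU, 16 base filters doubling per level, transposed-conv
  decoder, ~1.2 M parameters) classifying every pixel into
  {background, EZ, OPL zone, ELM zone, IZ+RPE+BM}, trained with the combined
  loss *L = (1−λ)·Dice + λ·weighted cross-entropy*. The network — forward,
  backprop, Adam — is implemented in RcppArmadillo; no external deep-learning
  framework is required. Wide scans are processed as full-height 128-column
  patches with 64-column overlap and stitched by probability averaging.
* **EZ biomarkers** per A-scan, from intensity profiles inside the segmented
  bands (all distances scaled by the axial resolution S_y ≈ 3.5 µm/px):
  - weighted peak distances **OPL_EZ, ELM_EZ, BM_EZ, ELM_BM** (µm),
  - **EZ_Th** — mean EZ thickness (µm),
  - **rEZI** — relative EZ intensity, mean of (P_EZ − P_OPL)/P_EZ in %,
  - **EZ_TV** — EZ granularity: total-variation-denoised (ROF, α = 0.05)
    local gray-level variation over a ±β-column neighbourhood (β = 3),
    normalized by 2βN, in %,
  sampled full-scan and at 0.5 mm nasal/temporal to the fovea.
* **En-face mapping** — per-B-scan EZ limits, linear interpolation between
  B-scans, EZ **area** in mm² (121 µm²/pixel) inside a 6-mm ETDRS region of
  interest, and EZ **width** as % of the ROI.
* **Statistics** — Shapiro–Wilk-routed two-group tests (t vs Wilcoxon
  rank-sum) and a Pearson correlation screen flagging r > 0.3.

See `vignettes/octez-methods.Rmd` for the model details, parameter defaults
and design choices.

## Worked example

Simulate a noise-free phantom, compute the biomarker record, and read off
the EZ measures:

```r
library(octez)

spec <- phantom_spec(image_height = 64, image_width = 160,
                     opl_depth = 26, opl_thickness = 5, opl_reflectance = 0.55,
                     elm_depth = 36, elm_thickness = 3, elm_reflectance = 0.50,
                     ez_depth  = 41, ez_thickness  = 3, ez_reflectance  = 0.85,
                     rpe_depth = 47, rpe_thickness = 5, rpe_reflectance = 0.90,
                     pit_depth = 0, pit_width = 0)
ph  <- generate_bscan(spec, seed = 1)
rec <- biomarker_record(ph$image, ph$mask, alpha = 0, beta = 3)
subset(rec, region == "full-scan")
```

```
     region measure     mean sd   n
1 full-scan  opl_ez 49.00000  0 160
2 full-scan  elm_ez 17.50000  0 160
3 full-scan   bm_ez 31.50000  0 160
4 full-scan  elm_bm 49.00000  0 160
5 full-scan   ez_th 10.50000  0 160
6 full-scan    rezi 35.29412  0 160
7 full-scan   ez_lv  0.00000  0 160
```

Every number is the geometry read back exactly: the EZ peak sits at row 42
and the OPL peak at row 28, so OPL_EZ = 14 px × 3.5 µm = **49 µm**; the EZ
band is 3 px, so EZ_Th = **10.5 µm**; rEZI = (0.85 − 0.55)/0.85 =
**35.29 %**; a noise-free phantom has zero EZ local variation. Note the
additivity ELM_BM = ELM_EZ + BM_EZ (17.5 + 31.5 = 49), which holds per
A-scan whenever the peaks are anatomically ordered.

Training the segmenter on a phantom population and segmenting a held-out
scan:

```r
specs <- sample_phantom_specs(200, seed = 11)
train <- lapply(seq_along(specs), function(i) {
  out <- generate_bscan(specs[[i]], seed = 100 + i)
  list(image = out$image$pixels, mask = out$mask)
})
cfg <- unet_config(epochs = 6, batch_size = 8, patch_width = 64, overlap = 0)
fit <- train_segmenter(train, config = cfg)

test  <- generate_bscan(sample_phantom_specs(1, seed = 99)[[1]], seed = 1)
pred  <- predict_classmap(fit$model, test$image)
segmentation_metrics(pred$mask, test$mask)
```

A command-line front end wrapping these functions lives at
`inst/cli/octez.R` (verbs `simulate`, `train`, `segment`, `biomarkers`,
`enface`, `stats`, `run`).

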