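---
title: "Quantifying the ellipsoid zone in SD-OCT: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the ellipsoid zone in SD-OCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octez)
```

## The problem

In spectral-domain optical coherence tomography (SD-OCT) of the outer
retina, the **ellipsoid zone (EZ)** — the second hyperreflective outer
band, at the photoreceptor inner/outer-segment junction — is a sensitive
structural correlate of photoreceptor health. In inherited retinal
degenerations such as *RPE65*-associated disease, the EZ attenuates,
thins and shortens laterally long before other layers are visibly
involved. `octez` implements an automated analysis chain for this
setting:

1. **segmentation** of each B-scan into five classes
   (0 background, 1 EZ, 2 OPL zone, 3 ELM zone, 4 IZ+RPE+BM) with a
   four-level U-Net;
2. **per-A-scan biomarkers** of the EZ computed from intensity profiles
   within the segmented bands;
3. **en-face quantification** of the EZ footprint in volume scans
   (area in mm², width as a percentage of a 6-mm ETDRS region of
   interest);
4. **group statistics** with normality-routed tests and a Pearson
   correlation screen.

Because no public SD-OCT dataset accompanies this problem, the package
ships a first-class **phantom generator** whose ground truth is exact by
construction; every downstream stage is validated against it.

## The phantom model

A phantom B-scan (`phantom_spec()`, `generate_bscan()`) is a stack of
four hyperreflective bands over a dark background, rendered at
Spectralis-like sampling (496-row A-scans at ~3.5 µm/pixel axial,
11 µm/pixel lateral so one en-face pixel is ≈121 µm²). Design choices:

* **Band profile.** Within a band the reflectance follows a raised
  cosine, renormalized so the *sampled* maximum equals the configured
  reflectance even for even band heights. This makes each band's
  intensity peak well defined, interior, and exactly recoverable — the
  property the peak-distance biomarkers rely on.
* **Foveal pit.** A Gaussian depression (depth in pixels, FWHM in
  pixels) shifts every band posteriorly near the fovea. Top and bottom
  of each band shift together, so per-column band thickness is
  preserved exactly; the pit exercises fovea-centred sampling without
  confounding thickness recovery.
* **Disease knobs.** `ez_attenuation` multiplies the EZ reflectance;
  `ez_extent_mm` truncates the EZ laterally around the fovea. Volume
  phantoms (`generate_volume()`) give each B-scan the EZ extent of an
  elliptical footprint cross-section, which has a closed-form area to
  validate against.
* **Speckle.** Multiplicative gamma noise with unit mean and standard
  deviation `speckle_level` (shape 1/level², scale level²), the standard
  OCT speckle surrogate; unit mean preserves band reflectances on
  average. Output is clipped to [0, 1].

What the phantom does **not** emulate: photorealistic texture, inner
retinal layers, vascular shadowing, motion/nystagmus artifacts, or
Spectralis intensity calibration (raw control-eye intensity
distributions are not published, so reflectances are free parameters).
Tests passing on phantoms therefore demonstrate algorithmic
correctness — exact geometry recovery, oracle equivalence,
learnability — not clinical performance.

## Segmentation

The network (`build_unet()`) is a four-level U-Net: double 5×5
convolution blocks with batch normalization and leaky-ReLU, 16 filters
at the first level doubling per encoder level, 2×2 max pooling, a
mirrored decoder with 2×2 stride-2 transposed convolutions and skip
concatenations, and a final 1×1 convolution onto 5 classes
(`r format(build_unet(unet_config())$n_params, big.mark = ",")`
parameters — about 1.2 M). It is implemented directly in
RcppArmadillo (float32, im2col/GEMM convolutions, analytic
backpropagation verified against finite differences in the test suite,
Adam optimizer). The network is fully convolutional; inputs need height
and width divisible by 8.

**Loss.** Training minimizes
$$L = (1-\lambda)\,L_{\text{Dice}} + \lambda\,L_{\text{wCE}},$$
with $\lambda \in (0,1)$ (default 0.5 — a symmetric mix, since no
published value exists). $L_{\text{Dice}}$ is the soft Dice loss
averaged over classes with smoothing $\varepsilon = 1$ in numerator and
denominator, so classes absent from prediction and truth contribute no
loss or gradient pathology. $L_{\text{wCE}}$ is class-weighted
cross-entropy normalized by the realized weight sum; weights default to
inverse class frequency computed on the training masks, which
counteracts the extreme imbalance of the thin EZ/ELM bands against the
background (~95 % of pixels).

**Patching.** Wide scans are split into full-height patches of 128
columns with a 64-column overlap (stride = width − overlap). A
1024-wide high-resolution scan yields 15 patches, a 768-wide high-speed
scan 11; when the width is not aligned to the stride, the final patch
is completed by reflecting the image about its right edge. At
inference, per-patch probabilities are stitched by arithmetic averaging
on overlaps followed by renormalization — order-independent and
idempotent where patches agree — and the label is the per-pixel argmax
with ties broken toward the lower class index.

**Splitting.** Train/validation splits are at the *participant* level
(all scans of an eye follow their participant) and stratified by
cohort, with per-stratum training counts rounded half away from zero;
a roster of 94 controls + 22 patients at 80/20 yields 93 training
participants (75 + 18), independent of the seed.

**Training scale.** The learnability checks train the full 16-filter
architecture on 200 randomized 64×64 phantoms (batch 8, Adam at 1e-3, 6
epochs) and evaluate EZ-class Dice on 20 held-out phantoms; a
single-phantom overfit run (250 steps) verifies capacity. These sizes
are the package's chosen test scale: the architecture is exactly the
clinical one, while the raster is smaller so the whole suite stays
convenient on a laptop CPU. Optimizer, learning rate and epochs are
config-exposed (`unet_config()`) rather than asserted as canonical.

## Per-A-scan biomarkers

All biomarkers operate on intensities normalized to [0, 1] and use the
axial resolution $S_y$ (µm/pixel, default 3.5) to convert pixel
distances to micrometres. Columns missing any required layer are
excluded from each biomarker's mean and the number of valid columns is
reported — atrophic retinas routinely lose the EZ in part of the scan,
and silently averaging zeros would bias every measure.

**Weighted peak distances.** For each A-scan, the intensity peak inside
each segmented band (ties broken to the inner row, deterministically)
and the BM boundary — the outermost pixel of the IZ+RPE+BM band — give
four distances: OPL–EZ, ELM–EZ, BM–EZ, ELM–BM, each $|\Delta\text{row}|
\cdot S_y$. Distances are reported as magnitudes: clinical tables are
all-positive, and magnitudes preserve the per-column identity
$\text{ELM\_BM} = \text{ELM\_EZ} + \text{BM\_EZ}$ whenever the peaks
are anatomically ordered (ELM above EZ above BM) — a property the test
suite asserts exactly.

**EZ thickness.** Mean over EZ-bearing columns of the inclusive band
height, $(\text{lower} - \text{upper} + 1)\cdot S_y$. The inclusive
count makes a one-pixel band $S_y$ thick rather than zero — a
difference-form definition is ambiguous on this point, and a band that
exists should not have zero thickness.

**Relative EZ intensity (rEZI).** Mean over valid columns of
$(P_{EZ} - P_{OPL})/P_{EZ}$, in percent, where $P$ are the per-column
peak intensities. The OPL peak is the reference. The sign is preserved
(negative where the OPL outshines the EZ); columns with a zero EZ peak
are excluded and counted.

**EZ granularity.** After ROF total-variation denoising with parameter
$\alpha$ (default 0.05), the local variation of column $x$ sums absolute
gray-level differences against its $2\beta$ lateral neighbours over the
column's EZ rows ($\beta \in \{3,5,7\}$, default 3; out-of-range
neighbours skipped), and the scalar granularity is
$$EZ_{TV} = \frac{\sum_x EZ_{LV}(x)}{2\beta N}\times 100,$$
with $N$ the number of EZ-bearing A-scans. Note the normalization does
**not** divide by the EZ band height; the per-column row count is
recoverable from the band structure if a user wants to post-normalize.
A flattened, degraded EZ gives low $EZ_{TV}$; heavier smoothing
(larger $\alpha$) monotonically lowers it on noisy scans, which the
tests assert over $\alpha \in \{0.005, 0.05, 0.5\}$.

**TV denoising.** `tv_denoise()` solves the ROF model
$\min_u \tfrac12\|u-f\|^2 + \alpha\,TV(u)$ with Chambolle's dual
projection iteration (step $\tau = 0.125$, convergence tolerance 1e-4
on the image update). On single-row images the scheme reduces to 1-D
ROF, whose closed-form solution on two-plateau signals (each plateau
shrinks toward the other by $\alpha/n_i$) is the analytic oracle in the
tests; on 2-D images the output's total variation never exceeds the
input's.

**Regional sampling.** Biomarkers are reported full-scan and at 0.5 mm
nasal and temporal to the foveal centre, averaging over a ±0.1-mm
window. The locus is standard; the window half-width is a package
choice (no averaging extent is published) — wide enough to be robust to
single-column noise at 11 µm sampling (±9 columns), narrow enough to
stay local. Nasal means toward the optic disc: right of the fovea in
left-eye scans, left in right-eye scans.

## En-face EZ area and width

Per B-scan, the EZ extent is the outer envelope between the leftmost
and rightmost EZ column — interior gaps within one B-scan are bridged
by convention, matching a two-limit formulation; scans without EZ are
flagged absent. Left and right limits are linearly interpolated (in
column units against slow-axis position) across absent runs bounded on
both sides by EZ-bearing scans; absent runs at the volume edge are
**not** extrapolated. The footprint is resampled on a square en-face
grid (11 µm pitch by default, ≈121 µm²/pixel), masked by the region of
interest, and tallied into mm².

The ROI defaults to the 6×6-mm **square** bounding the ETDRS circle
rather than the 6-mm disc: published control-eye EZ areas (≈34.5 mm²)
exceed the disc's 28.27 mm², so the effective clinical ROI cannot have
been the disc; both shapes are exposed by flag. EZ width per B-scan is
the ROI-clipped extent over the 6-mm diameter, in percent, clipped to
[0, 100].

## Statistics

`compare_groups()` reproduces the clinical routing rule: Shapiro–Wilk
on both samples; both p > 0.05 → two-sided two-sample t test (Welch by
default — equal variances were not asserted, and Welch is the safer
default; the pooled form is a switch), otherwise the Wilcoxon rank-sum
test (exact enumeration when both n ≤ 20 without ties, otherwise the
continuity-corrected normal approximation). Constant samples, for which
Shapiro–Wilk is undefined, are handled explicitly: two identical
constant groups give a degenerate null result (p = 1) and a single
constant sample routes to the rank-sum test. No multiple-testing
correction is applied, matching per-biomarker raw-p reporting.
`correlation_screen()` computes pairwise Pearson r over complete cases
and flags r > 0.3 on the *signed* coefficient — negative associations
are reported with a note but never flagged.

## Numerical and degenerate-input conventions

* Rasters are row 1 = innermost (vitreous side), columns = A-scans,
  1-based indexing throughout the R API.
* Peak ties break to the inner (smaller) row; argmax ties break to the
  lower class index; max-pool ties route gradient to the first maximum
  in a fixed scan order. All deterministic.
* Biomarkers on scans with zero valid columns return explicit `NA`
  with `n = 0`, never silent zeros.
* Identical seeds give bit-identical phantoms, augmentations, splits
  and training runs.

## Demonstration scale

```{r pipeline-demo, eval = FALSE}
cfg <- pipeline_config(out_dir = tempfile("octez"), seed = 1,
                       n_control = 6, n_patient = 6)
res <- run_pipeline(cfg)
head(res$comparisons)
```

The bundled pipeline demo simulates two small cohorts (96×192 phantoms,
speckle 0.15, patients with EZ attenuation 0.55 and extent 0.7 mm),
segments from ground truth by default, and writes biomarker and
comparison tables plus a provenance log; `scripts/acceptance.R`
recomputes the package's headline quantities from scratch at the same
scales. Sizes were chosen so the full chain — including network
training in the test suite — completes comfortably on one CPU.

## Known limitations

* The trained clinical model and its weights are not reproduced;
  learnability is demonstrated on phantoms only.
* The granularity normalization ties $EZ_{TV}$ to the EZ band height;
  comparisons across datasets with different axial sampling should
  post-normalize by the band row count.
* Proprietary Spectralis containers (.vol/.e2e) are out of scope;
  rasters travel as PNG/TIFF with JSON sidecars.
* The en-face ROI inference (square vs disc) is a documented judgement
  call, switchable by flag.
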