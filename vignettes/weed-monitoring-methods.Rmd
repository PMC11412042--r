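---
title: "Monitoring grass weeds in wheat: models, generators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring grass weeds in wheat: models, generators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(weedsight)
```

## The problem

Graminaceous (grass) weeds such as *Alopecurus* and *Poa* are the dominant
weeds of wheat during the overwintering and jointing phases, and they are
notoriously hard to monitor from the air: their colour histograms and
400–1000 nm reflectance curves nearly coincide with those of wheat
seedlings, differing appreciably only in narrow green and red regions.
What does separate the two at UAV resolution is fine leaf texture. This
package implements an end-to-end analysis built on that premise:

1. a **three-class semantic segmenter** (soil / wheat / weed) over RGB
   orthoscenes, from which the weed **canopy cover** (CC) is read off as a
   pixel fraction;
2. **narrowband NDVI band-pair selection**: an exhaustive sweep of
   `NDVI(lambda_i, lambda_j)` over all hyperspectral band pairs, correlated
   with weed biomass, to find the most informative pair;
3. a **support-vector regression** of weed biomass on CC plus vegetation
   indices (NDVI, RVI, SAVI, and the selected narrowband NDVI);
4. a descriptive **impact analysis** of weed infestation on wheat dry
   weight and grain yield across sowing method, plant density, and growth
   stage.

Field campaigns of this kind rarely ship public imagery, so all inputs
here are produced by a first-class synthetic generator whose structure
and effect sizes are fixed up front; every downstream stage is tested
against what the generator planted.

## The segmentation model

The segmenter is an encoder–decoder convolutional network with atrous
spatial pyramid pooling (ASPP). The encoder is a four-stage residual
network whose deepest stage keeps 1/16 resolution by replacing its stride
with dilated (rate-2) convolutions. The ASPP head applies five parallel
branches to the deepest features — a 1×1 convolution, three 3×3
convolutions at dilation rates 6, 12 and 18, and a global-average-pooling
branch — and fuses their concatenation with a 1×1 convolution. The decoder
projects an early 1/4-resolution feature map to 48 channels with a 1×1
convolution, upsamples the ASPP output 4-fold (bilinear), concatenates,
applies a 3×3 convolution, and upsamples 4-fold again before a per-pixel
softmax over the three classes. Exact probability ties resolve to the
lowest class index (soil < wheat < weed).

Two presets share this topology:

| preset | stage widths | head | input | intended use |
|--------|--------------|------|-------|--------------|
| `desk` | 16/32/64/128 | 64   | 96 px | CPU-scale training, tests |
| `full` | 64/128/256/512 | 256 | 320 px | GPU-scale capacity class |

The `desk` preset exists so that the full train–validate loop runs on a
single CPU core in minutes; it has more than an order of magnitude fewer
parameters than `full`. Training minimizes mean per-pixel cross-entropy
with Adam (default learning rate `1e-3`, batch 8, 20 epochs — these
hyperparameters are package defaults, surfaced in `train_config()`), and
the returned checkpoint is the epoch with the best validation MIoU. The
whole network — im2col convolutions, batch normalization, bilinear
upsampling, and their adjoints — is implemented in the package over BLAS
matrix products (with a small C++ gather/scatter kernel) and is verified
against central finite differences in the test suite. Batch-norm running
statistics are seeded from the first training batch and then updated with
momentum 0.1, so even very short runs evaluate coherently.

`infer_mask()` processes images whole when their sides are divisible
by 16 (two 4-fold upsamplings); larger or ragged images are processed in
`input_size` chunks on an overlap-free grid with border chunks aligned to
the image edge, and reassembled by provenance.

## Accuracy metrics

Segmentation accuracy derives from a K×K confusion tensor via one-vs-rest
counts: `IoU = TP/(TP+FP+FN)`, MIoU the unweighted mean over evaluated
classes (a class absent from both truth and prediction is excluded and the
denominator adjusted), `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
and `F1 = 2TP/(N+TP-TN)` — which is algebraically identical to the
harmonic-mean form, an identity the tests check on random draws. An
undefined precision (class never predicted) is reported as `NA`, never
as zero. Stratified reports pool pixels within a stratum rather than
averaging per-tile metrics, so every pixel carries equal weight; the two
conventions genuinely differ on unequal tiles and the pooled one is the
package's documented choice.

Regression accuracy uses `RMSE = sqrt(mean((pred-obs)^2))`,
`R^2 = 1 - SSE/SST`, and a relative error in prediction defined here as
`REP = 100*RMSE/mean(obs)` percent. REP has no universally fixed
definition; the RMSE-over-mean form is this package's documented
convention.

## The synthetic scene generator

`render_scene()` produces a co-registered RGB image, an optional 176-band
reflectance cube (400–1000 nm, ~3.4 nm sampling, consistent with a
3.5 nm-resolution pushbroom sensor), and an exact 3-class mask on one
pixel grid.

**Layout.** Drilled scenes place wheat along parallel, slightly wavy rows
at a configurable pixel spacing; broadcast scenes threshold a smooth
two-octave noise field into irregular clumps. Weed patches are clustered
Gaussian blobs. Class assignment thresholds continuous fields at exact
pixel counts, so cover targets are hit to within one pixel.

**Colour and texture.** Wheat and weed take their RGB colour from the
same endmember windows (B 450–495, G 495–570, R 620–700 nm), and their
endmembers differ only by small *bipolar* offsets inside the green and
red windows that integrate to roughly zero over each broadband window —
so the two classes are nearly indistinguishable by colour (per-channel
histogram intersections ≥ 0.8, typically ≥ 0.95), mirroring the field
situation. What distinguishes them is texture: wheat renders as a
high-frequency oriented stripe pattern (thin blades, period ≈ 3.2 px,
row-aligned under drilling), weeds as a coarser pattern (period ≈ 7.5 px)
with independent orientation. Both modulations share one amplitude
distribution, so colour histograms stay matched.

**Occlusion.** Overhanging wheat hides a fraction of weed pixels from the
nadir view. The generator relabels exactly that fraction of weed pixels —
those nearest to wheat canopy — as wheat in the image, cube and mask,
while the recorded truth covers keep their pre-occlusion values; the mask
weed fraction therefore equals `truth_cover × (1 − occlusion_rate)` to
within a pixel. Defaults follow field observation: 5% during wintering,
10% at jointing, +3 points at high plant density, never above 20%.

**Spectra.** Cube pixels are class endmembers scaled by the local canopy
density and texture, plus Gaussian sensor noise. Vegetation reflectance
responds to biomass through a band-wise coupling profile peaked at a
designated band pair per class and stage — (960, 733) and (960, 719) nm
for wheat and weed during wintering, (960, 710) and (960, 700) nm at
jointing — with gains at the NIR band and losses at the red-edge band.
Two further design elements make the designated pair *recoverable by an
NDVI sweep*, not merely planted:

- the canopy response `f(biomass)` is parameterized so the designated
  pair's NDVI is exactly linear in biomass (inverting the rational NDVI
  form at that pair) — encoding the premise that the selected narrowband
  NDVI is a linear biomass proxy;
- sample-to-sample canopy condition (closure, pigment, illumination
  geometry) perturbs reflectance multiplicatively through two
  wavelength-dependent amplitude profiles — a spectral ramp and a clipped
  parabola — both of which take a common value exactly at the designated
  band pair. A normalized difference only cancels a multiplicative
  perturbation whose amplitude is equal at its two bands, so the nuisance
  drops out of the narrowband NDVI at the designated pair and nowhere
  jointly else. This is the generator's mechanism for *why* one pair is
  empirically best, and the band-pair sweep must rediscover it.

With the default reflectance noise (sd 0.01) the sweep recovers the
planted wintering pairs essentially always and the jointing pairs in
most draws (their designated red bands sit lower on the red edge, where
NDVI is intrinsically noisier); in every case the designated pair
correlates more strongly with biomass than at least 95% of all pairs.

**What the generator does not emulate.** No radiative transfer (leaf
angle, multiple scattering), no georeferencing or stitching artifacts, no
mixed boundary pixels (masks are exact), no weed species distinction
beyond one "grass weed" class, and no illumination/BRDF field structure.
Passing tests therefore demonstrate that the *pipeline* recovers what the
generator embeds under realistic noise — not that the trained desk model
would transfer to real UAV imagery.

## The field-trial generator

`simulate_plot_trials()` draws a factorial trial — weed-emergence stage
(W/J) × sowing (B/D) × plant density (L/H) × ordinal weed level 0–3, ten
replicate plots per cell by default. Weed-free controls sit at configured
means (grain yield 7200 kg/ha at high density, 6800 at low; dry weight
8200/7800). The reduction schedule is anchored at the worst cell
(broadcast, high density, wintering weeds, top level): 71% dry-weight and
60% yield reduction — 4320 kg/ha below the 7200 kg/ha control. Other
cells attenuate multiplicatively (drill ×0.80, low density ×0.85,
jointing ×0.75), so broadcast > drill, high > low, wintering > jointing
in effect size. Intermediate weed levels interpolate linearly between
control and the maximum; the interpolation is this package's choice, not
a reported measurement. Noise is multiplicative log-normal with a
mean-one parameterization, so cell means are unbiased; with sd 0.05 and
ten replicates, recovered maxima land within about one percentage point
of the schedule.

`simulate_plot_features()` emulates what the imaging pipeline would
deliver per plot: weed canopy cover as a saturating function of biomass
plus observation noise (sd 0.03 — segmentation-derived cover carries
boundary and occlusion error), and vegetation indices computed from
simulated weed-area mean spectra. A small reflectance floor keeps the
ratio index finite in dark red-absorption bands.

## Biomass estimation

`fit_biomass_model()` draws a seeded 50/50 modeling/validation split,
standardizes features *and* the response with modeling-half statistics
only (the tests assert the absence of leakage), and fits an
epsilon-insensitive support-vector regression (radial kernel, C = 10,
epsilon = 0.1, kernel width 1/(d × mean feature variance) — all exposed
and all package defaults, since such hyperparameters are rarely printed
in field studies). Scores on both halves come from the same
`regression_scores()` used everywhere else. Univariate baselines (CC
only, or one index only) are ordinary least squares per stage × sowing
cell; under the default generator they validate worse than the CC+VI
model in at least three of the four cells, reproducing the qualitative
ordering that motivates the multivariate model.

## Impact analysis

`reductions_vs_control()` compares each treated cell mean against its own
weed-free control; `max_reduction()` extracts the extreme relative or
absolute reduction (ties resolve to the first key in sorted order);
`factor_contrasts()` reports the sowing/density/stage orderings. The
module is deliberately descriptive — no hypothesis tests are attached,
matching the descriptive character of the analysis it mirrors.

## Numerical and scale choices

- **Problem sizes.** The package's reference protocol trains the desk
  preset on 500 synthetic 96-px tiles (70/30 split, 20 epochs, seed 1),
  reaching validation MIoU around 0.89 in a few minutes on one CPU core;
  the plumbing checks tile 1000 scenes of 636×1590 px into exactly 10,000
  tiles of 318×318 and split them 7000/3000. Mask-only rendering
  (`include_rgb = FALSE`) exists for such layout-scale studies.
- **Determinism.** Every stochastic step takes an integer seed; identical
  (config, seed) gives bit-identical scenes, trials, splits and training
  histories on a fixed thread configuration.
- **Degenerate inputs.** Zero-denominator index pixels are `NaN` and
  excluded from downstream means; constant observations flag `R^2` as
  `NA`; a class absent from truth and prediction is excluded from MIoU;
  an undefined precision is `NA`; degenerate band pairs are flagged and
  skipped by the sweep's argmax.
- **Tiling.** 0-based, row-major provenance coordinates, origin top-left;
  partial border tiles are dropped; stitching by provenance reconstructs
  the cropped region exactly.
- **SAVI soil factor.** L defaults to 0.5, the conventional intermediate
  value, and is a parameter.

## Known limitations

The desk-scale segmenter is a capacity-reduced analogue, not a
reproduction of GPU-scale training; real-field transfer is out of scope.
The generator's texture dichotomy is cleaner than real canopies, which is
why near-ceiling segmentation accuracy is attainable — stated the other
way, a model that fails here is certainly broken, but one that passes is
not thereby field-ready. Validation-half RMSEs depend on plot-level
observation noise whose true field values are unknowable without the
original data; only the modeling-half accuracy bound (R² ≥ 0.85 per
cell) is treated as a quantitative anchor.
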