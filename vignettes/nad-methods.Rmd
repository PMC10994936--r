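---
title: "Attenuation-based tumor-margin mapping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attenuation-based tumor-margin mapping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(octnad)
```

# The model

An OCT A-scan measures backscattered intensity along the beam axis. Under
the single-scattering approximation the signal decays exponentially with
depth,

$$I(z) \propto e^{-2\mu_t z},$$

where $\mu_t$ (mm⁻¹) is the total attenuation coefficient of the medium
and the factor 2 accounts for the round trip of the light. Inverting this
relation pointwise, $\mu_t = -\tfrac{1}{2}\,\partial_z \ln I$, is exact on
noiseless data but hopeless under speckle; `octnad` therefore estimates
$\mu_t$ as minus half the ordinary-least-squares slope of $\ln I$ against
depth over a sliding window (40 samples, 375 µm at the default 9.375 µm
axial pitch). The pointwise inversion is kept as `oac_pointwise()` for
comparison only.

Tumor tissue attenuates more slowly than normal parenchyma, so an en-face
map of $\mu_t$ at fixed depth below the surface shows the tumor as a
low-OAC region. Because the *measured* OAC also declines with depth for
instrumental reasons (beam focus, sensitivity roll-off), a fixed
threshold fails at depth. The chain therefore normalizes each en-face map
against a fixed tumor ROI (min–max, so the ROI spans [0, 1] at every
depth by construction), low-pass filters, and takes the RMS of the x- and
y-forward differences:

$$\mathrm{NAD} = \sqrt{\left(\Delta \mathrm{NOAC}_x\right)^2 +
                       \left(\Delta \mathrm{NOAC}_y\right)^2}.$$

NAD is a gradient magnitude on the normalized map: non-negative, zero in
homogeneous regions, large at lateral attenuation discontinuities — the
tumor margin — at any depth at which the margin exists.

**Assumptions.** Single scattering (no multiple-scattering tail), a
detectable air–tissue interface on most A-lines, a piecewise-homogeneous
medium at the scale of the fit window, and a user-supplied ROI that lies
inside the tumor. The method highlights *all* OAC discontinuities; a
high-attenuation white-matter tract (e.g. the corpus callosum) produces a
NAD response just like a tumor margin does, and no attempt is made to
classify the two.

# Parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `fit_window_px` | 40 | samples | 375 µm at 9.375 µm pitch; long enough to average speckle along z, short enough to stay locally homogeneous |
| `lateral_avg_width` | 21 | A-lines | nearest odd width to a 20-line window, so the average stays centred and maps stay registered; 20 (left-biased) available for literal fidelity |
| `average_domain` | `"log"` | — | see below |
| `lowpass_sigma_px` | 2 | px | suppresses residual speckle grain (~3 px at the 28 µm lateral resolution and 9 µm pitch) without erasing margins |
| `surface_presmooth_px` | 3 | samples | stabilizes the argmax of the axial difference under speckle; set to 1 on noiseless data, where raw detection is pixel-exact |
| `refractive_index` | 1 | — | divisor applied to a sidecar's air-path axial spacing at load; spacings inside the package are always in tissue |
| `depths_um` | all evaluable | µm | every window-start sample from the surface to the deepest depth at which at least half the pixels are unmasked |

# Why the lateral average runs on the log signal

The OAC estimator is a slope fit on $\ln I$. If neighbouring A-lines are
averaged in the *linear* intensity domain, then near a boundary between
attenuations $\mu_1 < \mu_2$ the averaged signal is a mixture
$f\,e^{-2\mu_1 z} + (1-f)\,e^{-2\mu_2 z}$, whose logarithm is dominated by
the slowly decaying component at depth: even a small tumor fraction $f$
makes the fitted slope look tumor-like. The apparent margin then creeps
*outward* with depth by up to half the averaging window. Averaging the
log-compressed B-scan instead (a geometric mean — and the B-scan "image"
conventionally displayed in OCT *is* log-compressed) keeps the estimator
linear in the averaged quantity: the fitted OAC at a mixed pixel is the
corresponding mixture of slopes, transitions stay laterally symmetric,
and the NAD ridge sits on the geometric boundary at every depth. Speckle
suppression is equivalent: per-pixel spread still falls by roughly the
square root of the window width, and the log-domain speckle offset
($\mathbb{E}[\ln u]$ for unit-mean exponential $u$) is constant in depth,
so it cancels in the slope. `average_domain = "linear"` restores the
literal linear-domain reading for comparison.

# Numerical and design choices

* **Surface detection** differences `log1p(I)` rather than raw intensity
  so bright speckle spikes do not dominate; ties in the argmax break at
  the shallowest index (the physical surface is the first large rise). An
  A-line is invalid when its best rise is below 5× its own median
  absolute axial difference (or below an absolute floor of 10⁻⁶, so
  numerical dust on featureless A-lines never counts). Invalid A-lines
  are masked, never interpolated. A 3×3 median filter regularizes the
  height map; it is optional because it nudges single-column staircase
  steps, which is also why the noiseless-exactness checks run with
  `median_filter = FALSE` and no presmoothing.
* **Window-start convention.** `depth_um` is converted to the nearest
  sample and the fit window *starts* there; the realized start depth is
  recorded on every map. A map therefore characterizes tissue over
  `[d, d + 375 µm]`, which matters when interpreting margins near the
  bottom of a lesion.
* **Missing data.** Non-positive intensities have no logarithm and are
  treated as missing; fits with fewer than 3 usable samples are masked.
  Negative fitted OACs (possible under speckle) are retained and counted,
  never clipped — clipping would bias the subsequent ROI normalization.
* **NOAC is not clipped to [0, 1].** The normalization guarantees the
  range only inside the ROI; clipping elsewhere would flatten gradients
  at bright normal structures and erase their margins. A degenerate ROI
  (equal min and max, e.g. on noiseless homogeneous phantoms) is an
  error, not a silent division by zero.
* **Low-pass filtering** is a separable truncated Gaussian (support
  4σ) applied as a normalized convolution: the kernel is renormalized
  over the unmasked support, so masked holes neither bleed `NA` outward
  nor darken their neighbourhood, and σ = 0 is the exact identity. The
  filter runs after normalization; the two commute up to the affine map,
  so the order is observable only through clipping, which is off.
* **Staggered grids.** The x- and y-differences live on half-pixel
  staggered grids; NAD pairs `Δx(i, j)` with `Δy(i, j)` on the common
  corner grid, whose cell (i, j) sits at original coordinate
  (i + ½, j + ½). The ridge-localization helpers account for this offset.
* **Ridge radius.** `ridge_radius()` reports the radius of maximal
  angular-mean NAD around a seed point (bilinear interpolation along 360
  rays, 0.25 px radial step); averaging over angle before the argmax
  makes the statistic robust to speckle. The per-ray tracer used by
  `extract_boundary()` additionally smooths each radial profile over
  ~1 px and applies a circular median over 9 neighbouring rays, since a
  closed boundary varies slowly with angle. Radial quantization means
  "strictly shrinking" margin sequences can contain exact ties at the
  0.25 px resolution.
* **I/O.** The bit-exact volume format is raw little-endian float32 plus
  a JSON sidecar; multi-page TIFF export quantizes to 16-bit unsigned
  with the scale recorded in the sidecar (the available TIFF writer
  stores integer samples only). Every rendered PNG is paired with a
  full-precision CSV so tests and downstream analyses never read numbers
  off pixels.

# What the phantoms emulate — and what they do not

`phantom_spec()` builds volumes with a surface (flat, tilted plane, or
Gaussian bump), Beer–Lambert decay through a voxelized attenuation field
(background plus ellipsoid/cylinder/slab inclusions, later inclusions
overriding earlier), and fully developed intensity speckle: an
independent unit-mean exponential multiplier per voxel, the limiting
distribution after square-law detection. The optical path is accumulated
voxel by voxel (µ piecewise constant), which the windowed OLS fit inverts
*exactly* on homogeneous segments — the basis of the machine-precision
checks. `glioma_phantom_preset()` fixes the study-like scene: a 3 mm⁻¹
background (a realistic cortical attenuation at 1300 nm), a 1.5 mm⁻¹
ellipsoidal tumor (tumor attenuates at about half the normal-tissue
rate), and a 6 mm⁻¹ thin band standing in for the corpus callosum, with
speckle and a fixed seed.

Deliberately *not* modelled: confocal gating and sensitivity roll-off
(the instrumental depth decline of measured OAC — the normalization step
is exercised by the genuine attenuation decline instead), the lateral
point-spread function (phantom speckle is white, real speckle has
resolution-scale grain), multiple scattering, polarization, and motion.
Passing phantom tests therefore demonstrates the correctness of the
estimator chain and its geometric fidelity, not instrument-level realism;
on real data the ROI placement and the instrument's depth response remain
the dominant uncertainties.

Test problem sizes are chosen for desk-scale runs: 128³ homogeneous
volumes for exactness and recovery, a 160×128×128 cylinder scene and a
192×160×160 ellipsoid scene for boundary localization, and the reduced
(128×96×96) preset for the end-to-end CLI checks.

# Known limitations

* The ROI is an explicit input; nothing validates that it actually lies
  inside tumor, and a misplaced ROI silently rescales every map.
* NAD highlights every attenuation discontinuity, including non-tumor
  structure; it is a contrast-enhancement tool, not a classifier, and no
  sensitivity/specificity claims are made.
* Margins deeper than roughly the fit window below a lesion's bottom cap
  fade by construction (the window leaves the lesion), so the evaluable
  depth range for a structure of axial extent $c$ ends near
  $c - \text{window}$ below its equator.
* Depth below the surface is geometric, computed from the in-tissue
  axial pitch; if the pitch is actually air-path, supply
  `refractive_index` at load time or all depths scale accordingly.
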