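# octnad

Three-dimensional tumor-margin delineation from volumetric optical
coherence tomography (OCT) by normalized-absolute-difference (NAD)
mapping.

## The problem

Infiltrative brain tumors such as glioblastoma scatter light differently
from the surrounding parenchyma: tumor tissue attenuates the OCT beam
more slowly than normal tissue. The optical attenuation coefficient
(OAC, µ<sub>t</sub>, in mm⁻¹) can therefore separate tumor from normal
tissue — but only superficially, because the measured OAC declines with
depth (beam focus, sensitivity roll-off), so a fixed OAC threshold stops
working a few hundred micrometres below the surface. `octnad` implements
a processing chain that makes the *margin* — the lateral discontinuity in
attenuation — visible at every depth:

1. **Surface detection and flattening.** Each A-line's surface is the
   position of its greatest axial intensity variation (argmax of the first
   difference of the smoothed log profile); the volume is re-indexed so
   depth is measured below the surface.
2. **Depth-windowed OAC estimation.** The single-scatter model
   `I(z) ∝ exp(−2 µₜ z)` (the factor 2 is the round-trip path) is
   inverted by an ordinary-least-squares fit of `ln I` against depth over
   a 40-pixel (375 µm) sliding window, after averaging 21 neighbouring
   A-lines within each B-scan to suppress speckle. One fit per A-line per
   depth yields en-face OAC maps.
3. **ROI normalization (NOAC).** Each en-face map is min–max normalized
   against a fixed box placed inside the tumor:
   `NOAC = (OAC − min_ROI) / (max_ROI − min_ROI)`,
   so tumor contrast is pinned to [0, 1] at every depth regardless of the
   depth decline of the raw OAC.
4. **NAD mapping.** After Gaussian low-pass filtering, forward
   differences in x and y are combined pointwise into
   `NAD = √(ΔNOACₓ² + ΔNOAC_y²)` — a gradient-magnitude image that is
   large exactly at attenuation discontinuities, i.e. at the tumor
   boundary. Stacking NAD maps over depth gives a volumetric margin map.

Because no public volumetric OCT dataset accompanies this method, the
package ships a synthetic SS-OCT phantom generator (Beer–Lambert decay
through a voxelized attenuation field, surface topography, unit-mean
exponential speckle) with analytic ground truth, so every stage is
validated against known geometry.

## Conventions

* Arrays are indexed `(z, x, y)`: z along the A-line (index 1 =
  shallowest sample), x across A-lines of a B-scan, y across frames.
  All indices are 1-based.
* Voxel spacings are stored in micrometres, in tissue. If a file declares
  air-path axial spacing, pass `refractive_index` at load time.
* Linear-domain intensities are non-negative; `NA` marks missing samples.

## Worked example

A tumor-mimicking cylinder of radius 300 µm (attenuation 1.5 mm⁻¹
against a 3 mm⁻¹ background, fully developed speckle) is recovered to
sub-pixel accuracy at every depth:

```r
library(octnad)

sp <- phantom_spec(160, 128, 128, mu_background = 3,
                   surface = surface_flat(150),
                   inclusions = list(inclusion("cylinder",
                                               center_um = c(567, 567, 0),
                                               semi_axes_um = c(300, 300, 1),
                                               mu = 1.5)),
                   noise = noise_spec("speckle"), seed = 11)
vol <- render_volume(sp)

res <- run_nad_pipeline(vol, roi = enface_roi(56, 72, 56, 72),
                        config = pipeline_config(depths_um = c(200, 400, 600)),
                        verbose = TRUE)
#> depth   200.0 um: min_roi 1.008, max_roi 1.953 mm^-1, masked 0.0%, negative OAC 0
#> depth   400.0 um: min_roi 1.003, max_roi 1.914 mm^-1, masked 0.0%, negative OAC 0
#> depth   600.0 um: min_roi 1, max_roi 2.135 mm^-1, masked 0.0%, negative OAC 0

sapply(res$nad$maps, ridge_radius, center_px = c(64, 64))  # true radius: 300 um
#> [1] 297.00 299.25 301.50
```

The `min_roi`/`max_roi` lines are the per-depth normalization constants
(the OAC range inside the tumor ROI, mm⁻¹ — the speckle-driven spread
around the true 1.5 mm⁻¹); `ridge_radius` reports the radius of maximal
angular-mean NAD around the inclusion centre, i.e. the located margin,
within 3 µm (a third of a pixel) of the true 300 µm at all three depths.
`glioma_phantom_preset()` builds a richer scene (ellipsoidal tumor whose
cross-section shrinks with depth, plus a high-attenuation band mimicking
the corpus callosum) used throughout the test suite.

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/octnad.R simulate --preset small --seed 7 --out /tmp/ph
Rscript inst/cli/octnad.R nad --input /tmp/ph.bin --roi 40,48,48,56 --out /tmp/out
Rscript inst/cli/octnad.R overlay --input /tmp/ph.bin --roi 40,48,48,56 \
        --depth 400 --out /tmp/overlay.png
```

Every rendered image is paired with a full-precision CSV (and the NAD
stack with a JSON provenance sidecar), so numbers never have to be read
off pixels.

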