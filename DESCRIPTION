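Package: octnad
Title: Tumor-Margin Delineation from Volumetric OCT via Normalized
    Absolute Difference Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Depth-resolved optical attenuation coefficient (OAC) estimation
    from swept-source optical coherence tomography (SS-OCT) intensity volumes
    by windowed log-linear fitting, per-depth min-max normalization of en-face
    OAC maps against a tumor region of interest, and construction of
    normalized absolute difference (NAD) gradient-magnitude maps that
    highlight tumor margins in three dimensions.  Includes a synthetic
    SS-OCT phantom generator (Beer-Lambert decay, surface topography,
    multiplicative speckle) with analytic ground truth, surface detection
    and volume flattening, lossless map/volume I/O, and a command-line
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
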