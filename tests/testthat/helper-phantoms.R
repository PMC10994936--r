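# shared fixtures, built once per test run and cached by name
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

homogeneous_phantom <- function(mu, noise = "none", seed = 3L,
                                nz = 128L, nx = 64L, ny = 64L) {
  phantom_spec(nz, nx, ny, mu_background = mu, surface = surface_flat(150),
               noise = noise_spec(noise), seed = seed)
}

# speckled homogeneous volume reused by surface/oac tests
speckled_flat_volume <- function() {
  fixture("speckled_flat", function() {
    sp <- homogeneous_phantom(1, noise = "speckle", nx = 96L, ny = 96L)
    list(spec = sp, truth = build_mu_field(sp), volume = render_volume(sp))
  })
}

cylinder_phantom <- function(seed = 11L) {
  fixture(paste0("cylinder", seed), function() {
    sp <- phantom_spec(160, 128, 128, mu_background = 3,
                       surface = surface_flat(150),
                       inclusions = list(inclusion("cylinder",
                                                   center_um = c(63 * 9, 63 * 9, 0),
                                                   semi_axes_um = c(300, 300, 1),
                                                   mu = 1.5)),
                       noise = noise_spec("speckle"), seed = seed)
    truth <- build_mu_field(sp)
    vol <- render_volume(sp, truth)
    surf <- detect_surface(vol)
    list(spec = sp, truth = truth, volume = vol,
         surface = surf, flat = flatten(vol, surf),
         center_px = c(64, 64), roi = enface_roi(56, 72, 56, 72))
  })
}

# brute-force reference for the NOAC -> differences -> RMS chain,
# written as explicit per-pixel loops
brute_force_nad <- function(oac, roi) {
  sub <- oac[roi$x0:roi$x1, roi$y0:roi$y1]
  mn <- min(sub[is.finite(sub)])
  mx <- max(sub[is.finite(sub)])
  nx <- nrow(oac); ny <- ncol(oac)
  noac <- matrix(NA_real_, nx, ny)
  for (i in seq_len(nx)) for (j in seq_len(ny))
    noac[i, j] <- (oac[i, j] - mn) / (mx - mn)
  nad <- matrix(NA_real_, nx - 1, ny - 1)
  for (i in seq_len(nx - 1)) for (j in seq_len(ny - 1)) {
    dxv <- noac[i + 1, j] - noac[i, j]
    dyv <- noac[i, j + 1] - noac[i, j]
    nad[i, j] <- sqrt(dxv^2 + dyv^2)
  }
  nad
}
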