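test_that("lateral averaging is an NA-aware truncated moving mean", {
  b <- matrix(rnorm(20 * 9), 20, 9)
  expect_identical(lateral_average(b, 1), b)
  cb <- matrix(2, 20, 9)
  expect_equal(lateral_average(cb, 5), cb)
  expect_error(lateral_average(b, 11), "exceeds")
  # centred odd window with edge truncation
  av <- lateral_average(b, 3)
  expect_equal(av[, 5], rowMeans(b[, 4:6]))
  expect_equal(av[, 1], rowMeans(b[, 1:2]))
  # even width is left-biased by one
  av20 <- lateral_average(b, 4)
  expect_equal(av20[, 5], rowMeans(b[, 3:6]))
  # missing samples are excluded, not propagated
  b2 <- b; b2[3, 5] <- NA
  expect_equal(lateral_average(b2, 3)[3, 5], mean(b[3, c(4, 6)]))
})

test_that("averaging speckle reduces per-pixel spread about sqrt(width)-fold", {
  set.seed(8)
  b <- matrix(rexp(512 * 64), 512, 64)  # unit-mean speckle about signal 1
  av <- lateral_average(b, 21)
  inner <- 11:54  # columns with a full window
  ratio <- mean(apply(b[, inner], 2, sd)) / mean(apply(av[, inner], 2, sd))
  expect_lt(abs(ratio - sqrt(21)) / sqrt(21), 0.2)
})

test_that("the windowed fit inverts exact exponential decay", {
  z <- (0:39) * 9.375e-3
  mu <- fit_window_oac(log(exp(-2 * 1.5 * z)), dz_um = 9.375)
  expect_equal(mu, 1.5, tolerance = 1e-12)
  # independent oracle: lm() on the same samples
  y <- -2 * 0.8 * z + 3 + sin(1:40) * 0.05
  expect_equal(fit_window_oac(y, 9.375),
               -unname(coef(lm(y ~ z))[2]) / 2, tolerance = 1e-10)
  expect_equal(fit_window_oac(rep(1.3, 40), 9.375), 0)
  expect_true(is.na(fit_window_oac(c(1, 2, NA, NA), 9.375)))
  # 375 um window at 40 px implies the 9.375 um axial pitch
  expect_equal(40 * 9.375, 375)
})

test_that("depth profiles are flat for homogeneous media and step between layers", {
  sp <- homogeneous_phantom(1, nz = 128L, nx = 16L, ny = 16L)
  vol <- render_volume(sp)
  flat <- flatten(vol, detect_surface(vol, axial_presmooth_px = 1))
  prof <- oac_depth_profile(flat, enface_roi(4, 12, 4, 12))
  expect_true(all(diff(prof$depth_um) > 0))
  ok <- !is.na(prof$oac)
  expect_true(any(ok))
  expect_equal(prof$oac[ok], rep(1, sum(ok)), tolerance = 1e-9)

  # two layers: shallow mu 0.5 above 600 um, deep mu 2 below
  sp2 <- phantom_spec(192, 16, 16, surface = surface_flat(150), mu_background = 0.5,
                      inclusions = list(inclusion("slab", c(0, 67.5, 1300),
                                                  c(1, 80, 700), mu = 2)))
  vol2 <- render_volume(sp2)
  flat2 <- flatten(vol2, detect_surface(vol2, axial_presmooth_px = 1))
  prof2 <- oac_depth_profile(flat2, enface_roi(4, 12, 4, 12))
  shallow <- prof2$oac[prof2$depth_um + 375 <= 600]
  deep <- prof2$oac[prof2$depth_um >= 600 & prof2$depth_um + 375 <= 1200]
  mid <- prof2$oac[!is.na(prof2$oac)]
  expect_equal(shallow[!is.na(shallow)], rep(0.5, sum(!is.na(shallow))),
               tolerance = 1e-6)
  expect_equal(deep[!is.na(deep)], rep(2, sum(!is.na(deep))), tolerance = 1e-6)
  expect_true(all(mid > 0.5 - 1e-6 & mid < 2 + 1e-6))
})

test_that("en-face OAC maps are exact on noiseless phantoms and scale-invariant", {
  sp <- homogeneous_phantom(2, nz = 128L, nx = 48L, ny = 48L)
  vol <- render_volume(sp)
  flat <- flatten(vol, detect_surface(vol, axial_presmooth_px = 1))
  om <- enface_oac_map(flat, 405)
  expect_lt(max(abs(om$value - 2), na.rm = TRUE), 1e-9)
  expect_equal(om$realized_depth_um, round(405 / 9.375) * 9.375)
  # global positive rescaling leaves the slope of the log untouched
  v2 <- oct_volume(flat$intensity * 37, 9.375, 9, 9, flattened = TRUE)
  om2 <- enface_oac_map(v2, 405)
  expect_equal(om2$value, om$value, tolerance = 1e-12)
})

test_that("windows that overrun the axial extent mask progressively", {
  # tilt along y so lateral (x) averaging cannot fill the deep-edge holes
  sp <- phantom_spec(96, 32, 32, surface = surface_plane(40, gy = 1.22),
                     mu_background = 1)
  vol <- render_volume(sp)
  flat <- flatten(vol, detect_surface(vol, axial_presmooth_px = 1))
  fracs <- vapply(c(100, 400, 500, 525), function(d) {
    mean(is.na(suppressWarnings(enface_oac_map(flat, d))$value))
  }, numeric(1))
  expect_true(all(diff(fracs) >= 0))
  expect_gt(fracs[4], fracs[1])
  expect_warning(enface_oac_map(flat, 5000), "masked")
})

test_that("speckled homogeneous maps recover the true attenuation in the median", {
  for (mu in c(0.5, 2)) {
    sp <- homogeneous_phantom(mu, noise = "speckle", seed = 31L,
                              nz = 128L, nx = 96L, ny = 96L)
    vol <- render_volume(sp)
    flat <- flatten(vol, detect_surface(vol))
    om <- enface_oac_map(flat, 300)
    expect_lt(abs(median(om$value, na.rm = TRUE) - mu) / mu, 0.1)
    expect_true(om$n_negative >= 0)  # negative fits retained, only counted
  }
})

test_that("tumor regions show lower OAC than background in the preset", {
  sp <- glioma_phantom_preset()
  sp$noise <- noise_spec("none")
  gt <- build_mu_field(sp)
  vol <- render_volume(sp, gt)
  flat <- flatten(vol, detect_surface(vol, axial_presmooth_px = 1))
  om <- enface_oac_map(flat, 400)
  mu_row <- gt$mu_field[ceiling(400 / 9.375) + gt$surface_index[1, 1], , ]
  tumor_px <- mu_row == sp$inclusions[[1]]$mu
  normal_px <- mu_row == sp$mu_background  # excludes the high-OAC band
  inside <- om$value[tumor_px]; outside <- om$value[normal_px]
  inside <- inside[is.finite(inside)]; outside <- outside[is.finite(outside)]
  pooled <- sqrt((var(inside) + var(outside)) / 2)
  expect_gt((mean(outside) - mean(inside)) / max(pooled, 1e-12), 3)
  # region depth profile: tumor attenuates more slowly at shallow depth
  r <- sp$roi_suggestion
  ptum <- oac_depth_profile(flat, r)
  pbg <- oac_depth_profile(flat, enface_roi(5, 15, 5, 15))
  sel <- ptum$depth_um >= 300 & ptum$depth_um <= 450
  expect_true(all(ptum$oac[sel] < pbg$oac[sel], na.rm = TRUE))
})

test_that("negative fitted coefficients are reported, not clipped", {
  # rising profile -> negative attenuation
  a <- array(0, dim = c(64, 8, 8))
  z <- (seq_len(64) - 1) * 9.375e-3
  a[, , ] <- rep(exp(2 * 0.7 * z) + 1, 64)
  a[1, , ] <- 0
  vol <- oct_volume(a, 9.375, 9, 9, flattened = TRUE)
  om <- enface_oac_map(vol, 0, pipeline_config(lateral_avg_width = 1))
  expect_true(all(om$value < 0, na.rm = TRUE))
  expect_equal(om$n_negative, sum(!is.na(om$value)))
})

test_that("the pointwise estimator matches the fit on ideal decay", {
  z <- (0:63) * 9.375e-3
  prof <- 1e4 * exp(-2 * 1.2 * z)
  mu <- oac_pointwise(prof, 9.375)
  expect_true(is.na(mu[1]))
  expect_equal(mu[-1], rep(1.2, 63), tolerance = 1e-10)
})
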