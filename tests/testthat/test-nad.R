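make_oac_map <- function(value, depth_um = 450) {
  structure(list(value = value, depth_um = depth_um,
                 realized_depth_um = depth_um, window_px = 40L,
                 n_negative = sum(value < 0, na.rm = TRUE),
                 dx_um = 9, dy_um = 9),
            class = "oac_map")
}

test_that("normalization maps the ROI range onto [0, 1] exactly", {
  v <- matrix(3, 6, 6)
  v[2, 2] <- 2; v[3, 3] <- 4  # ROI extremes 2 and 4 mm^-1
  nm <- normalize_map(make_oac_map(v), enface_roi(2, 4, 2, 4))
  expect_equal(nm$value[1, 1], 0.5)   # pixel at 3 -> (3-2)/(4-2)
  expect_equal(nm$value[2, 2], 0)     # equals min_roi
  expect_equal(nm$value[3, 3], 1)     # equals max_roi
  expect_equal(nm$min_roi, 2)
  expect_equal(nm$max_roi, 4)
  # values outside the ROI may leave [0, 1] and are not clipped
  v2 <- v; v2[6, 6] <- 9
  nm2 <- normalize_map(make_oac_map(v2), enface_roi(2, 4, 2, 4))
  expect_equal(nm2$value[6, 6], 3.5)
})

test_that("degenerate or fully masked ROIs are rejected", {
  expect_error(normalize_map(make_oac_map(matrix(1, 5, 5)), enface_roi(1, 3, 1, 3)),
               "degenerate")
  vm <- matrix(NA_real_, 5, 5); vm[5, 5] <- 1
  expect_error(normalize_map(make_oac_map(vm), enface_roi(1, 3, 1, 3)),
               "unmasked")
  expect_error(normalize_map(make_oac_map(matrix(1, 3, 3)), enface_roi(1, 5, 1, 5)),
               "exceeds")
})

test_that("normalization is invariant under affine rescaling of the OAC", {
  set.seed(21)
  roi <- enface_roi(3, 6, 2, 7)
  for (rep in 1:5) {
    v <- matrix(rnorm(80, 3), 8, 10)
    n1 <- normalize_map(make_oac_map(v), roi)
    n2 <- normalize_map(make_oac_map(1.7 * v + 0.9), roi)
    expect_equal(n2$value, n1$value, tolerance = 1e-12)
  }
})

test_that("the low-pass filter is a mask-aware normalized Gaussian", {
  m <- matrix(rnorm(15 * 11), 15, 11)
  expect_identical(lowpass_filter(m, 0), m)
  expect_equal(lowpass_filter(matrix(4, 9, 9), 3), matrix(4, 9, 9),
               tolerance = 1e-12)
  # unit impulse away from edges reproduces the discrete normalized kernel
  imp <- matrix(0, 41, 41); imp[21, 21] <- 1
  sm <- lowpass_filter(imp, 2)
  expect_lt(abs(sum(sm) - 1), 1e-6)
  r <- -20:20
  k1 <- exp(-r^2 / (2 * 4)); k1[abs(r) > 8] <- 0
  k1 <- k1 / sum(k1)
  oracle <- outer(k1, k1)
  expect_equal(sm, oracle, tolerance = 1e-9)
  # masked pixels stay masked and neighbours renormalize over valid support
  mh <- matrix(1, 7, 7); mh[4, 4] <- NA
  smh <- lowpass_filter(mh, 1.5)
  expect_true(is.na(smh[4, 4]))
  expect_equal(smh[is.finite(smh)], rep(1, 48), tolerance = 1e-12)
})

test_that("directional differences follow the staggered-grid contract", {
  expect_error(directional_differences(matrix(1, 1, 5)), "at least 2")
  cm <- matrix(7, 6, 5)
  d <- directional_differences(cm)
  expect_equal(dim(d$dx), c(5, 4))
  expect_true(all(d$dx == 0) && all(d$dy == 0))
  # linear ramp in x: dx constant s, dy zero
  ramp <- matrix(rep(0.3 * (1:6), 5), 6, 5)
  dr <- directional_differences(ramp)
  expect_true(all(abs(dr$dx - 0.3) < 1e-12) && all(dr$dy == 0))
  # a step of height h along one column appears only in dx at that column
  st <- matrix(0, 6, 5); st[4:6, ] <- 2.5
  ds <- directional_differences(st)
  expect_true(all(ds$dx[3, ] == 2.5))
  expect_true(all(ds$dx[-3, ] == 0) && all(ds$dy == 0))
  # differences touching a masked pixel are masked
  hm <- matrix(1, 6, 5); hm[3, 3] <- NA
  dh <- directional_differences(hm)
  expect_true(is.na(dh$dx[2, 3]) && is.na(dh$dx[3, 3]))
  expect_true(is.na(dh$dy[3, 2]) && is.na(dh$dy[3, 3]))
})

test_that("the NAD map is the pointwise RMS of the two difference fields", {
  dx <- matrix(3, 4, 4); dy <- matrix(4, 4, 4)
  nm <- nad_map(dx, dy)
  expect_true(all(nm$value == 5))
  expect_true(all(nad_map(matrix(0, 2, 2), matrix(0, 2, 2))$value == 0))
  h <- matrix(c(0.7, 0, 0, 0), 2, 2)
  expect_equal(nad_map(h, matrix(0, 2, 2))$value, abs(h))
  expect_error(nad_map(matrix(0, 2, 2), matrix(0, 3, 2)), "identical shape")
  # non-negative, zero iff both inputs zero
  set.seed(4)
  a <- matrix(rnorm(36), 6, 6); b <- matrix(rnorm(36), 6, 6)
  b[a == 0] <- 0
  v <- nad_map(a, b)$value
  expect_true(all(v >= 0))
  expect_identical(unname(which(v == 0)), unname(which(a == 0 & b == 0)))
})

test_that("the pipeline reproduces a brute-force per-pixel computation exactly", {
  set.seed(17)
  roi <- enface_roi(3, 6, 3, 6)
  for (rep in 1:10) {
    oac <- matrix(rnorm(64, mean = 3, sd = 1), 8, 8)
    nm <- normalize_map(make_oac_map(oac), roi)
    df <- directional_differences(nm)
    got <- nad_map(df$dx, df$dy)$value
    expect_identical(got, brute_force_nad(oac, roi))
  }
})

test_that("homogeneous speckled volumes give near-zero NAD at every depth", {
  fx <- speckled_flat_volume()
  flat <- flatten(fx$volume, detect_surface(fx$volume))
  nv <- nad_volume(flat, enface_roi(40, 56, 40, 56),
                   depths_um = c(200, 400, 600))
  for (m in nv$maps) {
    expect_lt(median(m$value, na.rm = TRUE), 0.05)
    expect_lt(max(m$value, na.rm = TRUE), 0.3)
  }
})

test_that("NAD stacks localize a cylindrical boundary within 2 pixels", {
  cyl <- cylinder_phantom()
  deps <- seq(150, 750, by = 150)
  nv <- nad_volume(cyl$flat, cyl$roi, depths_um = deps)
  expect_equal(nv$depths_um, deps)
  expect_true(all(is.finite(nv$provenance$per_depth$min_roi)))
  for (m in nv$maps) {
    r <- ridge_radius(m, cyl$center_px)
    expect_lt(abs(r - 300) / 9, 2)
  }
})

test_that("ridge extraction recovers a circular boundary within 2 pixels", {
  cyl <- cylinder_phantom()
  nv <- nad_volume(cyl$flat, cyl$roi, depths_um = 300)
  tr <- octnad:::ridge_trace(nv$maps[[1]], cyl$center_px)
  err_px <- abs(tr$r_px - 300 / 9)
  expect_lt(mean(err_px, na.rm = TRUE), 2)
  mask <- extract_boundary(nv$maps[[1]], "ridge", center = cyl$center_px)
  expect_gt(sum(mask), 50)  # a ring of marked pixels
})

test_that("threshold boundaries handle empty and ideal ring inputs", {
  zm <- structure(list(value = matrix(0, 8, 8), depth_um = 0, dx_um = 9,
                       dy_um = 9, offset_px = 0.5), class = "nad_map")
  expect_warning(m0 <- extract_boundary(zm, "threshold", 0.9), "empty|no positive")
  expect_false(any(m0))
  ring <- matrix(0, 21, 21)
  ij <- expand.grid(i = 1:21, j = 1:21)
  rr <- sqrt((ij$i - 11)^2 + (ij$j - 11)^2)
  ring[cbind(ij$i, ij$j)[abs(rr - 6) < 0.6, ]] <- 1
  rm <- structure(list(value = ring, depth_um = 0, dx_um = 9, dy_um = 9,
                       offset_px = 0.5), class = "nad_map")
  got <- extract_boundary(rm, "threshold", level = 1 - mean(ring > 0))
  expect_identical(got, ring > 0)
})

test_that("fully masked depths degrade to masked slices with a warning", {
  fx <- speckled_flat_volume()
  flat <- flatten(fx$volume, detect_surface(fx$volume))
  w <- capture_warnings(nv <- nad_volume(flat, enface_roi(40, 56, 40, 56),
                                         depths_um = c(300, 2000)))
  expect_true(any(grepl("NAD slice masked", w)))
  expect_true(all(is.na(nv$maps[[2]]$value)))
  expect_false(all(is.na(nv$maps[[1]]$value)))
})

test_that("NAD volumes stack, export and record provenance", {
  cyl <- cylinder_phantom()
  nv <- nad_volume(cyl$flat, cyl$roi, depths_um = c(200, 400))
  arr <- as.array(nv)
  expect_equal(dim(arr), c(127, 127, 2))
  base <- file.path(tempdir(), "nadstack")
  write_nad_volume(nv, base)
  meta <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  expect_equal(meta$depths_um, c(200, 400))
  expect_equal(nrow(meta$per_depth), 2)
  expect_equal(meta$config$lateral_avg_width, 21)
  pages <- tiff::readTIFF(paste0(base, ".tiff"), all = TRUE)
  expect_length(pages, 2)
})
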