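#' Normalize an en-face OAC map against the tumor ROI
#'
#' Min-max normalization `(OAC - min_ROI) / (max_ROI - min_ROI)` using the
#' extreme OAC values inside a fixed region of interest placed in the tumor,
#' applied to every unmasked pixel of the map.  Within the ROI the result
#' spans exactly \[0, 1\] at every depth, which is what makes tumor contrast
#' depth-independent; outside the ROI values may leave \[0, 1\] and are
#' deliberately not clipped (clipping would erase gradients at bright
#' normal structures such as the corpus callosum).
#'
#' @param oac_map an [enface_oac_map()] result.
#' @param roi an [enface_roi()] with at least 4 unmasked pixels.
#' @return An object of class `noac_map` carrying the dimensionless map and
#'   the recorded normalization constants `min_roi`, `max_roi` (mm^-1).
#' @export
normalize_map <- function(oac_map, roi) {
  stopifnot(inherits(oac_map, "oac_map"))
  v <- oac_map$value
  check_roi_bounds(roi, nrow(v), ncol(v))
  sub <- v[roi$x0:roi$x1, roi$y0:roi$y1]
  sub <- sub[is.finite(sub)]
  if (length(sub) < 4L)
    stop("ROI has fewer than 4 unmasked pixels at depth ",
         oac_map$depth_um, " um")
  mn <- min(sub); mx <- max(sub)
  if (mx == mn)
    stop("degenerate normalization: ROI min and max OAC are equal (",
         fmt_num(mn), " mm^-1)")
  structure(list(value = (v - mn) / (mx - mn),
                 depth_um = oac_map$depth_um,
                 realized_depth_um = oac_map$realized_depth_um,
                 window_px = oac_map$window_px,
                 n_negative = oac_map$n_negative,
                 dx_um = oac_map$dx_um, dy_um = oac_map$dy_um,
                 roi = roi, min_roi = mn, max_roi = mx,
                 lowpass_sigma_px = 0),
            class = "noac_map")
}

#' Low-pass filter an NOAC map
#'
#' Separable Gaussian smoothing in x and y, applied before differencing to
#' suppress residual speckle variation.  Masked pixels are excluded by
#' normalized convolution: the kernel weights are renormalized over the
#' unmasked support, so holes neither bleed `NA` nor darken their
#' neighbourhood; masked pixels stay masked.  `sigma_px = 0` is the
#' identity.
#'
#' @param noac_map a [normalize_map()] result (or a plain matrix).
#' @param sigma_px Gaussian sigma in pixels (kernel truncated at 4 sigma).
#' @return Same class as the input.
#' @export
lowpass_filter <- function(noac_map, sigma_px) {
  if (sigma_px < 0) stop_validation("`sigma_px` must be >= 0")
  m <- map_matrix(noac_map)
  sm <- gaussian_blur_masked(m, sigma_px)
  if (is.matrix(noac_map)) return(sm)
  noac_map$value <- sm
  noac_map$lowpass_sigma_px <- sigma_px
  noac_map
}

gaussian_blur_masked <- function(m, sigma) {
  if (sigma == 0) return(m)
  w <- is.finite(m)
  m0 <- m
  m0[!w] <- 0
  kx <- gaussian_band(nrow(m), sigma)
  ky <- gaussian_band(ncol(m), sigma)
  num <- kx %*% m0 %*% ky
  den <- kx %*% (w + 0) %*% ky
  out <- num / den
  out[!w | den == 0] <- NA_real_
  out
}

#' Forward differences of an NOAC map in x and y
#'
#' `dx(i, j) = NOAC(i+1, j) - NOAC(i, j)` and the analogue in y, both
#' restricted to the common `(nx-1) x (ny-1)` grid so that the two fields
#' can be combined pointwise.  The differences live on half-pixel staggered
#' grids; pairing `dx(i, j)` with `dy(i, j)` co-locates them on the corner
#' grid whose cell `(i, j)` sits at original coordinate `(i + 0.5, j + 0.5)`.
#' A difference touching a masked pixel is masked.
#'
#' @param noac_map a (filtered) [normalize_map()] result or a matrix.
#' @return List with matrices `dx` and `dy`, both `(nx-1) x (ny-1)`.
#' @export
directional_differences <- function(noac_map) {
  m <- map_matrix(noac_map)
  nx <- nrow(m); ny <- ncol(m)
  if (nx < 2L || ny < 2L)
    stop_validation("need at least 2 pixels in each lateral direction")
  dx <- m[2:nx, , drop = FALSE] - m[1:(nx - 1), , drop = FALSE]
  dy <- m[, 2:ny, drop = FALSE] - m[, 1:(ny - 1), drop = FALSE]
  list(dx = dx[, 1:(ny - 1), drop = FALSE],
       dy = dy[1:(nx - 1), , drop = FALSE])
}

#' Normalized absolute difference (NAD) map
#'
#' Pointwise root-mean-square combination `sqrt(dx^2 + dy^2)` of the two
#' directional NOAC differences: a gradient-magnitude image that is
#' non-negative, zero only where both differences vanish, and large at
#' attenuation discontinuities, i.e. at tumor boundaries.
#'
#' @param dx,dy matching difference fields from
#'   [directional_differences()].
#' @param depth_um,dx_um,dy_um optional provenance carried onto the map.
#' @return An object of class `nad_map`; its `value` lives on the corner
#'   grid (`offset_px = 0.5` relative to the original map pixels).
#' @export
nad_map <- function(dx, dy, depth_um = NA_real_, dx_um = NA_real_, dy_um = NA_real_) {
  if (!is.matrix(dx) || !is.matrix(dy) || !all(dim(dx) == dim(dy)))
    stop_validation("`dx` and `dy` must be matrices of identical shape")
  v <- sqrt(dx^2 + dy^2)
  structure(list(value = v, depth_um = depth_um,
                 dx_um = dx_um, dy_um = dy_um, offset_px = 0.5),
            class = "nad_map")
}

#' @export
print.nad_map <- function(x, ...) {
  cat(sprintf("<nad_map> %d x %d at depth %g um, masked %.1f%%, max %.3g\n",
              nrow(x$value), ncol(x$value), x$depth_um,
              100 * mean(is.na(x$value)),
              suppressWarnings(max(x$value, na.rm = TRUE))))
  invisible(x)
}

default_depth_list <- function(volume, averaged_log, config) {
  d <- vol_dims(volume)
  w <- config$fit_window_px
  usable <- matrix(is.finite(averaged_log), d$nz, d$nx * d$ny)
  navail <- apply(usable, 2, function(col) {
    r <- which(col)
    if (length(r)) max(r) else 0L
  })
  starts <- seq_len(max(d$nz - w + 1L, 0L))
  frac <- vapply(starts, function(k) mean(navail >= k + w - 1L), numeric(1))
  kmax <- if (any(frac >= 0.5)) max(starts[frac >= 0.5]) else 0L
  if (kmax < 1L)
    stop_validation("no depth has at least half of the A-lines unmasked")
  (seq_len(kmax) - 1) * volume$dz_um
}

#' Volumetric NAD stack
#'
#' Runs the full per-depth chain — en-face OAC map, ROI normalization,
#' low-pass filtering, directional differences, RMS combination — over a
#' list of depths and stacks the resulting NAD maps.  Lateral averaging is
#' performed once and shared by all depths.  The stack records, per depth,
#' the normalization constants, masked fraction and negative-OAC count.
#'
#' @param volume a flattened linear-domain [oct_volume()].
#' @param roi [enface_roi()] used for normalization at every depth (one
#'   fixed box, as a single tumor ROI is reused across the stack).
#' @param depths_um increasing depths below the surface, um; `NULL` selects
#'   every window-start sample from the surface down to the deepest depth
#'   at which at least half the pixels are unmasked.
#' @param config a [pipeline_config()].
#' @param verbose emit one message per depth with the QC numbers.
#' @return An object of class `nad_volume`: `maps` (list of [nad_map()]),
#'   `depths_um`, and a `provenance` data frame (per-depth `min_roi`,
#'   `max_roi`, `masked_frac`, `n_negative`) plus the configuration used.
#' @export
nad_volume <- function(volume, roi, depths_um = NULL,
                       config = pipeline_config(), verbose = FALSE) {
  check_flattened(volume)
  d <- vol_dims(volume)
  check_roi_bounds(roi, d$nx, d$ny)
  averaged <- averaged_log_volume(volume, config)
  if (is.null(depths_um)) depths_um <- config$depths_um
  if (is.null(depths_um)) depths_um <- default_depth_list(volume, averaged, config)
  if (!length(depths_um)) stop_validation("empty depth list")
  if (is.unsorted(depths_um, strictly = TRUE))
    stop_validation("`depths_um` must be strictly increasing")
  maps <- vector("list", length(depths_um))
  prov <- data.frame(depth_um = depths_um, min_roi = NA_real_,
                     max_roi = NA_real_, masked_frac = NA_real_,
                     n_negative = NA_integer_)
  for (i in seq_along(depths_um)) {
    dep <- depths_um[i]
    om <- enface_oac_map(volume, dep, config, averaged = averaged)
    prov$masked_frac[i] <- mean(is.na(om$value))
    prov$n_negative[i] <- om$n_negative
    if (all(is.na(om$value))) {
      warning(sprintf("depth %g um: OAC map fully masked; NAD slice masked", dep))
      maps[[i]] <- nad_map(matrix(NA_real_, d$nx - 1, d$ny - 1),
                           matrix(NA_real_, d$nx - 1, d$ny - 1),
                           depth_um = dep, dx_um = volume$dx_um,
                           dy_um = volume$dy_um)
      next
    }
    nm <- normalize_map(om, roi)
    prov$min_roi[i] <- nm$min_roi
    prov$max_roi[i] <- nm$max_roi
    nm <- lowpass_filter(nm, config$lowpass_sigma_px)
    df <- directional_differences(nm)
    maps[[i]] <- nad_map(df$dx, df$dy, depth_um = dep,
                         dx_um = volume$dx_um, dy_um = volume$dy_um)
    if (verbose)
      message(sprintf(
        "depth %7.1f um: min_roi %.4g, max_roi %.4g mm^-1, masked %.1f%%, negative OAC %d",
        dep, nm$min_roi, nm$max_roi, 100 * prov$masked_frac[i], om$n_negative))
  }
  structure(list(maps = maps, depths_um = depths_um,
                 provenance = list(per_depth = prov, config = unclass(config))),
            class = "nad_volume")
}

#' @export
print.nad_volume <- function(x, ...) {
  cat(sprintf("<nad_volume> %d depths, %g to %g um below surface\n",
              length(x$depths_um), min(x$depths_um), max(x$depths_um)))
  invisible(x)
}

#' Stack a NAD volume into a 3-D array
#'
#' @param x a [nad_volume()].
#' @param ... unused.
#' @return Array `(nx-1, ny-1, n_depths)`.
#' @export
as.array.nad_volume <- function(x, ...) {
  d <- dim(x$maps[[1]]$value)
  arr <- array(NA_real_, dim = c(d[1], d[2], length(x$maps)))
  for (i in seq_along(x$maps)) arr[, , i] <- x$maps[[i]]$value
  arr
}

#' Write a NAD volume to disk
#'
#' Multi-page 16-bit TIFF (one page per depth, scale recorded in the JSON
#' provenance sidecar) plus the per-depth provenance table.
#'
#' @param nadvol a [nad_volume()].
#' @param base output base path (`<base>.tiff`, `<base>.json`).
#' @return Invisibly, the written paths.
#' @export
write_nad_volume <- function(nadvol, base) {
  stopifnot(inherits(nadvol, "nad_volume"))
  arr <- as.array(nadvol)
  scale <- suppressWarnings(max(arr, na.rm = TRUE))
  if (!is.finite(scale) || scale <= 0) scale <- 1
  pages <- lapply(seq_len(dim(arr)[3]), function(i) {
    p <- t(arr[, , i]) / scale
    p[!is.finite(p)] <- 0
    pmin(pmax(p, 0), 1)
  })
  tf <- paste0(base, ".tiff")
  tiff::writeTIFF(pages, tf, bits.per.sample = 16L, compression = "none",
                  reduce = FALSE)
  jf <- paste0(base, ".json")
  jsonlite::write_json(
    list(depths_um = nadvol$depths_um, intensity_scale = scale,
         page_layout = "rows = y, cols = x, page = depth",
         per_depth = nadvol$provenance$per_depth,
         config = nadvol$provenance$config),
    jf, auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(tiff = tf, json = jf))
}

#' Extract a boundary mask from a NAD map
#'
#' Convenience segmentation of the NAD ridge; the NAD map itself is the
#' validated product, this mask is a display aid.
#'
#' * `threshold`: pixels at or above the `level` quantile of the unmasked
#'   values.
#' * `ridge`: for rays cast from `center` every degree, mark the pixel at
#'   the radius of maximal interpolated NAD along that ray.
#'
#' @param nadmap a [nad_map()].
#' @param method `"threshold"` or `"ridge"`.
#' @param level quantile in \[0, 1\] for the threshold method.
#' @param center `(x, y)` seed in original map pixel coordinates for the
#'   ridge method.
#' @return Logical matrix on the NAD grid.
#' @export
extract_boundary <- function(nadmap, method = c("threshold", "ridge"),
                             level = 0.9, center = NULL) {
  stopifnot(inherits(nadmap, "nad_map"))
  method <- match.arg(method)
  v <- nadmap$value
  if (method == "threshold") {
    vals <- v[is.finite(v)]
    if (!length(vals) || all(vals == 0)) {
      warning("NAD map has no positive values; empty boundary mask")
      return(matrix(FALSE, nrow(v), ncol(v)))
    }
    q <- quantile(vals, level, names = FALSE)
    if (q <= 0) q <- .Machine$double.eps
    mask <- is.finite(v) & v >= q
  } else {
    if (is.null(center)) stop_validation("ridge method needs a `center`")
    prof <- ridge_trace(nadmap, center)
    mask <- matrix(FALSE, nrow(v), ncol(v))
    ok <- is.finite(prof$ix) & is.finite(prof$iy)
    mask[cbind(prof$ix[ok], prof$iy[ok])] <- TRUE
  }
  if (!any(mask)) warning("boundary mask is empty")
  mask
}
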