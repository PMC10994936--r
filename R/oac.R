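#' Lateral A-line averaging within a B-scan
#'
#' Replaces each A-line of a B-scan with the mean of a centred moving
#' window of neighbouring A-lines, truncated at the edges (the mean runs
#' over the available neighbours) and excluding missing samples.  This is
#' the speckle-suppression step that precedes the log-linear fit; it acts
#' along x only, within one B-scan, never across frames.
#'
#' @param bscan numeric matrix `(z, x)`, linear-domain intensity (`NA` =
#'   missing).
#' @param width window width in A-lines; odd widths are centred, an even
#'   width is left-biased by half a pixel (provided for a literal 20-line
#'   window).
#' @return Matrix of the same shape.
#' @export
lateral_average <- function(bscan, width) {
  if (!is.matrix(bscan)) stop_validation("`bscan` must be a (z, x) matrix")
  width <- as.integer(width)
  if (width < 1L) stop_validation("`width` must be >= 1")
  if (width > ncol(bscan))
    stop_validation("`width` exceeds the number of A-lines")
  if (width == 1L) return(bscan)
  t(moving_mean_cols(t(bscan), width))
}

# NA-aware moving mean of width w along the rows of a matrix; odd w is
# centred, even w takes one more neighbour on the left
moving_mean_cols <- function(m, w) {
  n <- nrow(m)
  hl <- w %/% 2L
  hr <- (w - 1L) %/% 2L
  v <- is.finite(m)
  m0 <- m
  m0[!v] <- 0
  cs <- rbind(0, apply(m0, 2, cumsum))
  cn <- rbind(0, apply(v + 0, 2, cumsum))
  lo <- pmax(seq_len(n) - hl, 1L)
  hi <- pmin(seq_len(n) + hr, n)
  s <- cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]
  k <- cn[hi + 1L, , drop = FALSE] - cn[lo, , drop = FALSE]
  out <- s / k
  out[k == 0] <- NA_real_
  out
}

#' Windowed OAC from one log-intensity profile
#'
#' Ordinary-least-squares slope `b` of natural-log intensity against depth
#' (in mm) over the window; the attenuation coefficient is `-b / 2`, the
#' factor 2 accounting for the round-trip path of the light.  Values may be
#' negative under noise and are deliberately not clipped.  Fewer than 3
#' usable samples yield `NA`.
#'
#' @param log_profile natural-log intensity samples over one window
#'   (`NA`/non-finite = missing; take `log()` of linear data first and treat
#'   non-positive intensities as missing).
#' @param dz_um axial sample spacing, um (in tissue).
#' @return Attenuation coefficient in mm^-1, or `NA`.
#' @examples
#' z <- (0:39) * 9.375e-3                 # depth, mm
#' fit_window_oac(log(exp(-2 * 1.5 * z)), dz_um = 9.375)  # 1.5 mm^-1
#' @export
fit_window_oac <- function(log_profile, dz_um) {
  y <- as.numeric(log_profile)
  z <- (seq_along(y) - 1) * dz_um / 1000
  ok <- is.finite(y)
  if (sum(ok) < 3L) return(NA_real_)
  z <- z[ok]; y <- y[ok]
  zc <- z - mean(z)
  den <- sum(zc^2)
  if (den == 0) return(NA_real_)
  -sum(zc * y) / den / 2
}

# Vectorized windowed OLS over a block of log profiles.
# L: (w x P) natural-log intensity with NA for missing; z_mm: length-w depths.
# Returns list(mu = length-P attenuation (NA-masked), n = valid counts).
fit_block <- function(L, z_mm) {
  V <- is.finite(L)
  L0 <- L
  L0[!V] <- 0
  n <- colSums(V)
  Sz <- colSums(z_mm * V)
  Szz <- colSums(z_mm^2 * V)
  Sy <- colSums(L0)
  Szy <- colSums(z_mm * L0)
  den <- Szz - Sz^2 / n
  num <- Szy - Sz * Sy / n
  mu <- -num / den / 2
  mu[n < 3L | !is.finite(mu)] <- NA_real_
  list(mu = mu, n = n)
}

#' Laterally averaged log-intensity volume
#'
#' Applies [lateral_average()] slice by slice and returns the natural-log
#' intensity array consumed by the windowed fit.  With
#' `config$average_domain = "log"` (the default) the log-compressed B-scan
#' is averaged (a geometric mean): the OAC is the slope of log intensity,
#' so averaging the fitted quantity keeps lateral boundary transitions
#' symmetric.  With `"linear"`, raw intensities are averaged first and the
#' log taken afterwards; the log of a two-region mixture is then dominated
#' by the slower decay, which smears margins outward with depth.
#' Non-positive intensities are missing (`NA`) in either domain.
#'
#' Computing this once and passing it to [enface_oac_map()] via its
#' `averaged` argument avoids re-averaging when many depths are mapped
#' (as [nad_volume()] does internally).
#'
#' @param volume a flattened linear-domain [oct_volume()].
#' @param config a [pipeline_config()].
#' @return Array `(nz, nx, ny)` of averaged natural-log intensity.
#' @export
averaged_log_volume <- function(volume, config = pipeline_config()) {
  d <- vol_dims(volume)
  width <- config$lateral_avg_width
  v <- volume$intensity
  if (identical(config$average_domain, "log")) {
    v[!is.finite(v) | v <= 0] <- NA_real_
    v <- log(v)
    if (width <= 1L) return(v)
    out <- array(NA_real_, dim = c(d$nz, d$nx, d$ny))
    for (iy in seq_len(d$ny))
      out[, , iy] <- lateral_average(v[, , iy], width)
    out
  } else {
    if (width > 1L) {
      out <- array(NA_real_, dim = c(d$nz, d$nx, d$ny))
      for (iy in seq_len(d$ny))
        out[, , iy] <- lateral_average(v[, , iy], width)
      v <- out
    }
    v[!is.finite(v) | v <= 0] <- NA_real_
    log(v)
  }
}

check_flattened <- function(volume) {
  if (!inherits(volume, "oct_volume") || !volume$flattened)
    stop_validation("expected a flattened volume (see flatten())")
  if (volume$log_domain)
    stop_validation("expected linear-domain intensities")
  invisible(volume)
}

#' En-face OAC map at one depth
#'
#' Averages neighbouring A-lines within each B-scan (in the domain set by
#' `config$average_domain`, log-compressed by default), converts the
#' requested depth below the surface to the nearest window-start sample,
#' and fits the log-linear decay over `fit_window_px` samples on every
#' A-line.  The window *starts* at the nominal depth; the realized
#' (rounded) start depth is recorded on the map.  Non-positive intensities
#' are treated as missing in the fit; pixels with fewer than 3 usable
#' samples are masked.
#'
#' @param volume a flattened linear-domain [oct_volume()].
#' @param depth_um window start depth below the surface, um.
#' @param config a [pipeline_config()].
#' @param averaged internal: pre-averaged log-intensity array (from the
#'   per-volume averaging pass) to avoid re-averaging per depth.
#' @return An object of class `oac_map`: `value` (`nx x ny` matrix, mm^-1,
#'   `NA` = masked), `depth_um`, `realized_depth_um`, `window_px`,
#'   `n_negative` (count of negative fitted coefficients, retained for QC,
#'   never clipped), and the lateral spacings.
#' @export
enface_oac_map <- function(volume, depth_um, config = pipeline_config(),
                           averaged = NULL) {
  check_flattened(volume)
  d <- vol_dims(volume)
  w <- config$fit_window_px
  if (is.null(averaged)) averaged <- averaged_log_volume(volume, config)
  start <- as.integer(round(depth_um / volume$dz_um)) + 1L
  new_map <- function(vals) {
    nneg <- sum(vals < 0, na.rm = TRUE)
    structure(list(value = matrix(vals, d$nx, d$ny),
                   depth_um = depth_um,
                   realized_depth_um = (start - 1) * volume$dz_um,
                   window_px = w, n_negative = nneg,
                   dx_um = volume$dx_um, dy_um = volume$dy_um),
              class = "oac_map")
  }
  if (start < 1L || start + w - 1L > d$nz) {
    warning(sprintf("depth %g um leaves no room for a %d-px window; map fully masked",
                    depth_um, w))
    return(new_map(rep(NA_real_, d$nx * d$ny)))
  }
  block <- matrix(averaged[start:(start + w - 1L), , ], w, d$nx * d$ny)
  z_mm <- (start - 1L + seq_len(w) - 1L) * volume$dz_um / 1000
  fit <- fit_block(block, z_mm)
  new_map(fit$mu)
}

#' @export
print.oac_map <- function(x, ...) {
  cat(sprintf(
    "<oac_map> %d x %d at depth %g um (window start %g um, %d px)\n",
    nrow(x$value), ncol(x$value), x$depth_um, x$realized_depth_um, x$window_px))
  cat(sprintf("  masked %.1f%%, negative fits %d\n",
              100 * mean(is.na(x$value)), x$n_negative))
  invisible(x)
}

#' OAC depth profile of a lateral region
#'
#' Averages the region's A-lines into one profile (in the configured
#' averaging domain), then slides the fit window one sample at a time from
#' the surface, emitting one OAC per window-start depth.
#'
#' @param volume a flattened linear-domain [oct_volume()].
#' @param lateral_region an [enface_roi()] selecting the A-lines.
#' @param config a [pipeline_config()].
#' @return An object of class `oac_profile`: a data frame with `depth_um`
#'   (strictly increasing window-start depths) and `oac` (mm^-1).
#' @export
oac_depth_profile <- function(volume, lateral_region, config = pipeline_config()) {
  check_flattened(volume)
  d <- vol_dims(volume)
  check_roi_bounds(lateral_region, d$nx, d$ny)
  r <- lateral_region
  sub <- volume$intensity[, r$x0:r$x1, r$y0:r$y1, drop = FALSE]
  if (identical(config$average_domain, "log")) {
    sub[!is.finite(sub) | sub <= 0] <- NA_real_
    lp <- rowMeans(matrix(log(sub), d$nz), na.rm = TRUE)
  } else {
    prof <- rowMeans(matrix(sub, d$nz), na.rm = TRUE)
    prof[!is.finite(prof) | prof <= 0] <- NA_real_
    lp <- log(prof)
  }
  lp[!is.finite(lp)] <- NA_real_
  w <- config$fit_window_px
  starts <- seq_len(max(d$nz - w + 1L, 0L))
  if (!length(starts)) stop_validation("fit window longer than the axial extent")
  oac <- vapply(starts, function(k) {
    fit_window_oac(lp[k:(k + w - 1L)], volume$dz_um)
  }, numeric(1))
  structure(data.frame(depth_um = (starts - 1) * volume$dz_um, oac = oac),
            class = c("oac_profile", "data.frame"))
}

#' Pointwise attenuation estimate (alternative estimator)
#'
#' The direct single-scatter inversion `mu(z) = -ln(I(z) / i0) / (2 z)`,
#' provided for comparison with the windowed fit used by the pipeline.
#' It is exact on noiseless homogeneous decay but far noisier than the
#' windowed fit under speckle, which is why the pipeline fits a slope
#' instead.
#'
#' @param intensity_profile linear intensity along one flattened A-line
#'   (index 1 = surface).
#' @param dz_um axial spacing, um.
#' @param i0 surface intensity; defaults to the first positive sample.
#' @return Numeric vector of mm^-1 values (`NA` at the surface sample and
#'   wherever intensity is non-positive).
#' @export
oac_pointwise <- function(intensity_profile, dz_um, i0 = NULL) {
  y <- as.numeric(intensity_profile)
  if (is.null(i0)) i0 <- y[which(is.finite(y) & y > 0)[1]]
  z_mm <- (seq_along(y) - 1) * dz_um / 1000
  out <- -log(y / i0) / (2 * z_mm)
  out[!is.finite(out) | y <= 0] <- NA_real_
  out
}
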