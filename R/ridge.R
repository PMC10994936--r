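# NAD ridge localization: angularly averaged radial profiles and per-ray
# argmax traces around a seed point.  The NAD grid is staggered half a pixel
# from the original map pixels (see directional_differences), which these
# helpers account for when converting coordinates.

nad_grid_coords <- function(nadmap, center_px) {
  off <- if (!is.null(nadmap$offset_px)) nadmap$offset_px else 0.5
  c(center_px[1] - off, center_px[2] - off)
}

#' Angularly averaged radial NAD profile
#'
#' Interpolates the NAD map along rays cast from a centre point and
#' averages over angles, giving mean NAD as a function of radius.  The
#' radius of the maximum of this profile is the NAD ridge radius, an
#' estimate of a circular boundary's radius.
#'
#' @param nadmap a [nad_map()].
#' @param center_px `(x, y)` centre in original map pixel coordinates
#'   (1-based).
#' @param r_max_px largest radius probed, pixels (default: to the nearest
#'   map edge).
#' @param dr_px radial step, pixels.
#' @param n_theta number of rays.
#' @return Data frame with `r_px`, `r_um`, `mean_nad` and `frac_valid`
#'   (fraction of rays with an unmasked sample at that radius).
#' @export
ridge_radius_profile <- function(nadmap, center_px, r_max_px = NULL,
                                 dr_px = 0.25, n_theta = 360L) {
  stopifnot(inherits(nadmap, "nad_map"))
  v <- nadmap$value
  ctr <- nad_grid_coords(nadmap, center_px)
  if (is.null(r_max_px))
    r_max_px <- min(ctr[1] - 1, nrow(v) - ctr[1], ctr[2] - 1, ncol(v) - ctr[2])
  if (r_max_px < 2) stop_validation("centre too close to the map edge")
  radii <- seq(1, r_max_px, by = dr_px)
  theta <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  ct <- cos(theta); st <- sin(theta)
  mean_nad <- numeric(length(radii))
  frac_valid <- numeric(length(radii))
  for (i in seq_along(radii)) {
    r <- radii[i]
    s <- interp2(v, ctr[1] + r * ct, ctr[2] + r * st)
    frac_valid[i] <- mean(is.finite(s))
    mean_nad[i] <- if (frac_valid[i] > 0) mean(s, na.rm = TRUE) else NA_real_
  }
  px_um <- nadmap$dx_um
  data.frame(r_px = radii,
             r_um = if (is.finite(px_um)) radii * px_um else NA_real_,
             mean_nad = mean_nad, frac_valid = frac_valid)
}

#' NAD ridge radius
#'
#' Radius (um) at which the angularly averaged NAD is maximal; radii where
#' fewer than half the rays are unmasked are excluded.
#'
#' @inheritParams ridge_radius_profile
#' @return Ridge radius in um (`NA` if no radius is evaluable).  Requires
#'   near-isotropic lateral sampling (`dx_um == dy_um`).
#' @export
ridge_radius <- function(nadmap, center_px, r_max_px = NULL,
                         dr_px = 0.25, n_theta = 360L) {
  if (is.finite(nadmap$dx_um) && is.finite(nadmap$dy_um) &&
      abs(nadmap$dx_um - nadmap$dy_um) > 1e-6 * nadmap$dx_um)
    stop_validation("ridge_radius assumes isotropic lateral sampling")
  prof <- ridge_radius_profile(nadmap, center_px, r_max_px, dr_px, n_theta)
  ok <- prof$frac_valid >= 0.5 & is.finite(prof$mean_nad)
  if (!any(ok)) return(NA_real_)
  prof$r_um[ok][which.max(prof$mean_nad[ok])]
}

# per-ray argmax radius; returns one NAD-grid pixel per ray.  The sampled
# profile is smoothed over ~1 px of radius before the argmax so that
# speckle-scale fluctuation does not capture single rays.
ridge_trace <- function(nadmap, center_px, r_max_px = NULL,
                        dr_px = 0.25, n_theta = 360L) {
  v <- nadmap$value
  ctr <- nad_grid_coords(nadmap, center_px)
  if (is.null(r_max_px))
    r_max_px <- min(ctr[1] - 1, nrow(v) - ctr[1], ctr[2] - 1, ncol(v) - ctr[2])
  radii <- seq(1, max(r_max_px, 2), by = dr_px)
  theta <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  smooth_w <- max(1L, round(1 / dr_px))
  ix <- iy <- r_hat <- rep(NA_real_, n_theta)
  for (t in seq_along(theta)) {
    xs <- ctr[1] + radii * cos(theta[t])
    ys <- ctr[2] + radii * sin(theta[t])
    s <- interp2(v, xs, ys)
    if (all(!is.finite(s))) next
    s <- as.vector(box_smooth_rows(matrix(s, ncol = 1), smooth_w))
    k <- which.max(s)
    r_hat[t] <- radii[k]
  }
  # circular median over neighbouring rays: a closed boundary varies slowly
  # with angle, so single rays captured by off-ridge noise peaks are outliers
  if (n_theta >= 9L) {
    padded <- c(tail(r_hat, 4L), r_hat, head(r_hat, 4L))
    r_hat <- vapply(seq_len(n_theta), function(t) {
      median(padded[t:(t + 8L)], na.rm = TRUE)
    }, numeric(1))
    r_hat[is.nan(r_hat)] <- NA_real_
  }
  ix <- round(ctr[1] + r_hat * cos(theta))
  iy <- round(ctr[2] + r_hat * sin(theta))
  ix[ix < 1 | ix > nrow(v)] <- NA_real_
  iy[iy < 1 | iy > ncol(v)] <- NA_real_
  list(theta = theta, r_px = r_hat, ix = ix, iy = iy)
}
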