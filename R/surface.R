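#' Detect the sample surface on every A-line
#'
#' The surface is taken as the position of the greatest axial intensity
#' variation: per A-line, the argmax of the first forward difference of the
#' (optionally box-smoothed) `log1p` intensity profile, with ties broken at
#' the shallowest index.  Differencing `log1p(I)` rather than raw `I` keeps
#' the detector robust to bright speckle spikes.  A-lines whose largest
#' difference falls below `min_prominence` are marked invalid (masked, never
#' interpolated); a 3x3 median filter then regularizes the height map over
#' the valid pixels.
#'
#' @param volume a linear-domain [oct_volume()].
#' @param axial_presmooth_px width of the centred axial box smoothing
#'   applied before differencing (1 = none; with no noise, 1 makes
#'   detection exact).
#' @param min_prominence minimum accepted forward difference (log domain).
#'   `NULL` uses a per-A-line default of 5 times the median absolute axial
#'   difference of that A-line.
#' @param median_filter logical; apply the 3x3 median regularization.
#' @return An object of class `surface_map`: `z_index` (`nx x ny` matrix of
#'   1-based surface sample indices, `NA` where invalid) and `valid`
#'   (logical matrix).
#' @export
detect_surface <- function(volume, axial_presmooth_px = 3L,
                           min_prominence = NULL, median_filter = TRUE) {
  stopifnot(inherits(volume, "oct_volume"))
  if (volume$log_domain)
    stop_validation("detect_surface expects a linear-domain volume")
  d <- vol_dims(volume)
  if (d$nz < 2L) stop_validation("need at least 2 axial samples")
  P <- d$nx * d$ny
  M <- log1p(matrix(volume$intensity, d$nz, P))
  M <- box_smooth_rows(M, as.integer(axial_presmooth_px))
  D <- M[-1L, , drop = FALSE] - M[-d$nz, , drop = FALSE]
  i0 <- max.col(t(D), ties.method = "first")
  peak <- D[cbind(i0, seq_len(P))]
  thr <- if (is.null(min_prominence)) {
    5 * col_medians(abs(D))
  } else {
    rep(min_prominence, P)
  }
  # absolute floor: a genuine surface rise is O(1) in the log domain, so
  # numerical dust on featureless A-lines never counts as a surface
  valid <- is.finite(peak) & peak > 1e-6 & peak >= thr
  if (!any(valid))
    stop("surface detection failed: no A-line has a prominent intensity rise")
  z <- i0 + 1L  # surface = sample the rise lands on
  z[!valid] <- NA_integer_
  zm <- matrix(z, d$nx, d$ny)
  vm <- matrix(valid, d$nx, d$ny)
  if (median_filter)
    zm <- round(median3x3(zm, vm))
  structure(list(z_index = zm, valid = vm, nz = d$nz, nx = d$nx, ny = d$ny),
            class = "surface_map")
}

#' @export
print.surface_map <- function(x, ...) {
  cat(sprintf("<surface_map> %d x %d, %.1f%% valid, z range [%s, %s]\n",
              x$nx, x$ny, 100 * mean(x$valid),
              suppressWarnings(min(x$z_index, na.rm = TRUE)),
              suppressWarnings(max(x$z_index, na.rm = TRUE))))
  invisible(x)
}

#' Flatten a volume to depth-below-surface coordinates
#'
#' Shifts every A-line so that its detected surface sample sits at output
#' index 1; sample `j` of the output then lies at depth `(j - 1) * dz_um`
#' below the surface.  Samples shifted beyond the acquisition window are
#' padded with `NA`, and invalid A-lines are fully masked.  Every non-`NA`
#' output sample equals exactly one input sample.
#'
#' @param volume a linear-domain [oct_volume()].
#' @param surface the matching [detect_surface()] result.
#' @return A flattened [oct_volume()].
#' @export
flatten <- function(volume, surface) {
  stopifnot(inherits(volume, "oct_volume"), inherits(surface, "surface_map"))
  d <- vol_dims(volume)
  if (surface$nx != d$nx || surface$ny != d$ny || surface$nz != d$nz)
    stop_validation("surface map does not match volume extents")
  if (mean(surface$valid) < 0.5)
    stop_validation("surface invalid on more than half of the A-lines")
  P <- d$nx * d$ny
  M <- matrix(volume$intensity, d$nz, P)
  k <- as.vector(surface$z_index) - 1L  # shift per A-line
  k[is.na(k)] <- d$nz                   # invalid: everything shifts out
  src <- rep(seq_len(d$nz), P) + rep(k, each = d$nz)
  ok <- src <= d$nz
  lin <- rep((seq_len(P) - 1L) * d$nz, each = d$nz) + src
  out <- rep(NA_real_, d$nz * P)
  out[ok] <- M[lin[ok]]
  oct_volume(array(out, dim = c(d$nz, d$nx, d$ny)),
             dz_um = volume$dz_um, dx_um = volume$dx_um, dy_um = volume$dy_um,
             log_domain = volume$log_domain, flattened = TRUE)
}

#' Export a surface map as CSV and a grayscale heightmap PNG
#'
#' @param surface a [detect_surface()] result.
#' @param path output base path (`.csv` and `.png` applied).
#' @return Invisibly, the written paths.
#' @export
write_surface_map <- function(surface, path) {
  stopifnot(inherits(surface, "surface_map"))
  m <- surface$z_index * 1.0
  base <- if (tolower(tools::file_ext(path)) %in% c("csv", "png"))
    tools::file_path_sans_ext(path) else path
  out <- write_map(m, base, colormap = "Grays",
                   display_range = c(1, surface$nz))
  invisible(out)
}
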