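#' OCT intensity volume
#'
#' Container for a 3-D OCT intensity field with its physical voxel spacing.
#' The array is indexed `(z, x, y)`: `z` runs along the A-line (index 1 is
#' the shallowest sample of the acquisition window), `x` across the A-lines
#' of one B-scan, and `y` across B-scan frames.  Indices are 1-based.
#'
#' Spacings are stored *in tissue*; if a file declares air-path axial
#' spacing, divide by the group refractive index at load time (see the
#' `refractive_index` field of [pipeline_config()] and [read_volume()]).
#'
#' @param intensity 3-D numeric array `(nz, nx, ny)`.  Linear-domain
#'   intensities must be non-negative; `NA` marks missing samples (used by
#'   [flatten()] for shifted-out padding).
#' @param dz_um,dx_um,dy_um voxel spacing in micrometres (> 0).
#' @param log_domain logical; `TRUE` if the values are log-intensity.
#' @param flattened logical; `TRUE` once A-lines have been re-indexed so
#'   that depth below the detected surface is `(z - 1) * dz_um`.
#' @return An object of class `oct_volume`.
#' @seealso [read_volume()], [write_volume()], [render_volume()]
#' @examples
#' v <- oct_volume(array(1, dim = c(8, 4, 3)), dz_um = 9.375, dx_um = 9, dy_um = 9)
#' dim(v$intensity)
#' @export
oct_volume <- function(intensity, dz_um, dx_um, dy_um,
                       log_domain = FALSE, flattened = FALSE) {
  if (!is.array(intensity) || length(dim(intensity)) != 3L)
    stop_validation("`intensity` must be a 3-D array indexed (z, x, y)")
  if (any(dim(intensity) < 1L))
    stop_validation("all extents must be >= 1")
  for (s in c(dz_um, dx_um, dy_um))
    if (!is.numeric(s) || length(s) != 1L || !is.finite(s) || s <= 0)
      stop_validation("voxel spacings must be single positive numbers")
  if (!log_domain) {
    mn <- suppressWarnings(min(intensity, na.rm = TRUE))
    if (is.finite(mn) && mn < 0)
      stop_validation("linear-domain intensities must be >= 0")
  }
  structure(
    list(intensity = intensity,
         dz_um = as.numeric(dz_um), dx_um = as.numeric(dx_um),
         dy_um = as.numeric(dy_um),
         log_domain = isTRUE(log_domain), flattened = isTRUE(flattened)),
    class = "oct_volume")
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("<oct_volume> %d x %d x %d (z, x, y)\n", d[1], d[2], d[3]))
  cat(sprintf("  spacing: dz %.4g um, dx %.4g um, dy %.4g um (in tissue)\n",
              x$dz_um, x$dx_um, x$dy_um))
  cat(sprintf("  span: %.3g x %.3g x %.3g mm\n",
              d[1] * x$dz_um / 1000, d[2] * x$dx_um / 1000, d[3] * x$dy_um / 1000))
  cat(sprintf("  domain: %s%s\n", if (x$log_domain) "log" else "linear",
              if (x$flattened) ", flattened to depth-below-surface" else ""))
  invisible(x)
}

#' @export
dim.oct_volume <- function(x) dim(x$intensity)

vol_dims <- function(volume) {
  d <- dim(volume$intensity)
  list(nz = d[1], nx = d[2], ny = d[3])
}
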