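#' Surface topography generators for phantoms
#'
#' Surface depth (um from the top of the acquisition window) as a function
#' of the lateral position.  `surface_flat` is a constant plane,
#' `surface_plane` a tilted plane with gradients in um depth per um lateral
#' distance, and `surface_bump` a Gaussian mound.
#'
#' @param z0_um base depth of the surface, um.
#' @param gx,gy plane gradients (um axial per um lateral).
#' @param amplitude_um bump height (positive = deeper at the centre).
#' @param sigma_um bump lateral scale.
#' @param center_frac bump centre as fractions of the lateral field of view.
#' @return A surface descriptor used in [phantom_spec()].
#' @name phantom_surfaces
NULL

#' @rdname phantom_surfaces
#' @export
surface_flat <- function(z0_um) {
  structure(list(type = "flat", z0_um = z0_um), class = "phantom_surface")
}

#' @rdname phantom_surfaces
#' @export
surface_plane <- function(z0_um, gx = 0, gy = 0) {
  structure(list(type = "plane", z0_um = z0_um, gx = gx, gy = gy),
            class = "phantom_surface")
}

#' @rdname phantom_surfaces
#' @export
surface_bump <- function(z0_um, amplitude_um, sigma_um, center_frac = c(0.5, 0.5)) {
  structure(list(type = "bump", z0_um = z0_um, amplitude_um = amplitude_um,
                 sigma_um = sigma_um, center_frac = center_frac),
            class = "phantom_surface")
}

#' Attenuation inclusion inside a phantom
#'
#' Regions of distinct attenuation embedded in the background medium.
#' Depth coordinates are measured below the local surface.
#'
#' * `ellipsoid`: centre `(cx, cy, cz)` with semi-axes `(ax, ay, az)`;
#'   emulates a tumor nodule (set `mu` below the background).
#' * `cylinder`: lateral ellipse `(cx, cy, ax, ay)` extruded through all
#'   depths (the `cz`/`az` entries are ignored).
#' * `slab`: band `|y - cy| <= ay`, `|depth - cz| <= az`, spanning all x;
#'   emulates a high-attenuation white-matter tract such as the corpus
#'   callosum.
#'
#' @param shape `"ellipsoid"`, `"cylinder"` or `"slab"`.
#' @param center_um numeric `(cx, cy, cz)` in um; `cz` is depth below the
#'   surface.
#' @param semi_axes_um numeric `(ax, ay, az)` in um, all > 0.
#' @param mu attenuation coefficient inside the inclusion, mm^-1 (>= 0).
#' @return An object of class `phantom_inclusion`.
#' @export
inclusion <- function(shape = c("ellipsoid", "cylinder", "slab"),
                      center_um, semi_axes_um, mu) {
  shape <- match.arg(shape)
  if (length(center_um) != 3L || length(semi_axes_um) != 3L)
    stop_validation("`center_um` and `semi_axes_um` must have length 3")
  if (any(semi_axes_um <= 0)) stop_validation("semi-axes must be > 0")
  if (mu < 0) stop_validation("`mu` must be >= 0")
  structure(list(shape = shape, center_um = as.numeric(center_um),
                 semi_axes_um = as.numeric(semi_axes_um), mu = as.numeric(mu)),
            class = "phantom_inclusion")
}

#' Noise model for phantoms
#'
#' Speckle is modelled as fully developed intensity speckle after
#' square-law detection: an independent per-voxel multiplicative factor
#' drawn from a unit-mean exponential distribution.  An additive noise
#' floor (same everywhere, including above the surface) can be added.
#'
#' @param kind `"none"` or `"speckle"`.
#' @param floor additive noise floor, intensity units (>= 0).
#' @return An object of class `phantom_noise`.
#' @export
noise_spec <- function(kind = c("none", "speckle"), floor = 0) {
  kind <- match.arg(kind)
  if (floor < 0) stop_validation("noise `floor` must be >= 0")
  structure(list(kind = kind, floor = as.numeric(floor)), class = "phantom_noise")
}

#' Synthetic SS-OCT phantom specification
#'
#' Defines a volume with a surface, a Beer-Lambert attenuating medium with
#' region-dependent attenuation, and optional speckle, together with the
#' parameters needed to compute its analytic ground truth.
#'
#' @param nz,nx,ny grid extents.
#' @param dz_um,dx_um,dy_um voxel spacing, um (defaults follow a 375-um /
#'   40-pixel axial window and ~9 um lateral pitch).
#' @param surface a [surface_flat()], [surface_plane()] or [surface_bump()].
#' @param mu_background background attenuation, mm^-1.
#' @param inclusions list of [inclusion()]; later entries override earlier
#'   ones where they overlap.
#' @param i0 intensity at the surface (linear units).
#' @param noise a [noise_spec()].
#' @param seed integer seed making [render_volume()] deterministic.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(nz, nx, ny,
                         dz_um = 9.375, dx_um = 9, dy_um = 9,
                         surface = surface_flat(150),
                         mu_background = 3,
                         inclusions = list(),
                         i0 = 1e4,
                         noise = noise_spec("none"),
                         seed = 1L) {
  if (mu_background < 0) stop_validation("`mu_background` must be >= 0")
  if (i0 <= 0) stop_validation("`i0` must be > 0")
  if (!inherits(surface, "phantom_surface")) stop_validation("invalid `surface`")
  if (!inherits(noise, "phantom_noise")) stop_validation("invalid `noise`")
  for (inc in inclusions)
    if (!inherits(inc, "phantom_inclusion")) stop_validation("invalid inclusion")
  sp <- structure(list(nz = as.integer(nz), nx = as.integer(nx), ny = as.integer(ny),
                       dz_um = dz_um, dx_um = dx_um, dy_um = dy_um,
                       surface = surface, mu_background = mu_background,
                       inclusions = inclusions, i0 = i0, noise = noise,
                       seed = as.integer(seed)),
                  class = "phantom_spec")
  sz <- surface_z_matrix(sp)
  if (any(sz < 0) || any(sz > (nz - 1) * dz_um))
    stop_validation("surface must lie inside the axial window for all (x, y)")
  sp
}

#' Surface depth map of a phantom
#'
#' @param spec a [phantom_spec()].
#' @return `nx x ny` matrix of surface depths in um from the top of the
#'   acquisition window.
#' @export
surface_z_matrix <- function(spec) {
  x <- (seq_len(spec$nx) - 1) * spec$dx_um
  y <- (seq_len(spec$ny) - 1) * spec$dy_um
  s <- spec$surface
  switch(s$type,
    flat = matrix(s$z0_um, spec$nx, spec$ny),
    plane = outer(x * s$gx, y * s$gy, "+") + s$z0_um,
    bump = {
      cx <- s$center_frac[1] * max(x); cy <- s$center_frac[2] * max(y)
      r2 <- outer((x - cx)^2, (y - cy)^2, "+")
      s$z0_um + s$amplitude_um * exp(-r2 / (2 * s$sigma_um^2))
    })
}

# 1-based z index of the first sample at or below the surface, per A-line
surface_index_matrix <- function(spec) {
  sz <- surface_z_matrix(spec)
  matrix(as.integer(ceiling(sz / spec$dz_um)) + 1L, spec$nx, spec$ny)
}

#' Voxelized attenuation field and analytic ground truth
#'
#' Builds the true attenuation field of a phantom: zero above the surface,
#' the background value below it, and each inclusion's value inside the
#' inclusion (later inclusions override earlier ones).
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `ground_truth` with `mu_field` (array
#'   `(nz, nx, ny)`, mm^-1), `surface_z_um` (matrix, um),
#'   `surface_index` (matrix, 1-based z index of the surface sample), and
#'   the inclusion list.  See [boundary_radius()] for the analytic en-face
#'   boundary of an inclusion.
#' @export
build_mu_field <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  nz <- spec$nz; nx <- spec$nx; ny <- spec$ny
  P <- nx * ny
  sidx <- surface_index_matrix(spec)
  # depth below surface (um) of each sample; negative above the surface
  depth <- outer(seq_len(nz), as.vector(sidx), "-") * spec$dz_um
  below <- depth >= 0
  mu <- matrix(0, nz, P)
  mu[below] <- spec$mu_background
  x_um <- (seq_len(nx) - 1) * spec$dx_um
  y_um <- (seq_len(ny) - 1) * spec$dy_um
  X <- matrix(x_um, nx, ny)
  Y <- matrix(y_um, nx, ny, byrow = TRUE)
  for (inc in spec$inclusions) {
    cx <- inc$center_um[1]; cy <- inc$center_um[2]; cz <- inc$center_um[3]
    ax <- inc$semi_axes_um[1]; ay <- inc$semi_axes_um[2]; az <- inc$semi_axes_um[3]
    inside <- switch(inc$shape,
      ellipsoid = {
        lat2 <- as.vector(((X - cx) / ax)^2 + ((Y - cy) / ay)^2)
        ax2 <- ((depth - cz) / az)^2
        sweep(ax2, 2, lat2, "+") <= 1
      },
      cylinder = {
        lat <- as.vector(((X - cx) / ax)^2 + ((Y - cy) / ay)^2) <= 1
        matrix(lat, nz, P, byrow = TRUE)
      },
      slab = {
        lat <- as.vector(abs(Y - cy) <= ay)
        matrix(lat, nz, P, byrow = TRUE) & abs(depth - cz) <= az
      })
    inside <- inside & below
    if (!any(inside))
      warning("inclusion lies entirely above the surface or outside the grid")
    mu[inside] <- inc$mu
  }
  structure(list(mu_field = array(mu, dim = c(nz, nx, ny)),
                 surface_z_um = surface_z_matrix(spec),
                 surface_index = sidx,
                 inclusions = spec$inclusions,
                 spec = spec),
            class = "ground_truth")
}

#' Analytic en-face boundary radius of an inclusion
#'
#' For an ellipsoid with lateral semi-axis `a` and axial semi-axis `c`
#' centred `cz` below the surface, the cross-section at depth `d` is a
#' circle of radius `a * sqrt(1 - ((d - cz)/c)^2)` (requires `ax == ay`);
#' a cylinder has constant radius; a slab has no radius (`NA`).
#'
#' @param truth a `ground_truth` from [build_mu_field()].
#' @param depth_um depth(s) below the surface, um.
#' @param which index of the inclusion (default 1).
#' @return Radius in um (vectorized over `depth_um`); `NA` where the depth
#'   misses the inclusion.
#' @export
boundary_radius <- function(truth, depth_um, which = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  inc <- truth$inclusions[[which]]
  a <- inc$semi_axes_um[1]; ay <- inc$semi_axes_um[2]
  cz <- inc$center_um[3]; cc <- inc$semi_axes_um[3]
  switch(inc$shape,
    cylinder = rep(a, length(depth_um)),
    slab = rep(NA_real_, length(depth_um)),
    ellipsoid = {
      if (abs(a - ay) > 1e-9)
        stop_validation("boundary_radius requires a circular (ax == ay) ellipsoid")
      t <- 1 - ((depth_um - cz) / cc)^2
      ifelse(t >= 0, a * sqrt(t), NA_real_)
    })
}

#' Render a phantom into an OCT intensity volume
#'
#' Forward Beer-Lambert model: above the surface the signal is zero (plus
#' the noise floor); below it each A-line decays as
#' `i0 * exp(-2 * sum(mu * dz))`, the optical path accumulated voxel by
#' voxel through the (possibly heterogeneous) attenuation field, so light
#' traverses each depth twice.  Speckle multiplies the signal voxel-wise.
#' Deterministic given `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @param truth optional precomputed [build_mu_field()] result.
#' @return An [oct_volume()] in the linear domain.
#' @export
render_volume <- function(spec, truth = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.null(truth)) truth <- build_mu_field(spec)
  nz <- spec$nz; P <- spec$nx * spec$ny
  mu <- matrix(truth$mu_field, nz, P)
  dz_mm <- spec$dz_um / 1000
  # optical path to the top of each voxel: cumulative sum excluding itself
  path <- (apply(mu, 2, cumsum) - mu) * dz_mm
  depth <- outer(seq_len(nz), as.vector(truth$surface_index), "-")
  signal <- ifelse(depth >= 0, spec$i0 * exp(-2 * path), 0)
  if (spec$noise$kind == "speckle") {
    signal <- with_seed(spec$seed, signal * rexp(length(signal)))
  }
  signal <- signal + spec$noise$floor
  oct_volume(array(signal, dim = c(nz, spec$nx, spec$ny)),
             dz_um = spec$dz_um, dx_um = spec$dx_um, dy_um = spec$dy_um)
}

#' Glioma-like phantom preset
#'
#' A documented phantom emulating the structure of a coronally sectioned
#' tumor-bearing brain imaged face-on: a flat surface, a scattering
#' background, one low-attenuation ellipsoidal "tumor" nodule whose
#' en-face cross-section shrinks with depth, one thin high-attenuation
#' vertical band playing the role of the corpus callosum, and speckle.
#' The tumor attenuation is half the background and the band twice it.
#'
#' @param small logical; `TRUE` returns a reduced grid (128 x 96 x 96)
#'   with proportionally smaller structures, suitable for fast tests.
#' @param seed RNG seed stored in the spec.
#' @return A [phantom_spec()] with an extra `$roi_suggestion`, an
#'   [enface_roi()] centred inside the tumor for NOAC normalization.
#' @export
glioma_phantom_preset <- function(small = FALSE, seed = 101L) {
  if (small) {
    nz <- 128L; nx <- 96L; ny <- 96L
    tumor <- inclusion("ellipsoid", center_um = c(0.45 * 95 * 9, 0.55 * 95 * 9, 400),
                       semi_axes_um = c(280, 280, 350), mu = 1.5)
    band <- inclusion("slab", center_um = c(0, 0.12 * 95 * 9, 500),
                      semi_axes_um = c(1, 45, 500), mu = 6)
  } else {
    nz <- 192L; nx <- 160L; ny <- 160L
    tumor <- inclusion("ellipsoid", center_um = c(0.45 * 159 * 9, 0.55 * 159 * 9, 450),
                       semi_axes_um = c(450, 450, 450), mu = 1.5)
    band <- inclusion("slab", center_um = c(0, 0.12 * 159 * 9, 600),
                      semi_axes_um = c(1, 60, 600), mu = 6)
  }
  sp <- phantom_spec(nz, nx, ny,
                     surface = surface_flat(150),
                     mu_background = 3,
                     inclusions = list(tumor, band),
                     i0 = 1e4,
                     noise = noise_spec("speckle", floor = 0),
                     seed = seed)
  cx <- round(tumor$center_um[1] / sp$dx_um) + 1L
  cy <- round(tumor$center_um[2] / sp$dy_um) + 1L
  half <- max(2L, as.integer(tumor$semi_axes_um[1] / sp$dx_um / 3))
  sp$roi_suggestion <- enface_roi(cx - half, cx + half, cy - half, cy + half)
  sp
}

#' Export phantom ground truth
#'
#' Writes the scalar/inclusion parameters as JSON and the voxelized
#' attenuation field as a raw float32 volume with sidecar (via
#' [write_volume()]).
#'
#' @param truth a `ground_truth` from [build_mu_field()].
#' @param base output path base (files `<base>_truth.json`,
#'   `<base>_mu.bin`, `<base>_mu.json`).
#' @return Invisibly, the written paths.
#' @export
write_ground_truth <- function(truth, base) {
  stopifnot(inherits(truth, "ground_truth"))
  sp <- truth$spec
  meta <- list(mu_background = sp$mu_background, i0 = sp$i0,
               seed = sp$seed, noise = unclass(sp$noise),
               surface = unclass(sp$surface),
               inclusions = lapply(sp$inclusions, unclass))
  jf <- paste0(base, "_truth.json")
  jsonlite::write_json(meta, jf, auto_unbox = TRUE, digits = NA)
  muvol <- oct_volume(truth$mu_field, sp$dz_um, sp$dx_um, sp$dy_um)
  mf <- paste0(base, "_mu.bin")
  write_volume(muvol, mf)
  invisible(list(truth_json = jf, mu_volume = mf))
}
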