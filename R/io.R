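#' Write an OCT volume to disk
#'
#' Two on-disk layouts are supported, both accompanied by a JSON sidecar
#' carrying dtype, extents, spacings and domain flags:
#'
#' * `raw` (extension anything but `.tif`/`.tiff`): IEEE float32
#'   little-endian, z fastest, then x, then y.  Bit-exact for float32 data
#'   and the format used for lossless round trips.
#' * `tiff`: multi-page TIFF, one page per B-scan (page rows = z, columns =
#'   x), 16-bit unsigned samples scaled by the sidecar field
#'   `intensity_scale` (values quantized to 65535 levels).
#'
#' @param volume an [oct_volume()].
#' @param path output path; the sidecar is written next to it with the
#'   extension replaced by `.json`.
#' @return Invisibly, a list with the data and sidecar paths.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "oct_volume"))
  d <- vol_dims(volume)
  ext <- tolower(tools::file_ext(path))
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  meta <- list(nz = d$nz, nx = d$nx, ny = d$ny,
               dz_um = volume$dz_um, dx_um = volume$dx_um, dy_um = volume$dy_um,
               log_domain = volume$log_domain, flattened = volume$flattened)
  if (ext %in% c("tif", "tiff")) {
    v <- volume$intensity
    scale <- suppressWarnings(max(v, na.rm = TRUE))
    if (!is.finite(scale) || scale <= 0) scale <- 1
    pages <- lapply(seq_len(d$ny), function(iy) {
      p <- v[, , iy] / scale
      p[!is.finite(p)] <- 0
      pmin(pmax(p, 0), 1)
    })
    tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
                    reduce = FALSE)
    meta$dtype <- "uint16"
    meta$intensity_scale <- scale
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    v <- as.numeric(volume$intensity)
    v[!is.finite(v)] <- NaN
    writeBin(v, con, size = 4L, endian = "little")
    meta$dtype <- "float32"
  }
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(list(path = path, sidecar = sidecar))
}

#' Read an OCT volume
#'
#' Reads either layout written by [write_volume()]: a multi-page TIFF
#' (pages = B-scans, page rows = z, page columns = x) or raw binary, each
#' described by a JSON sidecar.  Sidecar spacings can be overridden, and an
#' air-path axial spacing is converted to in-tissue spacing by dividing by
#' `refractive_index`.
#'
#' @param path data file path (sidecar expected at the same path with a
#'   `.json` extension).
#' @param spacing_override optional named list with any of `dz_um`,
#'   `dx_um`, `dy_um`, taking precedence over the sidecar.
#' @param refractive_index divisor applied to the axial spacing (default 1,
#'   i.e. the sidecar spacing is already in tissue).
#' @return An [oct_volume()].
#' @export
read_volume <- function(path, spacing_override = NULL, refractive_index = 1) {
  if (!file.exists(path)) stop("volume file not found: ", path)
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  if (!file.exists(sidecar)) stop("sidecar not found: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  need <- c("dtype", "nz", "nx", "ny", "dz_um", "dx_um", "dy_um")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop_validation("sidecar missing field(s): ", paste(miss, collapse = ", "))
  if (!is.null(spacing_override))
    meta[names(spacing_override)] <- spacing_override
  if (any(unlist(meta[c("dz_um", "dx_um", "dy_um")]) <= 0))
    stop_validation("voxel spacings must be positive")
  nz <- meta$nz; nx <- meta$nx; ny <- meta$ny
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = identical(meta$dtype, "uint16"))
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) != ny)
      stop(sprintf("format error: %d TIFF pages but sidecar declares ny = %d",
                   length(pages), ny))
    if (!all(dim(pages[[1]]) == c(nz, nx)))
      stop(sprintf("format error: page is %d x %d but sidecar declares %d x %d",
                   nrow(pages[[1]]), ncol(pages[[1]]), nz, nx))
    arr <- array(NA_real_, dim = c(nz, nx, ny))
    scale <- if (!is.null(meta$intensity_scale)) meta$intensity_scale else 1
    for (iy in seq_len(ny)) {
      p <- pages[[iy]]
      if (identical(meta$dtype, "uint16")) p <- p / 65535 * scale
      arr[, , iy] <- p
    }
  } else {
    n <- nz * nx * ny
    size <- switch(meta$dtype,
                   float32 = 4L, float64 = 8L, uint16 = 2L,
                   stop_validation("unsupported dtype: ", meta$dtype))
    if (file.size(path) != n * size)
      stop(sprintf("format error: file has %d bytes, expected %d (%dx%dx%d %s)",
                   file.size(path), n * size, nz, nx, ny, meta$dtype))
    con <- file(path, "rb")
    on.exit(close(con))
    v <- if (meta$dtype == "uint16") {
      readBin(con, "integer", n = n, size = 2L, signed = FALSE, endian = "little")
    } else {
      readBin(con, "double", n = n, size = size, endian = "little")
    }
    arr <- array(as.numeric(v), dim = c(nz, nx, ny))
  }
  oct_volume(arr, dz_um = meta$dz_um / refractive_index,
             dx_um = meta$dx_um, dy_um = meta$dy_um,
             log_domain = isTRUE(meta$log_domain),
             flattened = isTRUE(meta$flattened))
}

map_matrix <- function(map2d) {
  if (is.matrix(map2d)) return(map2d)
  if (is.list(map2d) && is.matrix(map2d$value)) return(map2d$value)
  stop_validation("expected a matrix or a map object with a $value matrix")
}

#' Write an en-face map as lossless CSV plus a rendered PNG
#'
#' Every rendered image is paired with a full-precision CSV so numbers are
#' never read back off pixels.  Missing values are empty cells in the CSV
#' and transparent in the PNG; the display is clipped to `display_range`
#' while the CSV keeps raw values.
#'
#' @param map2d a matrix or any map object with a `$value` matrix
#'   (`oac_map`, `noac_map`, `nad_map`).  Rows are x, columns y.
#' @param path output base path; `.csv` and `.png` extensions are applied
#'   (an existing `.csv`/`.png` extension is stripped first).
#' @param colormap palette name passed to [grDevices::hcl.colors()].
#' @param display_range length-2 numeric display clip; defaults to `[0, 1]`
#'   for normalized (`noac_map`) maps and to the finite data range otherwise.
#' @return Invisibly, the CSV and PNG paths.
#' @export
write_map <- function(map2d, path, colormap = "viridis", display_range = NULL) {
  m <- map_matrix(map2d)
  base <- if (tolower(tools::file_ext(path)) %in% c("csv", "png"))
    tools::file_path_sans_ext(path) else path
  csv <- paste0(base, ".csv")
  pngf <- paste0(base, ".png")
  chr <- matrix("", nrow(m), ncol(m))
  ok <- is.finite(m)
  chr[ok] <- fmt_num(m[ok])
  write.table(chr, csv, sep = ",", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  if (is.null(display_range)) {
    display_range <- if (inherits(map2d, "noac_map")) c(0, 1)
    else suppressWarnings(range(m, finite = TRUE))
    if (!all(is.finite(display_range)) || diff(display_range) == 0)
      display_range <- c(0, 1)
  }
  pal <- hcl.colors(256, colormap)
  rgbv <- col2rgb(pal) / 255
  idx <- (pmin(pmax(m, display_range[1]), display_range[2]) - display_range[1]) /
    diff(display_range)
  idx <- 1L + as.integer(round(idx * 255))
  img <- array(0, dim = c(ncol(m), nrow(m), 4))  # PNG rows = y, cols = x
  for (ch in 1:3) {
    plane <- matrix(0, nrow(m), ncol(m))
    plane[ok] <- rgbv[ch, idx[ok]]
    img[, , ch] <- t(plane)
  }
  img[, , 4] <- t(ok + 0)
  png::writePNG(img, pngf)
  invisible(list(csv = csv, png = pngf))
}

#' Read a map CSV written by [write_map()]
#'
#' @param path CSV path.
#' @return Numeric matrix (rows x, columns y); empty cells become `NA`.
#' @export
read_map_csv <- function(path) {
  df <- read.csv(path, header = FALSE, colClasses = "character")
  m <- apply(as.matrix(df), c(1, 2), function(s) {
    if (is.na(s) || !nzchar(s)) NA_real_ else as.numeric(s)
  })
  dimnames(m) <- NULL
  m
}
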