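#' Run the full NAD pipeline on a raw volume
#'
#' Surface detection, flattening, and NAD stack construction in one call.
#'
#' @param volume a linear-domain [oct_volume()] (not yet flattened).
#' @param roi [enface_roi()] for normalization (falls back to
#'   `config$roi`).
#' @param config a [pipeline_config()].
#' @param verbose emit per-depth QC messages.
#' @return List with `surface` ([detect_surface()]), `flattened`
#'   ([flatten()]) and `nad` ([nad_volume()]).
#' @export
run_nad_pipeline <- function(volume, roi = NULL, config = pipeline_config(),
                             verbose = FALSE) {
  if (is.null(roi)) roi <- config$roi
  if (is.null(roi)) stop_validation("an ROI is required (argument or config)")
  surf <- detect_surface(volume, axial_presmooth_px = config$surface_presmooth_px)
  flat <- flatten(volume, surf)
  nv <- nad_volume(flat, roi, depths_um = config$depths_um,
                   config = config, verbose = verbose)
  list(surface = surf, flattened = flat, nad = nv)
}

#' Alpha-blended NAD overlay
#'
#' Renders a grayscale en-face OCT mean-intensity image at a depth with the
#' NAD map blended on top in colour (alpha proportional to NAD, clipped at
#' the 99th percentile).  Cosmetic defaults; the quantitative products are
#' the CSV exports.
#'
#' @param volume flattened [oct_volume()].
#' @param nadmap a [nad_map()] at the same depth.
#' @param path output PNG path.
#' @param config a [pipeline_config()] (for the window length).
#' @param colormap palette for the NAD layer.
#' @return Invisibly, `path`.
#' @export
write_overlay <- function(volume, nadmap, path, config = pipeline_config(),
                          colormap = "Inferno") {
  check_flattened(volume)
  d <- vol_dims(volume)
  start <- as.integer(round(nadmap$depth_um / volume$dz_um)) + 1L
  hi <- min(start + config$fit_window_px - 1L, d$nz)
  gray <- apply(volume$intensity[start:hi, , , drop = FALSE], c(2, 3),
                mean, na.rm = TRUE)
  gray <- log1p(gray)
  rng <- range(gray, finite = TRUE)
  gray <- (gray - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps)
  gray[!is.finite(gray)] <- 0
  # NAD grid is (nx-1)x(ny-1), staggered half a pixel; pad to align
  v <- nadmap$value
  nv <- matrix(0, d$nx, d$ny)
  nv[1:nrow(v), 1:ncol(v)] <- ifelse(is.finite(v), v, 0)
  vals <- v[is.finite(v)]
  cap <- if (length(vals)) quantile(vals, 0.99, names = FALSE) else 1
  if (!is.finite(cap) || cap <= 0) cap <- 1
  alpha <- pmin(nv / cap, 1)
  pal <- hcl.colors(256, colormap)
  rgbv <- col2rgb(pal) / 255
  idx <- 1L + as.integer(round(pmin(nv / cap, 1) * 255))
  img <- array(0, dim = c(d$ny, d$nx, 3))
  for (ch in 1:3) {
    layer <- matrix(rgbv[ch, idx], d$nx, d$ny)
    img[, , ch] <- t(gray * (1 - alpha) + layer * alpha)
  }
  png::writePNG(img, path)
  invisible(path)
}

cli_arg <- function(args, flag, default = NULL, n = 1L) {
  i <- which(args == flag)
  if (!length(i)) return(default)
  vals <- args[i + seq_len(n)]
  if (anyNA(vals)) stop("missing value for ", flag, call. = FALSE)
  vals
}

cli_collect <- function(args, flag) {
  i <- which(args == flag)
  if (!length(i)) return(NULL)
  args[i + 1L]
}

parse_roi_arg <- function(s) {
  p <- as.integer(strsplit(s, ",")[[1]])
  if (length(p) != 4L) stop("--roi expects x0,y0,x1,y1", call. = FALSE)
  enface_roi(p[1], p[3], p[2], p[4])
}

#' Command-line entry point
#'
#' Drives the pipeline from a shell via the `inst/cli/octnad.R` script:
#' ```
#' Rscript octnad.R simulate --preset full|small --seed N --out base
#' Rscript octnad.R oacmap   --input vol --config cfg --roi x0,y0,x1,y1 \
#'                           --depth d [--depth d ...] --out dir
#' Rscript octnad.R nad      --input vol --config cfg --roi x0,y0,x1,y1 --out dir
#' Rscript octnad.R overlay  --input vol --config cfg --roi x0,y0,x1,y1 \
#'                           --depth d --out file.png
#' ```
#' `simulate` writes a phantom volume (raw float32 + sidecar) and its
#' ground truth; `oacmap` writes en-face OAC maps (CSV + PNG) at the given
#' depths; `nad` writes the NAD stack (TIFF + JSON provenance) and per-depth
#' CSV/PNG maps; `overlay` writes a blended composite.
#'
#' @param args character vector of command-line arguments (defaults to the
#'   process arguments).
#' @return Exit status 0, invisibly.
#' @export
octnad_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) stop("usage: octnad.R <simulate|oacmap|nad|overlay> ...",
                          call. = FALSE)
  cmd <- args[1]
  args <- args[-1]
  load_cfg <- function() {
    cf <- cli_arg(args, "--config")
    if (is.null(cf)) pipeline_config() else load_config(cf)
  }
  switch(cmd,
    simulate = {
      preset <- cli_arg(args, "--preset", "small")
      seed <- as.integer(cli_arg(args, "--seed", "101"))
      out <- cli_arg(args, "--out")
      if (is.null(out)) stop("simulate needs --out", call. = FALSE)
      sp <- glioma_phantom_preset(small = identical(preset, "small"), seed = seed)
      truth <- build_mu_field(sp)
      vol <- render_volume(sp, truth)
      write_volume(vol, paste0(out, ".bin"))
      write_ground_truth(truth, out)
      r <- sp$roi_suggestion
      message(sprintf("wrote %s.bin (+sidecar, ground truth); suggested ROI %d,%d,%d,%d",
                      out, r$x0, r$y0, r$x1, r$y1))
    },
    oacmap = {
      cfg <- load_cfg()
      vol <- read_volume(cli_arg(args, "--input"),
                         refractive_index = cfg$refractive_index)
      depths <- as.numeric(cli_collect(args, "--depth"))
      out <- cli_arg(args, "--out", ".")
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      surf <- detect_surface(vol, axial_presmooth_px = cfg$surface_presmooth_px)
      flat <- flatten(vol, surf)
      write_surface_map(surf, file.path(out, "surface"))
      for (dep in depths) {
        om <- enface_oac_map(flat, dep, cfg)
        write_map(om, file.path(out, sprintf("oac_%04.0fum", dep)))
        message(sprintf("depth %g um: masked %.1f%%, negative fits %d",
                        dep, 100 * mean(is.na(om$value)), om$n_negative))
      }
    },
    nad = {
      cfg <- load_cfg()
      vol <- read_volume(cli_arg(args, "--input"),
                         refractive_index = cfg$refractive_index)
      roiarg <- cli_arg(args, "--roi")
      roi <- if (is.null(roiarg)) cfg$roi else parse_roi_arg(roiarg)
      out <- cli_arg(args, "--out", ".")
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      res <- run_nad_pipeline(vol, roi = roi, config = cfg, verbose = TRUE)
      write_surface_map(res$surface, file.path(out, "surface"))
      write_nad_volume(res$nad, file.path(out, "nad_stack"))
      for (m in res$nad$maps)
        write_map(m, file.path(out, sprintf("nad_%04.0fum", m$depth_um)))
    },
    overlay = {
      cfg <- load_cfg()
      vol <- read_volume(cli_arg(args, "--input"),
                         refractive_index = cfg$refractive_index)
      roiarg <- cli_arg(args, "--roi")
      roi <- if (is.null(roiarg)) cfg$roi else parse_roi_arg(roiarg)
      dep <- as.numeric(cli_arg(args, "--depth"))
      out <- cli_arg(args, "--out", "overlay.png")
      surf <- detect_surface(vol, axial_presmooth_px = cfg$surface_presmooth_px)
      flat <- flatten(vol, surf)
      cfg$depths_um <- NULL
      nv <- nad_volume(flat, roi, depths_um = dep, config = cfg)
      write_overlay(flat, nv$maps[[1]], out, cfg)
      message("wrote ", out)
    },
    stop("unknown subcommand: ", cmd, call. = FALSE))
  invisible(0L)
}
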