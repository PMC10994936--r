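#' Rectangular en-face region of interest
#'
#' A rectangle in en-face `(x, y)` pixel coordinates, 1-based and inclusive
#' on both ends.  Used both for the normalization ROI (the "red box" placed
#' inside the tumor) and for region averages in depth profiles.
#'
#' @param x0,x1,y0,y1 integer pixel bounds, `x0 <= x1`, `y0 <= y1`.
#' @return An object of class `enface_roi`.
#' @export
enface_roi <- function(x0, x1, y0, y1) {
  b <- c(x0 = x0, x1 = x1, y0 = y0, y1 = y1)
  if (any(!is.finite(b)) || any(b != round(b)))
    stop_validation("ROI bounds must be finite integers")
  if (x0 < 1 || y0 < 1 || x1 < x0 || y1 < y0)
    stop_validation("ROI requires 1 <= x0 <= x1 and 1 <= y0 <= y1")
  if ((x1 - x0 + 1) * (y1 - y0 + 1) < 4)
    stop_validation("ROI area must be at least 4 pixels")
  structure(list(x0 = as.integer(x0), x1 = as.integer(x1),
                 y0 = as.integer(y0), y1 = as.integer(y1)),
            class = "enface_roi")
}

check_roi_bounds <- function(roi, nx, ny) {
  if (!inherits(roi, "enface_roi")) stop_validation("`roi` must be an enface_roi")
  if (roi$x1 > nx || roi$y1 > ny)
    stop_validation(sprintf("ROI [%d:%d, %d:%d] exceeds map extent %d x %d",
                            roi$x0, roi$x1, roi$y0, roi$y1, nx, ny))
  invisible(roi)
}

#' Pipeline configuration
#'
#' Parameters of the OAC/NAD processing chain with their defaults.
#'
#' @param lateral_avg_width odd number of A-lines averaged within each
#'   B-scan before the log-linear fit (default 21; use 20 for a literal
#'   left-biased 20-line window, any even width is averaged left-biased).
#' @param fit_window_px depth-window length of the log-linear OAC fit, in
#'   axial pixels (default 40; at 9.375 um/pixel this spans 375 um).
#' @param lowpass_sigma_px Gaussian sigma (pixels) of the en-face low-pass
#'   filter applied to NOAC maps before differencing (default 2; 0 disables).
#' @param roi optional [enface_roi()] used for NOAC normalization.
#' @param depths_um optional increasing vector of evaluation depths (um
#'   below the surface); `NULL` lets [nad_volume()] choose every window
#'   start down to the deepest depth with at least half the pixels unmasked.
#' @param average_domain domain in which neighbouring A-lines are averaged
#'   before the fit: `"log"` (default) averages the log-compressed B-scan
#'   (geometric mean), which keeps the slope estimator linear in the
#'   averaged quantity and boundary transitions laterally symmetric;
#'   `"linear"` averages raw intensities, in which case the log of the
#'   averaged two-region mixture is dominated by the slower decay and
#'   margins smear outward with depth.
#' @param refractive_index group refractive index used only to convert an
#'   air-path axial spacing to in-tissue spacing at load time (default 1).
#' @param surface_presmooth_px axial box-smoothing width for
#'   [detect_surface()] (default 3; 1 disables, which makes detection exact
#'   on noiseless data).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(lateral_avg_width = 21L,
                            fit_window_px = 40L,
                            lowpass_sigma_px = 2,
                            roi = NULL,
                            depths_um = NULL,
                            average_domain = c("log", "linear"),
                            refractive_index = 1,
                            surface_presmooth_px = 3L) {
  average_domain <- match.arg(average_domain)
  if (fit_window_px < 3) stop_validation("`fit_window_px` must be >= 3")
  if (lateral_avg_width < 1) stop_validation("`lateral_avg_width` must be >= 1")
  if (lowpass_sigma_px < 0) stop_validation("`lowpass_sigma_px` must be >= 0")
  if (refractive_index <= 0) stop_validation("`refractive_index` must be > 0")
  if (surface_presmooth_px < 1) stop_validation("`surface_presmooth_px` must be >= 1")
  if (!is.null(depths_um)) {
    if (any(depths_um < 0)) stop_validation("`depths_um` must be non-negative")
    if (is.unsorted(depths_um, strictly = TRUE))
      stop_validation("`depths_um` must be strictly increasing")
  }
  if (!is.null(roi) && !inherits(roi, "enface_roi"))
    stop_validation("`roi` must be built with enface_roi()")
  structure(list(lateral_avg_width = as.integer(lateral_avg_width),
                 fit_window_px = as.integer(fit_window_px),
                 lowpass_sigma_px = as.numeric(lowpass_sigma_px),
                 roi = roi,
                 depths_um = depths_um,
                 average_domain = average_domain,
                 refractive_index = as.numeric(refractive_index),
                 surface_presmooth_px = as.integer(surface_presmooth_px)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Missing fields fall back to the [pipeline_config()] defaults; every
#' applied default is reported with a message.  The ROI may be given as a
#' mapping with keys `x0, x1, y0, y1`.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file; an empty file
#'   yields the full default configuration.
#' @return A validated `pipeline_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_validation("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    if (file.size(path) == 0) NULL else jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop_validation("config root must be a mapping")
  known <- names(formals(pipeline_config))
  extra <- setdiff(names(raw), known)
  if (length(extra))
    stop_validation("unknown config field(s): ", paste(extra, collapse = ", "))
  if (!is.null(raw$roi)) {
    r <- raw$roi
    need <- c("x0", "x1", "y0", "y1")
    if (!all(need %in% names(r)))
      stop_validation("config field `roi` must provide x0, x1, y0, y1")
    raw$roi <- enface_roi(r$x0, r$x1, r$y0, r$y1)
  }
  for (f in setdiff(known, names(raw))) {
    def <- formals(pipeline_config)[[f]]
    defval <- if (is.call(def) || is.name(def)) eval(def) else def
    if (length(defval) > 1) defval <- defval[1]  # match.arg choices
    message(sprintf("load_config: using default %s = %s", f,
                    paste(format(defval), collapse = ",")))
  }
  do.call(pipeline_config, raw)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat(sprintf("  lateral_avg_width: %d A-lines\n", x$lateral_avg_width))
  cat(sprintf("  fit_window_px: %d\n", x$fit_window_px))
  cat(sprintf("  lowpass_sigma_px: %g\n", x$lowpass_sigma_px))
  cat(sprintf("  average_domain: %s\n", x$average_domain))
  cat(sprintf("  surface_presmooth_px: %d\n", x$surface_presmooth_px))
  cat(sprintf("  refractive_index: %g\n", x$refractive_index))
  if (!is.null(x$roi))
    cat(sprintf("  roi: [%d:%d, %d:%d]\n", x$roi$x0, x$roi$x1, x$roi$y0, x$roi$y1))
  if (!is.null(x$depths_um))
    cat(sprintf("  depths_um: %s\n", paste(format(x$depths_um), collapse = ", ")))
  invisible(x)
}
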