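#' 2D intensity image with physical pixel size
#'
#' Light-weight container for a single-channel microscopy image. Pixels are
#' stored as a numeric matrix indexed `[y, x]` (row = y, column = x, origin
#' top-left); `pixel_size` is the isotropic in-plane sampling in micrometres.
#' Every correction applied by the package appends an entry to the
#' `provenance` list, so a processed image carries its own audit trail.
#'
#' @param pixels numeric matrix of finite, non-negative intensities
#' @param pixel_size micrometres per pixel (> 0)
#' @param provenance optional list of processing-step records
#' @return an object of class `image2d`
#' @export
image2d <- function(pixels, pixel_size = 1, provenance = list()) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (!all(is.finite(pixels)))
    stop("image2d: all intensities must be finite")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0)
    stop("image2d: pixel_size must be a single positive number")
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 provenance = provenance),
            class = "image2d")
}

#' @export
print.image2d <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<image2d> %d x %d px (%.3g x %.3g um), range [%.4g, %.4g]\n",
              d[1], d[2], d[1] * x$pixel_size, d[2] * x$pixel_size,
              min(x$pixels), max(x$pixels)))
  if (length(x$provenance))
    cat("  processing:", paste(vapply(x$provenance, `[[`, "", "step"),
                               collapse = " -> "), "\n")
  invisible(x)
}

#' @export
dim.image2d <- function(x) dim(x$pixels)

#' 3D intensity stack with physical voxel size
#'
#' Container for a confocal z-stack. Voxels are stored as a 3D numeric array
#' in `(z, y, x)` order; `voxel_size` is `c(dz, dy, dx)` in micrometres.
#' Confocal sampling is typically anisotropic (the reference acquisition here
#' is dz = 0.25 um against 0.1 um in-plane), so all geometric computations
#' downstream work in physical micrometres, never in voxel counts.
#'
#' @param voxels 3D numeric array, `(z, y, x)` order, finite and >= 0
#' @param voxel_size numeric `c(dz, dy, dx)` in micrometres, all > 0
#' @param provenance optional list of processing-step records
#' @return an object of class `voxel_grid`
#' @export
voxel_grid <- function(voxels, voxel_size, provenance = list()) {
  if (length(dim(voxels)) != 3)
    stop("voxel_grid: voxels must be a 3D array (z, y, x)")
  storage.mode(voxels) <- "double"
  if (!all(is.finite(voxels)))
    stop("voxel_grid: all intensities must be finite")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3 || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("voxel_grid: voxel_size must be positive c(dz, dy, dx)")
  structure(list(voxels = voxels, voxel_size = voxel_size,
                 provenance = provenance),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<voxel_grid> %d z x %d y x %d x voxels, voxel %.3g x %.3g x %.3g um\n",
    d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat(sprintf("  field: %.1f x %.1f x %.1f um, range [%.4g, %.4g]\n",
              d[1] * x$voxel_size[1], d[2] * x$voxel_size[2],
              d[3] * x$voxel_size[3], min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) dim(x$voxels)

#' Label map of segmented objects
#'
#' Integer labels congruent with the source image (2D) or stack (3D);
#' 0 is background, objects are numbered 1..k contiguously. `scale` inherits
#' the physical sampling of the source (`pixel_size` or `voxel_size`).
#' `flags` (filled by [filter_objects()]) records per-object QC flags;
#' `meta` carries segmentation diagnostics (seed counts per pre-split
#' component) used for merge-resolution QC.
#'
#' @param labels integer matrix (2D) or array (3D)
#' @param scale physical sampling: scalar (2D) or `c(dz, dy, dx)` (3D)
#' @param flags optional data.frame of per-object flags
#' @param meta optional list of segmentation diagnostics
#' @return an object of class `label_map`
#' @export
label_map <- function(labels, scale, flags = NULL, meta = list()) {
  storage.mode(labels) <- "integer"
  if (any(labels < 0)) stop("label_map: labels must be >= 0")
  structure(list(labels = labels, scale = as.numeric(scale),
                 flags = flags, meta = meta),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  k <- max(x$labels)
  cat(sprintf("<label_map> %s, %d object%s\n",
              paste(dim(x$labels), collapse = " x "), k,
              if (k == 1) "" else "s"))
  if (!is.null(x$flags) && nrow(x$flags)) {
    cat(sprintf("  flagged: %d border_touching, %d unresolved_merge\n",
                sum(x$flags$border_touching), sum(x$flags$unresolved_merge)))
  }
  invisible(x)
}

#' Number of objects in a label map
#' @param x a [label_map()]
#' @return integer count of distinct non-zero labels
#' @export
n_objects <- function(x) {
  stopifnot(inherits(x, "label_map"))
  length(setdiff(unique(as.vector(x$labels)), 0L))
}

#' Background specification for subtraction
#'
#' Three modes: `region` (mean of a user-supplied cell-free rectangle, the
#' default for fluorescence images), `constant` (a fixed value), and
#' `rolling_ball` (morphological background for gel images).
#'
#' @param mode one of `"region"`, `"constant"`, `"rolling_ball"`
#' @param region rectangle `c(x0, y0, width, height)` in 0-based pixel units
#'   (mode `region`)
#' @param value constant background (mode `constant`, >= 0)
#' @param radius structuring-element radius in pixels (mode `rolling_ball`)
#' @return an object of class `background_spec`
#' @export
background_spec <- function(mode = c("region", "constant", "rolling_ball"),
                            region = NULL, value = NULL, radius = NULL) {
  mode <- match.arg(mode)
  if (mode == "region") {
    if (is.null(region) || length(region) != 4)
      stop("background_spec: region mode needs c(x0, y0, width, height)")
    if (region[3] <= 0 || region[4] <= 0)
      stop("background_spec: empty background region")
  }
  if (mode == "constant") {
    if (is.null(value) || value < 0)
      stop("background_spec: constant mode needs value >= 0")
  }
  if (mode == "rolling_ball") {
    if (is.null(radius) || radius <= 0)
      stop("background_spec: rolling_ball mode needs radius > 0")
  }
  structure(list(mode = mode, region = region, value = value,
                 radius = radius), class = "background_spec")
}

# append a processing record; shared by every correction step
add_provenance <- function(obj, step, params) {
  obj$provenance <- c(obj$provenance,
                      list(list(step = step, params = params)))
  obj
}

#' Write a provenance log as JSON lines
#'
#' One JSON object per processing step, in application order.
#'
#' @param obj an `image2d` or `voxel_grid` with processing history
#' @param path output file
#' @return the path, invisibly
#' @export
write_provenance <- function(obj, path) {
  lines <- vapply(obj$provenance, function(p)
    jsonlite::toJSON(p, auto_unbox = TRUE), "")
  writeLines(lines, path)
  invisible(path)
}
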