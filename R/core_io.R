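#' Read a confocal z-stack from a multi-page TIFF
#'
#' Pages become z-planes in `(z, y, x)` order. The voxel size is mandatory:
#' volumes are meaningless without it. It may come from the arguments, from a
#' YAML config file (keys `dz`, `dxy` or `dz`, `dy`, `dx`), or from TIFF
#' resolution tags (in-plane only, and only when the tag unit is resolvable);
#' explicit arguments win.
#'
#' @param path multi-page single-channel grayscale TIFF
#' @param dz,dxy z-step and in-plane pixel size in micrometres
#' @param voxel_size alternative `c(dz, dy, dx)` in micrometres
#' @param config optional YAML file supplying the voxel size
#' @return a [voxel_grid()]
#' @export
read_stack <- function(path, dz = NULL, dxy = NULL, voxel_size = NULL,
                       config = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) > 2, TRUE)))
    stop("read_stack: expected single-channel grayscale TIFF ",
         "(got a multi-sample page)")
  if (!is.null(config)) {
    cfg <- yaml::read_yaml(config)
    if (is.null(voxel_size) && !is.null(cfg$dz)) {
      if (!is.null(cfg$dxy)) voxel_size <- c(cfg$dz, cfg$dxy, cfg$dxy)
      else if (!is.null(cfg$dy) && !is.null(cfg$dx))
        voxel_size <- c(cfg$dz, cfg$dy, cfg$dx)
    }
  }
  if (!is.null(dz) && !is.null(dxy)) voxel_size <- c(dz, dxy, dxy)
  if (is.null(voxel_size))
    stop("read_stack: voxel size is required (supply dz/dxy, voxel_size, ",
         "or a config file); volumes are meaningless without it")
  if (length(pages) == 1)
    warning("read_stack: single-page TIFF; treating as a stack of depth 1")
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  arr <- array(0, c(length(pages), ny, nx))
  for (z in seq_along(pages)) {
    if (!identical(dim(pages[[z]]), c(ny, nx)))
      stop("read_stack: pages have inconsistent dimensions")
    arr[z, , ] <- pages[[z]]
  }
  voxel_grid(arr, voxel_size,
             provenance = list(list(step = "read_stack",
                                    params = list(path = path,
                                                  voxel_size = voxel_size))))
}

#' Write an image or stack as a 16-bit grayscale TIFF
#'
#' Intensities are stored scaled to the image maximum over the full 16-bit
#' range; every quantitative step downstream (thresholds, ratios,
#' normalized profiles) is invariant to this global gain. The scale factor
#' is returned invisibly.
#'
#' @param obj an `image2d` or `voxel_grid`
#' @param path output TIFF path
#' @return invisibly, the intensity scale factor that was divided out
#' @export
write_image <- function(obj, path) {
  px <- if (inherits(obj, "image2d")) obj$pixels
        else if (inherits(obj, "voxel_grid")) obj$voxels
        else stop("write_image: need an image2d or voxel_grid")
  sc <- max(px, 1e-12)
  if (inherits(obj, "image2d")) {
    tiff::writeTIFF(px / sc, path, bits.per.sample = 16L)
  } else {
    pages <- lapply(seq_len(dim(px)[1]), function(z) px[z, , ] / sc)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  }
  invisible(sc)
}

# resolve a background_spec against an image matrix -> scalar or matrix
resolve_background <- function(px, bg) {
  switch(bg$mode,
    constant = bg$value,
    region = {
      x0 <- bg$region[1]; y0 <- bg$region[2]
      w <- bg$region[3]; h <- bg$region[4]
      rows <- (y0 + 1):(y0 + h); cols <- (x0 + 1):(x0 + w)
      if (min(rows) < 1 || max(rows) > nrow(px) ||
          min(cols) < 1 || max(cols) > ncol(px))
        stop("background region lies outside the image")
      mean(px[rows, cols])
    },
    rolling_ball = {
      brush <- EBImage::makeBrush(2 * ceiling(bg$radius) + 1, shape = "disc")
      EBImage::opening(px, brush)
    })
}

#' Subtract background from an image
#'
#' Resolves the [background_spec()] to a scalar (cell-free region mean or a
#' constant) or a smooth field (rolling ball), subtracts it, and by default
#' clamps at zero so no negative intensities are produced. Quantitative
#' ratio pipelines set `clamp = FALSE`: clamping rectifies the noise in dim
#' pixels and would bias downstream least-squares slopes, whereas
#' zero-mean residual noise does not. The resolved background and the
#' clamping choice are recorded in the image's provenance.
#'
#' @param img an [image2d()]
#' @param bg a [background_spec()]
#' @param clamp clamp negative results to zero (default TRUE)
#' @return background-subtracted `image2d`
#' @export
subtract_background <- function(img, bg, clamp = TRUE) {
  stopifnot(inherits(img, "image2d"), inherits(bg, "background_spec"))
  b <- resolve_background(img$pixels, bg)
  out <- img
  net <- img$pixels - b
  out$pixels <- if (clamp) pmax(net, 0) else net
  add_provenance(out, "subtract_background",
                 list(mode = bg$mode, clamp = clamp,
                      background = if (is.matrix(b)) mean(b) else b))
}

# quadratic illumination surface estimate shared by correct_illumination
# and prepare_fret
illum_surface <- function(px) {
  if (nrow(px) < 16 || ncol(px) < 16)
    stop("correct_illumination: image too small to fit a surface (< 16x16)")
  ny <- nrow(px); nx <- ncol(px)
  yy <- (row(px) - 1) / (ny - 1) - 0.5
  xx <- (col(px) - 1) / (nx - 1) - 0.5
  X <- cbind(1, as.vector(xx), as.vector(yy), as.vector(xx)^2,
             as.vector(yy)^2, as.vector(xx * yy))
  v <- as.vector(px)
  thr <- otsu_global(v)
  fg <- which(v > thr)
  use_fg <- length(fg) >= max(500, 0.002 * length(v)) &&
    length(fg) <= 0.95 * length(v)
  fit <- if (use_fg) lm.fit(X[fg, , drop = FALSE], v[fg]) else lm.fit(X, v)
  surf <- matrix(X %*% fit$coefficients, ny, nx)
  if (!all(is.finite(surf)))
    stop("correct_illumination: degenerate surface fit")
  surf <- surf / mean(surf)
  list(surface = pmax(surf, 0.05),
       fit_on = if (use_fg) "foreground" else "all")
}

correct_with_surface <- function(img, surf, fit_on, rescale = NULL) {
  corrected <- img$pixels / surf
  if (is.null(rescale)) {
    m <- mean(corrected)
    rescale <- if (m > 0) mean(img$pixels) / m else 1
  }
  img$pixels <- corrected * rescale
  add_provenance(img, "correct_illumination",
                 list(model = "quadratic_surface_division", fit_on = fit_on,
                      surface_range = range(surf)))
}

#' Correct a smooth illumination gradient
#'
#' Fits a low-order (quadratic) intensity surface
#' `a0 + a1 x + a2 y + a3 x^2 + a4 y^2 + a5 xy` by least squares, divides
#' it out, and rescales so the global mean is preserved. No flat-field
#' reference is assumed: the fitted surface is the illumination estimate.
#' In a sparse fluorescence scene only signal-bearing pixels express the
#' illumination profile (background is offset-free after subtraction), so
#' when the image has a clear foreground (above its Otsu split) the
#' surface is fitted to those pixels and evaluated everywhere; otherwise —
#' flat, empty or noise-only images — it is fitted to all pixels, which
#' leaves a flat image unchanged to numerical precision. The surface is
#' clamped below at 5% of its mean so extrapolation into empty corners
#' cannot blow up the division. Multi-channel pipelines
#' ([prepare_fret()]) estimate one surface from the strongest channel and
#' divide every channel by that same field, leaving inter-channel ratios
#' untouched.
#'
#' @param img an [image2d()], at least 16 x 16 pixels
#' @return gradient-corrected `image2d`
#' @export
correct_illumination <- function(img) {
  stopifnot(inherits(img, "image2d"))
  s <- illum_surface(img$pixels)
  correct_with_surface(img, s$surface, s$fit_on)
}

# bilinear translation by (dy, dx); pixels sampled outside become NA unless
# fill is given
translate_image <- function(px, dy, dx, fill = NA_real_) {
  ny <- nrow(px); nx <- ncol(px)
  ys <- row(px) + dy; xs <- col(px) + dx
  y0 <- floor(ys); x0 <- floor(xs)
  fy <- ys - y0; fx <- xs - x0
  get_px <- function(yi, xi) {
    ok <- yi >= 1 & yi <= ny & xi >= 1 & xi <= nx
    v <- matrix(fill, ny, nx)
    v[ok] <- px[cbind(yi[ok], xi[ok])]
    v
  }
  v00 <- get_px(y0, x0);     v01 <- get_px(y0, x0 + 1L)
  v10 <- get_px(y0 + 1L, x0); v11 <- get_px(y0 + 1L, x0 + 1L)
  (1 - fy) * (1 - fx) * v00 + (1 - fy) * fx * v01 +
    fy * (1 - fx) * v10 + fy * fx * v11
}

# shift estimation core shared by register_channels and prepare_fret:
# returns c(dy, dx) such that `moving` appears shifted by (dy, dx) relative
# to `reference`, plus a confidence flag
estimate_shift <- function(a, b) {
  ny <- nrow(a); nx <- ncol(a)
  fa <- fft(a - mean(a)); fb <- fft(b - mean(b))
  cc <- Re(fft(fa * Conj(fb), inverse = TRUE)) / length(a)
  peak <- which(cc == max(cc))[1]
  py <- (peak - 1) %% ny; px <- (peak - 1) %/% ny
  ccv <- as.vector(cc)
  conf <- (max(ccv) - median(ccv)) / (mad(ccv) + .Machine$double.eps)
  if (conf < 5)
    return(list(shift = c(dy = 0, dx = 0), confident = FALSE))
  para <- function(cm, c0, cp) {
    den <- cm - 2 * c0 + cp
    if (abs(den) < .Machine$double.eps) 0 else 0.5 * (cm - cp) / den
  }
  wrap <- function(i, n) ((i %% n) + n) %% n
  cyc <- function(y, x) cc[wrap(y, ny) + 1, wrap(x, nx) + 1]
  ry <- para(cyc(py - 1, px), cyc(py, px), cyc(py + 1, px))
  rx <- para(cyc(py, px - 1), cyc(py, px), cyc(py, px + 1))
  sy <- py + ry; sx <- px + rx
  if (sy > ny / 2) sy <- sy - ny
  if (sx > nx / 2) sx <- sx - nx
  list(shift = c(dy = -sy, dx = -sx), confident = TRUE)
}

#' Estimate and correct an inter-channel pixel shift
#'
#' The shift of `moving` relative to `reference` is estimated by the peak of
#' the FFT cross-correlation, refined to sub-pixel resolution by fitting a
#' parabola through the peak and its neighbours in each axis. The moving
#' image is then resampled onto the reference grid by bilinear
#' interpolation; pixels that sample outside the original frame are NA
#' (marked invalid rather than extrapolated). If the correlation peak is not
#' confidently above the correlation background, a warning is issued and a
#' zero shift applied.
#'
#' @param reference,moving same-shape [image2d()]s with overlapping content
#' @return list with `shift` (`c(dy, dx)` in pixels; `moving` appears shifted
#'   by this amount relative to `reference`) and `shifted` (the re-aligned
#'   moving image)
#' @export
register_channels <- function(reference, moving) {
  stopifnot(inherits(reference, "image2d"), inherits(moving, "image2d"))
  a <- reference$pixels; b <- moving$pixels
  if (!identical(dim(a), dim(b)))
    stop("register_channels: images must have the same shape")
  est <- estimate_shift(a, b)
  if (!est$confident) {
    warning("register_channels: correlation peak below confidence floor; ",
            "assuming zero shift")
    out <- add_provenance(moving, "register_channels",
                          list(shift = c(0, 0), confident = FALSE))
    return(list(shift = est$shift, shifted = out))
  }
  shift <- est$shift
  out <- moving
  out$pixels <- translate_image(b, shift[1], shift[2])
  out <- add_provenance(out, "register_channels",
                        list(shift = unname(shift), confident = TRUE))
  list(shift = shift, shifted = out)
}

# 3x3 uniform mean with replicate padding on a plain matrix
smooth3_mat <- function(px) {
  ny <- nrow(px); nx <- ncol(px)
  p <- rbind(px[1, , drop = FALSE], px, px[ny, , drop = FALSE])
  p <- cbind(p[, 1, drop = FALSE], p, p[, nx, drop = FALSE])
  acc <- matrix(0, ny, nx)
  for (dy in 0:2) for (dx in 0:2)
    acc <- acc + p[dy + seq_len(ny), dx + seq_len(nx)]
  acc / 9
}

#' Three-point smoothing
#'
#' One pass of a 3 x 3 uniform mean filter with replicate borders: the
#' minimal neighbourhood average consistent with "three-point" smoothing of
#' a 2D image. Exactly linear in intensity, so ratio quantities computed
#' after smoothing are unaffected by global gain.
#'
#' @param img an [image2d()]
#' @return smoothed `image2d`
#' @export
smooth3 <- function(img) {
  stopifnot(inherits(img, "image2d"))
  out <- img
  out$pixels <- smooth3_mat(img$pixels)
  add_provenance(out, "smooth3", list(kernel = "3x3 uniform"))
}

#' Read a rectangle list from a YAML annotation file
#'
#' Rectangles use keys `x0`, `y0`, `width`, `height` in 0-based pixel units.
#'
#' @param path YAML file with one rectangle or a named list of rectangles
#' @return a named list of `c(x0, y0, width, height)` vectors
#' @export
read_roi_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  as_rect <- function(r) {
    if (!all(c("x0", "y0", "width", "height") %in% names(r)))
      stop("ROI YAML entries need x0, y0, width, height")
    c(x0 = r$x0, y0 = r$y0, width = r$width, height = r$height)
  }
  if (all(c("x0", "y0", "width", "height") %in% names(cfg)))
    return(list(roi = as_rect(cfg)))
  lapply(cfg, as_rect)
}
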