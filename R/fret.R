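#' Three-channel FRET acquisition
#'
#' Bundles the donor, FRET (donor excitation / acceptor emission) and
#' acceptor channels of one sensitized-emission acquisition. The index can
#' only be computed once the channels have been taken through the
#' correction cascade ([prepare_fret()]); `registered` records that state.
#'
#' @param donor,fret,acceptor same-shape [image2d()]s
#' @param registered logical; has the correction cascade been applied?
#' @return an object of class `fret_acquisition`
#' @export
fret_acquisition <- function(donor, fret, acceptor, registered = FALSE) {
  stopifnot(inherits(donor, "image2d"), inherits(fret, "image2d"),
            inherits(acceptor, "image2d"))
  if (!identical(dim(donor$pixels), dim(fret$pixels)) ||
      !identical(dim(donor$pixels), dim(acceptor$pixels)))
    stop("fret_acquisition: the three channels must have the same shape")
  structure(list(donor = donor, fret = fret, acceptor = acceptor,
                 registered = registered),
            class = "fret_acquisition")
}

#' @export
print.fret_acquisition <- function(x, ...) {
  cat(sprintf("<fret_acquisition> %d x %d px, %s\n", nrow(x$donor$pixels),
              ncol(x$donor$pixels),
              if (x$registered) "corrected/registered" else "raw"))
  invisible(x)
}

#' Apply the correction cascade to a FRET acquisition
#'
#' In order: per-channel background subtraction, illumination-gradient
#' correction, pixel-shift correction (FRET and acceptor channels
#' registered onto the donor), then three-point smoothing. Each step is
#' recorded in the channels' provenance. Steps can be disabled for
#' diagnostic runs.
#'
#' @param acq a [fret_acquisition()]
#' @param background a single [background_spec()] or a list with elements
#'   `donor`, `fret`, `acceptor`
#' @param illumination,register,smooth logical switches for the
#'   corresponding steps
#' @return a corrected `fret_acquisition` with `registered = TRUE`
#' @export
prepare_fret <- function(acq, background = NULL, illumination = TRUE,
                         register = TRUE, smooth = TRUE) {
  stopifnot(inherits(acq, "fret_acquisition"))
  chans <- list(donor = acq$donor, fret = acq$fret, acceptor = acq$acceptor)
  if (!is.null(background)) {
    bgs <- if (inherits(background, "background_spec"))
      list(donor = background, fret = background, acceptor = background)
    else background
    for (ch in names(chans))
      chans[[ch]] <- subtract_background(chans[[ch]], bgs[[ch]],
                                         clamp = FALSE)
  }
  if (illumination) {
    # one shared surface, estimated from the brightest channel and applied
    # to all three with a common rescale: a shared multiplicative field
    # cancels from the index and from calibration slopes, so the
    # correction cannot distort inter-channel relations
    totals <- vapply(chans, function(ch) sum(ch$pixels), 0)
    ref <- chans[[which.max(totals)]]
    s <- illum_surface(ref$pixels)
    m <- mean(ref$pixels / s$surface)
    rescale <- if (m > 0) mean(ref$pixels) / m else 1
    chans <- lapply(chans, correct_with_surface, surf = s$surface,
                    fit_on = s$fit_on, rescale = rescale)
  }
  if (register) {
    # The FRET and acceptor channels share the camera-path shift relative
    # to the donor. Applying the full shift to the movers alone would blur
    # them by the interpolation kernel while leaving the donor sharp,
    # biasing pixel-wise slopes low; instead all three channels are
    # resampled half-way (donor by -s/2, movers by s_ch - s/2), so every
    # channel receives the same interpolation smoothing and they land on a
    # common grid.
    ests <- lapply(chans[c("fret", "acceptor")], function(ch)
      estimate_shift(chans$donor$pixels, ch$pixels))
    confident <- vapply(ests, `[[`, TRUE, "confident")
    s_mean <- if (any(confident))
      rowMeans(vapply(ests[confident], `[[`, numeric(2), "shift"))
    else c(0, 0)
    resample <- function(img, dy, dx, step) {
      px <- translate_image(img$pixels, dy, dx, fill = NA_real_)
      px[!is.finite(px)] <- 0  # edge pixels invalidated by resampling
      img$pixels <- px
      add_provenance(img, "register_channels",
                     list(shift = c(dy, dx), scheme = step))
    }
    chans$donor <- resample(chans$donor, -s_mean[1] / 2, -s_mean[2] / 2,
                            "symmetric_half_shift")
    for (ch in c("fret", "acceptor")) {
      s_ch <- if (ests[[ch]]$confident) ests[[ch]]$shift else s_mean
      chans[[ch]] <- resample(chans[[ch]], s_ch[1] - s_mean[1] / 2,
                              s_ch[2] - s_mean[2] / 2,
                              "symmetric_half_shift")
    }
  }
  if (smooth)
    chans <- lapply(chans, smooth3)
  fret_acquisition(chans$donor, chans$fret, chans$acceptor,
                   registered = TRUE)
}

# slope of fret ~ regressor over foreground pixels; optionally Theil-Sen.
# The reported r2 is computed on a quantile-binned mean profile rather than
# the raw pixel scatter: per-pixel noise deflates scatter r2 even when the
# calibration relation is perfectly linear, whereas the binned profile
# isolates the systematic relation the slope relies on.
fit_slope <- function(reg_px, fret_px, noise_floor, robust) {
  sel <- which(reg_px > noise_floor)
  n <- length(sel)
  if (n < 1000)
    stop("bleed-through calibration needs >= 1000 foreground pixels (got ",
         n, ")")
  xv <- reg_px[sel]; yv <- fret_px[sel]
  fit <- lm(yv ~ xv)
  slope <- unname(coef(fit)[2])
  # errors-in-variables correction: pixel noise in the regressor channel
  # attenuates the least-squares slope by s_x^2 / (s_x^2 + var_noise);
  # the noise variance is estimated from sub-floor (background) pixels of
  # the same processed channel and divided back out
  bgv <- reg_px[reg_px <= noise_floor]
  var_n <- if (length(bgv) > 100) mad(bgv)^2 else 0
  sx2 <- var(xv)
  if (is.finite(var_n) && var_n > 0 && var_n < 0.5 * sx2)
    slope <- slope * sx2 / (sx2 - var_n)
  intercept <- mean(yv) - slope * mean(xv)
  nb <- 20
  qs <- unique(quantile(xv, probs = seq(0, 1, length.out = nb + 1)))
  r2 <- if (length(qs) > 3) {
    bin <- cut(xv, qs, include.lowest = TRUE)
    bx <- tapply(xv, bin, mean); by <- tapply(yv, bin, mean)
    pred <- intercept + slope * bx
    ssr <- sum((by - pred)^2); sst <- sum((by - mean(by))^2)
    if (sst <= .Machine$double.eps) 1 else max(0, 1 - ssr / sst)
  } else summary(fit)$r.squared
  if (robust) {
    # Theil-Sen over a bounded random subsample of pixel pairs
    m <- min(n, 500L)
    ii <- sel[round(seq(1, n, length.out = m))]
    xs <- reg_px[ii]; ys <- fret_px[ii]
    dx <- outer(xs, xs, "-"); dyv <- outer(ys, ys, "-")
    ok <- upper.tri(dx) & abs(dx) > .Machine$double.eps
    slope <- median(dyv[ok] / dx[ok])
    intercept <- median(ys - slope * xs)
  }
  list(slope = slope, intercept = intercept, r2 = r2, n = n)
}

# default foreground floor: Otsu split of the regressor channel
default_floor <- function(px) otsu_global(as.vector(px))

#' Calibrate donor leakage from a donor-only sample
#'
#' On a background-subtracted acquisition of cells expressing only the
#' donor fluorophore, any FRET-channel signal is donor emission leaking
#' through the acceptor emission filter. The leakage fraction `x` is the
#' slope of the pixel-wise least-squares fit of FRET-channel against
#' donor-channel intensity over foreground pixels (donor above
#' `noise_floor`), with a free intercept reported as a diagnostic.
#'
#' @param donor_only a [fret_acquisition()] of a donor-only sample, taken
#'   through [prepare_fret()] (no registration target issues arise because
#'   calibration uses pixel-wise regression)
#' @param noise_floor intensity above which a donor pixel counts as
#'   foreground; default: Otsu threshold of the donor channel
#' @param robust use a Theil-Sen slope (outlier-heavy samples)
#' @return a `bleedthrough_calibration` with the `x` slot filled
#' @export
fit_bleedthrough <- function(donor_only, noise_floor = NULL,
                             robust = FALSE) {
  stopifnot(inherits(donor_only, "fret_acquisition"))
  if (is.null(noise_floor)) noise_floor <- default_floor(donor_only$donor$pixels)
  f <- fit_slope(donor_only$donor$pixels, donor_only$fret$pixels,
                 noise_floor, robust)
  if (f$r2 < 0.5)
    stop("fit_bleedthrough: calibration sample unsuitable (r2 = ",
         signif(f$r2, 3), ")")
  structure(list(x = max(f$slope, 0), y = NA_real_,
                 n_pixels = f$n, r2 = f$r2, intercept = f$intercept,
                 robust = robust),
            class = "bleedthrough_calibration")
}

#' Calibrate acceptor cross-excitation from an acceptor-only sample
#'
#' Mirror of [fit_bleedthrough()]: on an acceptor-only sample, FRET-channel
#' signal is acceptor fluorescence excited directly by the donor
#' excitation line; the cross-excitation fraction `y` is the slope of
#' FRET-channel vs acceptor-channel intensity. A warning is raised when the
#' sample's donor channel carries appreciable signal (it should not, for a
#' pure acceptor-only sample).
#'
#' @inheritParams fit_bleedthrough
#' @param acceptor_only a [fret_acquisition()] of an acceptor-only sample
#' @return a `bleedthrough_calibration` with the `y` slot filled
#' @export
fit_crossexcitation <- function(acceptor_only, noise_floor = NULL,
                                robust = FALSE) {
  stopifnot(inherits(acceptor_only, "fret_acquisition"))
  if (is.null(noise_floor))
    noise_floor <- default_floor(acceptor_only$acceptor$pixels)
  apx <- acceptor_only$acceptor$pixels
  dpx <- acceptor_only$donor$pixels
  fg <- apx > noise_floor
  if (any(fg) && mean(dpx[fg]) > 0.05 * mean(apx[fg]))
    warning("fit_crossexcitation: donor channel of the acceptor-only ",
            "sample is not negligible; sample may be contaminated")
  f <- fit_slope(apx, acceptor_only$fret$pixels, noise_floor, robust)
  if (f$r2 < 0.5)
    stop("fit_crossexcitation: calibration sample unsuitable (r2 = ",
         signif(f$r2, 3), ")")
  structure(list(x = NA_real_, y = max(f$slope, 0),
                 n_pixels = f$n, r2 = f$r2, intercept = f$intercept,
                 robust = robust),
            class = "bleedthrough_calibration")
}

#' Merge donor-leakage and cross-excitation calibrations
#'
#' @param x_cal result of [fit_bleedthrough()]
#' @param y_cal result of [fit_crossexcitation()]
#' @return a complete `bleedthrough_calibration`
#' @export
combine_calibration <- function(x_cal, y_cal) {
  stopifnot(inherits(x_cal, "bleedthrough_calibration"),
            inherits(y_cal, "bleedthrough_calibration"))
  structure(list(x = x_cal$x, y = y_cal$y,
                 n_pixels = min(x_cal$n_pixels, y_cal$n_pixels),
                 r2 = min(x_cal$r2, y_cal$r2),
                 intercept = c(x = x_cal$intercept, y = y_cal$intercept),
                 robust = x_cal$robust || y_cal$robust),
            class = "bleedthrough_calibration")
}

#' @export
print.bleedthrough_calibration <- function(x, ...) {
  cat("<bleedthrough_calibration>\n")
  cat(sprintf("  donor leakage x       : %s\n",
              if (is.na(x$x)) "-" else sprintf("%.4f", x$x)))
  cat(sprintf("  cross-excitation y    : %s\n",
              if (is.na(x$y)) "-" else sprintf("%.4f", x$y)))
  cat(sprintf("  pixels used           : %d (r2 = %.3f%s)\n", x$n_pixels,
              x$r2, if (x$robust) ", Theil-Sen" else ""))
  invisible(x)
}

#' @export
coef.bleedthrough_calibration <- function(object, ...)
  c(x = object$x, y = object$y)

#' Per-pixel sensitized-emission FRET index map
#'
#' Computes `(F - x*D - y*A) / A` per pixel: the acceptor emission under
#' donor excitation, stripped of donor leakage and direct acceptor
#' excitation, normalized by acceptor intensity. This is a sensitized-
#' emission index, not FRET efficiency. The ratio is unstable where the
#' acceptor is dim, so pixels with `A` at or below `acceptor_floor`
#' (default 3x the background SD of the acceptor channel) are undefined
#' (NA), not zero. The index is exactly invariant to global intensity
#' scaling of all three channels.
#'
#' @param acq a corrected, registered [fret_acquisition()]
#' @param cal a complete `bleedthrough_calibration` (both `x` and `y`)
#' @param acceptor_floor acceptor intensity below which the index is
#'   undefined; default `3 * bg_sd`
#' @param bg_sd background standard deviation of the acceptor channel;
#'   default: robust SD (mad) of sub-Otsu acceptor pixels
#' @return an object of class `fret_result` with `index_map` (matrix, NA
#'   where undefined), `acceptor_floor`, and the calibration used
#' @export
fret_index_map <- function(acq, cal, acceptor_floor = NULL, bg_sd = NULL) {
  stopifnot(inherits(acq, "fret_acquisition"))
  if (!acq$registered)
    stop("fret_index_map: acquisition has not been corrected/registered; ",
         "run prepare_fret() first")
  if (!inherits(cal, "bleedthrough_calibration") || is.na(cal$x) ||
      is.na(cal$y))
    stop("fret_index_map: need a complete calibration (both x and y)")
  A <- acq$acceptor$pixels
  if (is.null(acceptor_floor)) {
    if (is.null(bg_sd)) {
      thr <- otsu_global(as.vector(A))
      bgpx <- A[A <= thr]
      bg_sd <- if (length(bgpx) > 10) max(mad(bgpx), sd(bgpx) / 2) else 0
    }
    acceptor_floor <- 3 * bg_sd
  }
  idx <- (acq$fret$pixels - cal$x * acq$donor$pixels - cal$y * A) / A
  idx[A <= acceptor_floor] <- NA_real_
  structure(list(index_map = idx, acceptor_floor = acceptor_floor,
                 calibration = cal),
            class = "fret_result")
}

#' @export
print.fret_result <- function(x, ...) {
  ok <- is.finite(x$index_map)
  cat(sprintf(
    "<fret_result> %d x %d px, %.1f%% defined, mean index %.4f\n",
    nrow(x$index_map), ncol(x$index_map), 100 * mean(ok),
    mean(x$index_map[ok])))
  invisible(x)
}

#' Mean FRET index per cell
#'
#' Averages the index map over each labelled mask region, using only
#' defined pixels (acceptor above floor). Masks are typically drawn around
#' the nucleus where the envelope tension sensor resides; they may come
#' from a file or from [perinuclear_masks()]. Cells with fewer than
#' `min_pixels` defined pixels are dropped with a warning.
#'
#' @param result a `fret_result`
#' @param masks a [label_map()] or integer matrix of cell masks (0 =
#'   outside)
#' @param min_pixels minimum defined pixels per cell (default 50)
#' @return data.frame with `cell`, `mean_index`, `n_pixels`
#' @export
mean_fret_per_cell <- function(result, masks, min_pixels = 50) {
  stopifnot(inherits(result, "fret_result"))
  lab <- if (inherits(masks, "label_map")) masks$labels else masks
  if (!identical(dim(lab), dim(result$index_map)))
    stop("mean_fret_per_cell: masks and index map are not congruent")
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  rows <- lapply(ids, function(i) {
    v <- result$index_map[lab == i]
    v <- v[is.finite(v)]
    data.frame(cell = i, mean_index = mean(v), n_pixels = length(v))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(cell = integer(0), mean_index = numeric(0),
                      n_pixels = integer(0)))
  drop <- out$n_pixels < min_pixels
  if (any(drop)) {
    warning(sprintf(
      "mean_fret_per_cell: dropping %d cell(s) with < %d defined pixels",
      sum(drop), min_pixels))
    out <- out[!drop, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Compare per-cell FRET indices between two groups
#'
#' Two-tailed unpaired Student's t-test on per-cell mean indices (e.g.
#' tension sensor vs headless control).
#'
#' @param a,b numeric vectors or data.frames from [mean_fret_per_cell()]
#' @return an `htest`
#' @export
compare_fret_groups <- function(a, b) {
  va <- if (is.data.frame(a)) a$mean_index else a
  vb <- if (is.data.frame(b)) b$mean_index else b
  t.test(va, vb, var.equal = TRUE)
}

#' Perinuclear ring masks from a nuclear segmentation
#'
#' Builds a morphological ring between `r_inner` and `r_outer` micrometres
#' outside each segmented nucleus — the region where nuclear-envelope
#' sensor signal concentrates. Rings of different cells do not overlap
#' (disputed pixels resolve to the higher label). Manual masks always
#' take precedence over this automatic derivation.
#'
#' @param nuclei a 2D [label_map()] of nuclei
#' @param r_inner,r_outer ring radii in micrometres (defaults 0.5 and 1.5)
#' @return a [label_map()] of ring masks with the same labels
#' @export
perinuclear_masks <- function(nuclei, r_inner = 0.5, r_outer = 1.5) {
  stopifnot(inherits(nuclei, "label_map"))
  ps <- nuclei$scale[1]
  lab <- nuclei$labels
  k <- max(lab)
  if (k == 0) return(nuclei)
  brush <- function(r_um) {
    d <- 2L * as.integer(ceiling(r_um / ps)) + 1L
    EBImage::makeBrush(d, shape = "disc")
  }
  grown_out <- EBImage::dilate(lab, brush(r_outer))
  grown_in <- EBImage::dilate(lab, brush(r_inner))
  ring <- grown_out
  ring[grown_in > 0] <- 0L
  label_map(ring, ps)
}
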