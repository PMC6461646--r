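#' Extract and normalize a gel lane intensity profile
#'
#' The raw profile is the per-row mean across the lane width (migration
#' axis vertical, increasing downward from the well). Background is, by
#' default, the per-row mean of two flanking inter-lane strips; a rolling-
#' ball or constant background is available instead. The profile is then
#' normalized as `I = (I_n - I_b) / I_total` with
#' `I_total = sum(I_n - I_b)`, so the normalized lane is a unit-mass
#' distribution over migration position and is invariant to exposure
#' (multiplicative gain) changes. Negative background-subtracted values are
#' clipped to zero before summation; the clipped mass fraction is reported.
#'
#' @param gel an [image2d()] of the gel (bands bright)
#' @param lane rectangle `c(x0, y0, width, height)`, 0-based pixel units
#' @param background `"flank"` (default), a [background_spec()], or a
#'   single number
#' @param flank_width width in px of each flanking strip (mode `"flank"`)
#' @param flank_gap gap in px between lane edge and strip
#' @return an object of class `lane_profile` with `positions` (px from
#'   lane top), `raw`, `background`, `normalized`, `i_total`,
#'   `clipped_fraction`
#' @export
extract_lane_profile <- function(gel, lane, background = "flank",
                                 flank_width = 4, flank_gap = 2) {
  stopifnot(inherits(gel, "image2d"))
  px <- gel$pixels
  if (length(lane) != 4 || lane[3] <= 0 || lane[4] <= 0)
    stop("extract_lane_profile: lane must be c(x0, y0, width, height)")
  x0 <- lane[1]; y0 <- lane[2]; w <- lane[3]; h <- lane[4]
  if (x0 < 0 || y0 < 0 || x0 + w > ncol(px) || y0 + h > nrow(px))
    stop("extract_lane_profile: lane rectangle outside the image")
  rows <- (y0 + 1):(y0 + h)
  cols <- (x0 + 1):(x0 + w)
  raw <- rowMeans(px[rows, cols, drop = FALSE])
  bg <- if (identical(background, "flank")) {
    strip <- function(c0, c1) {
      c0 <- max(1, c0); c1 <- min(ncol(px), c1)
      if (c1 < c0) return(NULL)
      px[rows, c0:c1, drop = FALSE]
    }
    left <- strip(x0 - flank_gap - flank_width + 1, x0 - flank_gap)
    right <- strip(x0 + w + 1 + flank_gap, x0 + w + flank_gap + flank_width)
    both <- cbind(left, right)
    if (is.null(both))
      stop("extract_lane_profile: no room for flanking background strips")
    rowMeans(both)
  } else if (inherits(background, "background_spec")) {
    b <- resolve_background(px, background)
    if (is.matrix(b)) rowMeans(b[rows, cols, drop = FALSE]) else b
  } else if (is.numeric(background) && length(background) == 1) {
    background
  } else stop("extract_lane_profile: unrecognized background")
  net <- raw - bg
  clipped <- sum(pmax(-net, 0)) / max(sum(abs(net)), .Machine$double.eps)
  net <- pmax(net, 0)
  i_total <- sum(net)
  if (i_total <= 0 || max(net) <= 0)
    stop("extract_lane_profile: empty lane (no signal above background)")
  structure(list(positions = seq_len(h) - 1, raw = raw,
                 background = bg, normalized = net / i_total,
                 i_total = i_total, clipped_fraction = clipped),
            class = "lane_profile")
}

#' @export
print.lane_profile <- function(x, ...) {
  cat(sprintf(
    "<lane_profile> %d positions, I_total = %.4g, clipped %.2f%%\n",
    length(x$positions), x$i_total, 100 * x$clipped_fraction))
  invisible(x)
}

# local maxima of a profile with a simple prominence criterion;
# deterministic, ties resolved by position
find_bands <- function(v, prominence_frac = 0.05, smooth_halfwidth = 2) {
  if (smooth_halfwidth > 0) {
    k <- rep(1, 2 * smooth_halfwidth + 1)
    n <- length(v)
    vp <- c(rep(v[1], smooth_halfwidth), v, rep(v[n], smooth_halfwidth))
    v <- as.numeric(stats::filter(vp, k / sum(k), sides = 2))
    v <- v[(smooth_halfwidth + 1):(smooth_halfwidth + n)]
  }
  n <- length(v)
  cand <- which(diff(sign(diff(v))) < 0) + 1
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(i) {
    lmin <- min(v[1:i]); rmin <- min(v[i:n])
    v[i] - max(lmin, rmin)
  }, 0)
  cand[prom >= prominence_frac * max(v)]
}

#' Integrated band weights of a lane profile
#'
#' Detects bands as local maxima of the smoothed normalized profile and
#' integrates each band's mass between the valleys separating it from its
#' neighbours (outer boundaries mirror the inner half-widths). A linear
#' baseline between the boundary values is subtracted, which removes the
#' noise pedestal that background clipping leaves in signal-free stretches
#' of the lane. Weights are renormalized to sum to 1 over the detected
#' bands.
#'
#' @param profile a [lane_profile()]
#' @param n_bands optionally require / select this many bands (the
#'   strongest are kept)
#' @param prominence_frac band-detection prominence, fraction of max
#' @return data.frame with `position_px`, `weight`
#' @export
band_weights <- function(profile, n_bands = NULL, prominence_frac = 0.05) {
  stopifnot(inherits(profile, "lane_profile"))
  v <- profile$normalized
  n <- length(v)
  peaks <- find_bands(v, prominence_frac)
  if (!length(peaks)) stop("band_weights: no bands detected")
  if (!is.null(n_bands)) {
    if (length(peaks) < n_bands)
      stop("band_weights: detected ", length(peaks), " bands, need ",
           n_bands)
    peaks <- sort(peaks[order(-v[peaks])][seq_len(n_bands)])
  }
  k <- length(peaks)
  inner <- if (k > 1)
    vapply(seq_len(k - 1), function(i) {
      seg <- peaks[i]:peaks[i + 1]
      seg[which.min(v[seg])]
    }, 0L) else integer(0)
  lo <- c(max(1L, peaks[1] - (if (k > 1) inner[1] - peaks[1]
                              else peaks[1] - 1L)), inner)
  hi <- c(inner, min(n, peaks[k] + (if (k > 1) peaks[k] - inner[k - 1]
                                    else n - peaks[k])))
  area <- vapply(seq_len(k), function(i) {
    seg <- lo[i]:hi[i]
    base <- v[lo[i]] + (v[hi[i]] - v[lo[i]]) *
      (seg - lo[i]) / max(hi[i] - lo[i], 1)
    sum(pmax(v[seg] - base, 0))
  }, 0)
  data.frame(position_px = profile$positions[peaks],
             weight = area / sum(area))
}

#' Calibrate migration distance to fragment size with a ladder lane
#'
#' Ladder bands are detected as local maxima of the smoothed normalized
#' profile (prominence >= 5% of the maximum); their count must equal the
#' number of supplied sizes, and detected positions are paired with sizes
#' in order (largest fragment migrates least). The mapping is a piecewise-
#' linear interpolation of `log10(size)` against migration position — an
#' empirical mobility model, defined only within the ladder span: queries
#' outside it return NA rather than extrapolating.
#'
#' @param ladder a [lane_profile()] of the ladder lane
#' @param sizes fragment sizes in bp, in decreasing order
#' @param prominence_frac band-detection prominence, fraction of max
#' @return an object of class `size_calibration`
#' @export
calibrate_sizes <- function(ladder, sizes, prominence_frac = 0.05) {
  stopifnot(inherits(ladder, "lane_profile"))
  if (any(diff(sizes) >= 0))
    stop("calibrate_sizes: sizes must be strictly decreasing ",
         "(largest fragment first)")
  bands <- find_bands(ladder$normalized, prominence_frac)
  if (length(bands) != length(sizes))
    stop("calibrate_sizes: detected ", length(bands), " bands but ",
         length(sizes), " sizes were supplied")
  pos <- ladder$positions[bands]
  if (any(diff(pos) <= 0))
    stop("calibrate_sizes: detected bands are not monotone in position")
  structure(list(ladder_positions = pos, ladder_sizes = sizes),
            class = "size_calibration")
}

#' @export
print.size_calibration <- function(x, ...) {
  cat("<size_calibration>\n")
  print(data.frame(position_px = x$ladder_positions,
                   size_bp = x$ladder_sizes))
  invisible(x)
}

#' Map migration positions to fragment sizes
#'
#' @param object a `size_calibration`
#' @param positions migration positions (px)
#' @param ... unused
#' @return sizes in bp; NA outside the ladder span
#' @export
predict.size_calibration <- function(object, positions, ...) {
  lg <- approx(object$ladder_positions, log10(object$ladder_sizes),
               xout = positions, rule = 1)$y
  10^lg
}

#' Re-bin a lane profile onto a fragment-size axis
#'
#' Normalized lane mass is assigned to logarithmic size bins through the
#' ladder calibration. Binning transports mass (not density), so total
#' in-span mass is conserved exactly; the reported `density` divides each
#' bin's mass by its log10-size width, which is the Jacobian-corrected
#' quantity to plot against log size. A warning is raised when more than
#' 20% of the lane's mass migrates outside the calibrated span.
#'
#' @param profile a [lane_profile()]
#' @param cal a `size_calibration`
#' @param n_bins number of logarithmic size bins
#' @param bin_edges optional explicit bp bin edges (overrides `n_bins`);
#'   required when two distributions must share a grid
#' @return object of class `size_distribution` with `bin_edges`,
#'   `bin_centers` (geometric), `mass`, `density`, `mass_in_span`
#' @export
size_distribution <- function(profile, cal, n_bins = 60,
                              bin_edges = NULL) {
  stopifnot(inherits(profile, "lane_profile"),
            inherits(cal, "size_calibration"))
  sizes <- predict(cal, profile$positions)
  inspan <- is.finite(sizes)
  mass_in <- sum(profile$normalized[inspan])
  if (mass_in < 0.8)
    warning(sprintf(
      "size_distribution: %.1f%% of lane mass outside the ladder span",
      100 * (1 - mass_in)))
  if (is.null(bin_edges)) {
    rng <- log10(range(cal$ladder_sizes))
    bin_edges <- 10^seq(rng[1], rng[2], length.out = n_bins + 1)
  }
  lb <- log10(bin_edges)
  bin <- findInterval(log10(sizes[inspan]), lb, rightmost.closed = TRUE)
  bin[bin < 1] <- 1
  bin[bin > length(bin_edges) - 1] <- length(bin_edges) - 1
  mass <- vapply(seq_len(length(bin_edges) - 1), function(i)
    sum(profile$normalized[inspan][bin == i]), 0)
  centers <- sqrt(bin_edges[-1] * bin_edges[-length(bin_edges)])
  structure(list(bin_edges = bin_edges, bin_centers = centers,
                 mass = mass, density = mass / diff(lb),
                 mass_in_span = mass_in),
            class = "size_distribution")
}

#' @export
print.size_distribution <- function(x, ...) {
  med <- weighted_median(x$bin_centers, x$mass)
  cat(sprintf(
    "<size_distribution> %d bins over %.0f-%.0f bp, median ~ %.0f bp\n",
    length(x$mass), min(x$bin_edges), max(x$bin_edges), med))
  invisible(x)
}

#' @export
plot.size_distribution <- function(x, ...) {
  plot(x$bin_centers, x$density, log = "x", type = "h",
       xlab = "fragment size (bp)", ylab = "mass density (per log10 bp)",
       ...)
  invisible(x)
}

# mass-weighted median over bin centers
weighted_median <- function(v, w) {
  if (sum(w) <= 0) return(NA_real_)
  o <- order(v)
  cw <- cumsum(w[o]) / sum(w)
  v[o][which(cw >= 0.5)[1]]
}

#' Compare two fragment-size distributions as accessibility readouts
#'
#' At a matched DNase dose, more accessible chromatin is cut into smaller
#' fragments. The comparison reports, per distribution, the mass-weighted
#' median fragment size and the fraction of mass below `threshold_bp`
#' (the accessibility score), plus the A - B differences. Higher score =
#' more digestion = more accessible chromatin.
#'
#' @param dist_a,dist_b `size_distribution`s on a common bin grid
#' @param threshold_bp size threshold for the accessibility score
#'   (default 500 bp)
#' @return list of class `accessibility_summary`
#' @export
accessibility_summary <- function(dist_a, dist_b, threshold_bp = 500) {
  stopifnot(inherits(dist_a, "size_distribution"),
            inherits(dist_b, "size_distribution"))
  if (!isTRUE(all.equal(dist_a$bin_edges, dist_b$bin_edges)))
    stop("accessibility_summary: distributions are on different size grids")
  one <- function(d) {
    tot <- sum(d$mass)
    list(median_bp = weighted_median(d$bin_centers, d$mass),
         score = sum(d$mass[d$bin_centers < threshold_bp]) / tot)
  }
  a <- one(dist_a); b <- one(dist_b)
  structure(list(
    threshold_bp = threshold_bp,
    a = a, b = b,
    median_diff_bp = a$median_bp - b$median_bp,
    score_diff = a$score - b$score),
    class = "accessibility_summary")
}

#' @export
print.accessibility_summary <- function(x, ...) {
  cat("<accessibility_summary> (score = mass fraction below ",
      x$threshold_bp, " bp)\n", sep = "")
  cat(sprintf("  A: median %.0f bp, score %.3f\n", x$a$median_bp,
              x$a$score))
  cat(sprintf("  B: median %.0f bp, score %.3f\n", x$b$median_bp,
              x$b$score))
  cat(sprintf("  A - B: median %+.0f bp, score %+.3f\n",
              x$median_diff_bp, x$score_diff))
  invisible(x)
}
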