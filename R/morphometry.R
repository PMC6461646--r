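#' Segmentation parameters
#'
#' @param threshold `"auto"` (global Otsu on the smoothed image/stack) or a
#'   manual numeric threshold on raw intensities
#' @param seed_point_diameter minimum separation (um) between watershed
#'   seeds when splitting touching nuclei; default 6 um, roughly the
#'   diameter of a small nucleus
#' @param min_volume smallest object kept, um^3 (3D) or um^2 (2D)
#' @param surface_smoothing Gaussian sigma (um) applied before thresholding;
#'   default 0.2 um, well below nuclear scale
#' @return an object of class `segmentation_params`
#' @export
segmentation_params <- function(threshold = "auto", seed_point_diameter = 6,
                                min_volume = 20, surface_smoothing = 0.2) {
  if (seed_point_diameter <= 0)
    stop("segmentation_params: seed_point_diameter must be > 0")
  if (min_volume < 0) stop("segmentation_params: min_volume must be >= 0")
  structure(list(threshold = threshold,
                 seed_point_diameter = seed_point_diameter,
                 min_volume = min_volume,
                 surface_smoothing = surface_smoothing),
            class = "segmentation_params")
}

# global Otsu threshold of a numeric vector (EBImage's otsu is per-frame;
# packing the values into one frame makes it global)
otsu_global <- function(v) {
  r <- range(v)
  if (r[1] == r[2]) return(r[1])
  # histogram-based: a regular subsample leaves the threshold unchanged
  if (length(v) > 2^20) v <- v[seq(1, length(v), length.out = 2^20)]
  vn <- (v - r[1]) / (r[2] - r[1])
  thr <- EBImage::otsu(matrix(vn, ncol = 1), range = c(0, 1), levels = 256)
  thr * (r[2] - r[1]) + r[1]
}

# separable Gaussian kernel for one axis, sigma and spacing in um
gauss_kernel <- function(sigma_um, spacing_um) {
  if (sigma_um <= 0) return(1)
  s <- sigma_um / spacing_um
  half <- max(1L, ceiling(3 * s))
  k <- exp(-((-half:half)^2) / (2 * s^2))
  k / sum(k)
}

# anisotropy-aware Gaussian blur of a (z, y, x) array
blur3d <- function(arr, sigma_um, voxel_size, sigma_z_um = sigma_um) {
  d <- dim(arr)
  out <- as.vector(arr)
  sig <- c(sigma_z_um, sigma_um, sigma_um)
  for (axis in 0:2) {
    k <- gauss_kernel(sig[axis + 1], voxel_size[axis + 1])
    if (length(k) > 1)
      out <- .cpp_conv_axis3d(out, d, k, axis)
  }
  array(out, d)
}

#' Segment nuclei in a 2D DAPI image
#'
#' Gaussian smoothing, global Otsu threshold (or a manual value), hole
#' filling, connected-components labelling, and removal of objects below
#' `min_volume` (interpreted as um^2 in 2D).
#'
#' @param img an [image2d()] with nuclei brighter than background
#' @param params a [segmentation_params()]
#' @return a [label_map()]
#' @export
segment_nuclei_2d <- function(img, params = segmentation_params()) {
  stopifnot(inherits(img, "image2d"))
  px <- img$pixels
  sm <- px
  s_px <- params$surface_smoothing / img$pixel_size
  if (s_px > 0.3) sm <- EBImage::gblur(px, sigma = s_px)
  thr <- if (identical(params$threshold, "auto")) otsu_global(as.vector(sm))
         else params$threshold
  mask <- sm > thr
  if (!any(mask)) {
    warning("segment_nuclei_2d: no foreground pixels")
    return(label_map(matrix(0L, nrow(px), ncol(px)), img$pixel_size))
  }
  lab <- EBImage::bwlabel(mask)
  lab <- EBImage::fillHull(lab)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes * img$pixel_size^2 >= params$min_volume)
  relab <- integer(length(sizes))
  relab[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(px), ncol(px))
  nz <- lab > 0
  out[nz] <- relab[lab[nz]]
  label_map(out, img$pixel_size,
            meta = list(threshold = thr, n_removed_small =
                          length(sizes) - length(keep)))
}

# boundary polygon of a binary mask via marching squares (contourLines),
# smoothed with a circular moving average over ~1% of the vertices.
# Returns total perimeter in pixel units.
perimeter_contour <- function(mask, smooth_frac = 0.01) {
  m <- matrix(0, nrow(mask) + 2, ncol(mask) + 2)
  m[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask * 1
  cl <- grDevices::contourLines(x = seq_len(nrow(m)), y = seq_len(ncol(m)),
                                z = m, levels = 0.5)
  if (!length(cl)) return(0)
  total <- 0
  for (cont in cl) {
    p <- cbind(cont$x, cont$y)
    if (nrow(p) > 1 && all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), ,
                                                           drop = FALSE]
    n <- nrow(p)
    if (n < 3) next
    k <- max(3L, round(smooth_frac * n))
    if (k %% 2 == 0) k <- k + 1L
    if (k < n) {
      half <- k %/% 2
      csx <- cumsum(c(0, p[, 1], p[, 1]))  # doubled for wraparound
      csy <- cumsum(c(0, p[, 2], p[, 2]))
      win <- function(cs, i) (cs[i + k] - cs[i]) / k
      starts <- ((seq_len(n) - 1 - half) %% n) + 1  # circular window
      p <- cbind(win(csx, starts), win(csy, starts))
    }
    p <- rbind(p, p[1, ])
    total <- total + sum(sqrt(rowSums(diff(p)^2)))
  }
  total
}

#' Circularity of a single 2D object
#'
#' Computes `4 * pi * area / perimeter^2`: 1 for a disc, `pi/4` for a
#' square, smaller for elongated or irregular shapes. Area is the pixel
#' count times `pixel_size^2`. The perimeter is the length of the
#' marching-squares boundary polygon smoothed with a moving-average window
#' of about 1% of its vertices: the smoothing removes the pixel-staircase
#' length excess that would otherwise bias circularity low for smooth
#' shapes, while leaving polygonal outlines essentially exact. The value is
#' reported without clipping, so discretization may push a disc marginally
#' above or below 1.
#'
#' @param mask logical/0-1 matrix containing exactly one connected component
#' @param pixel_size micrometres per pixel
#' @return list with `circularity`, `area` (um^2), `perimeter` (um)
#' @export
circularity <- function(mask, pixel_size = 1) {
  mask <- mask > 0
  npx <- sum(mask)
  if (npx < 9)
    stop("circularity: component smaller than 9 px; ",
         "perimeter estimate unreliable")
  lab <- EBImage::bwlabel(mask)
  if (max(lab) != 1)
    stop("circularity: mask must contain exactly one connected component")
  area <- npx * pixel_size^2
  per <- perimeter_contour(mask) * pixel_size
  list(circularity = 4 * pi * area / per^2, area = area, perimeter = per)
}

# greedy selection of watershed seeds inside one connected component:
# candidates ordered by (distance desc, index asc); a candidate is kept if
# it is >= sep_um from every kept seed. Also counts distinct maxima
# "clusters": two maxima belong to the same structure when they are within
# plateau_um of each other OR the distance field along the segment joining
# them shows no appreciable dip (an elongated nucleus carries a ridge of
# near-equal maxima, whereas genuinely merged nuclei are separated by a
# saddle). The cluster count is the merge-resolution diagnostic.
select_seeds <- function(coords_um, dists, sep_um, plateau_um,
                         saddle_fun = NULL) {
  ord <- order(-dists, seq_along(dists))
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept)) { kept <- i; next }
    d2 <- colSums((t(coords_um[kept, , drop = FALSE]) - coords_um[i, ])^2)
    if (all(d2 >= sep_um^2)) kept <- c(kept, i)
  }
  reps <- integer(0)
  for (i in ord) {
    if (!length(reps)) { reps <- i; next }
    d2 <- sqrt(colSums((t(coords_um[reps, , drop = FALSE]) -
                          coords_um[i, ])^2))
    same <- d2 < plateau_um
    if (!any(same) && !is.null(saddle_fun)) {
      for (j in reps) {
        sad <- saddle_fun(coords_um[i, ], coords_um[j, ])
        dip <- min(dists[i], dists[j]) - sad
        if (dip < max(plateau_um / 2, 0.08 * min(dists[i], dists[j]))) {
          same <- TRUE
          break
        }
      }
    }
    if (!any(same)) reps <- c(reps, i)
  }
  list(seeds = kept, n_clusters = length(reps))
}

#' Segment nuclei in a 3D confocal stack
#'
#' The stack is Gaussian-smoothed (sigma `surface_smoothing`, physically
#' scaled per axis), thresholded globally (Otsu by default), and labelled by
#' 6-connected components. Touching nuclei are split by a seeded watershed
#' on the Euclidean distance transform computed in physical micrometres
#' (which is what makes the anisotropic 0.25 vs 0.1 um sampling innocuous):
#' seeds are distance-transform local maxima kept greedily at pairwise
#' separation >= `seed_point_diameter`, ties broken by larger distance then
#' scan order, so the output is deterministic. Objects below `min_volume`
#' are removed. Per-component seed diagnostics are retained for
#' [filter_objects()].
#'
#' @param stack a [voxel_grid()]
#' @param params a [segmentation_params()]
#' @return a [label_map()] with `scale = voxel_size`
#' @export
segment_nuclei_3d <- function(stack, params = segmentation_params()) {
  stopifnot(inherits(stack, "voxel_grid"))
  vs <- stack$voxel_size
  d <- dim(stack$voxels)
  sm <- blur3d(stack$voxels, params$surface_smoothing, vs,
               sigma_z_um = params$surface_smoothing)
  thr <- if (identical(params$threshold, "auto")) otsu_global(as.vector(sm))
         else params$threshold
  mask <- sm > thr
  if (!any(mask)) {
    warning("segment_nuclei_3d: no foreground voxels")
    return(label_map(array(0L, d), vs))
  }
  # fill in-plane holes (blurred nuclei interiors are solid; this is
  # insurance against noise pits)
  for (z in seq_len(d[1])) {
    sl <- mask[z, , ]
    if (any(sl)) mask[z, , ] <- EBImage::fillHull(sl * 1L) > 0
  }
  comp <- array(.cpp_label3d(as.vector(mask), d), d)
  dist <- array(.cpp_edt3d(as.vector(mask), d, vs), d)
  floor_val <- max(2 * max(vs), 0.3)
  cand <- .cpp_local_maxima3d(as.vector(dist), d, floor_val)
  cand <- as.integer(cand)
  seeds <- array(0L, d)
  comp_meta <- list()
  plateau_um <- max(2 * max(vs), 1.0)
  if (length(cand)) {
    zi <- (cand - 1) %% d[1]
    yi <- ((cand - 1) %/% d[1]) %% d[2]
    xi <- (cand - 1) %/% (d[1] * d[2])
    coords_um <- cbind(zi * vs[1], yi * vs[2], xi * vs[3])
    cids <- comp[cand]
    next_label <- 0L
    # distance-field value along the segment between two maxima (nearest-
    # voxel sampling); used to distinguish ridges from true saddles
    saddle_fun <- function(p, q) {
      ts <- seq(0, 1, length.out = 25)
      vals <- vapply(ts, function(t) {
        pt <- p + t * (q - p)
        iz <- min(max(round(pt[1] / vs[1]) + 1, 1), d[1])
        iy <- min(max(round(pt[2] / vs[2]) + 1, 1), d[2])
        ix <- min(max(round(pt[3] / vs[3]) + 1, 1), d[3])
        dist[iz, iy, ix]
      }, 0)
      min(vals)
    }
    for (cid in sort(unique(cids))) {
      sel <- which(cids == cid)
      ss <- select_seeds(coords_um[sel, , drop = FALSE], dist[cand[sel]],
                         params$seed_point_diameter, plateau_um,
                         saddle_fun)
      lab_ids <- integer(0)
      for (i in ss$seeds) {
        next_label <- next_label + 1L
        seeds[cand[sel[i]]] <- next_label
        lab_ids <- c(lab_ids, next_label)
      }
      comp_meta[[as.character(cid)]] <-
        list(n_seeds = length(ss$seeds), n_clusters = ss$n_clusters,
             labels = lab_ids)
    }
  }
  # components whose every maximum fell below the floor still need a seed
  has_seed <- unique(comp[seeds > 0])
  missing <- setdiff(setdiff(unique(as.vector(comp)), 0L), has_seed)
  next_label <- max(seeds)
  for (cid in missing) {
    vox <- which(comp == cid)
    best <- vox[order(-dist[vox], vox)][1]
    next_label <- next_label + 1L
    seeds[best] <- next_label
    comp_meta[[as.character(cid)]] <-
      list(n_seeds = 1L, n_clusters = 1L, labels = next_label)
  }
  lab <- array(.cpp_watershed_seeded(as.vector(dist), as.vector(seeds),
                                     as.vector(mask), d), d)
  # drop small objects, then relabel contiguously
  sizes <- tabulate(lab[lab > 0], nbins = max(lab))
  vol_per_vox <- prod(vs)
  keep <- which(sizes * vol_per_vox >= params$min_volume & sizes > 0)
  relab <- integer(length(sizes))
  relab[keep] <- seq_along(keep)
  nzi <- which(lab > 0)
  lab[nzi] <- relab[lab[nzi]]
  comp_meta <- lapply(comp_meta, function(m) {
    m$labels_final <- relab[m$labels][relab[m$labels] > 0]
    m
  })
  label_map(lab, vs,
            meta = list(threshold = thr, components = comp_meta,
                        seed_point_diameter = params$seed_point_diameter,
                        plateau_um = plateau_um,
                        n_removed_small = length(sizes) - length(keep)))
}

#' Flag objects that cannot be measured confidently
#'
#' Two QC flags, mirroring the practice of discarding nuclei that cannot be
#' segmented confidently: `border_touching` for objects clipped by the xy
#' field edge (z truncation is pervasive in confocal stacks and only raises
#' a warning), and `unresolved_merge` for objects from a pre-split component
#' whose distance-transform maxima indicated more nuclei than the watershed
#' (at the given `seed_point_diameter`) could separate, or whose split
#' produced fewer final objects than seeds. Flagged objects stay in the
#' label map but are excluded from population statistics.
#'
#' @param labels a [label_map()] from [segment_nuclei_3d()] or
#'   [segment_nuclei_2d()]
#' @return the `label_map` with a populated `flags` data.frame
#' @export
filter_objects <- function(labels) {
  stopifnot(inherits(labels, "label_map"))
  lab <- labels$labels
  k <- max(lab)
  if (k == 0) {
    labels$flags <- data.frame(label = integer(0),
                               border_touching = logical(0),
                               unresolved_merge = logical(0))
    return(labels)
  }
  d <- dim(lab)
  border <- logical(k)
  if (length(d) == 3) {
    edge <- unique(c(lab[, 1, ], lab[, d[2], ], lab[, , 1], lab[, , d[3]]))
    ztouch <- unique(c(lab[1, , ], lab[d[1], , ]))
    ztouch <- setdiff(ztouch, 0L)
    if (length(ztouch))
      warning(sprintf("filter_objects: %d object(s) touch the z limits ",
                      length(ztouch)),
              "of the stack; volumes may be truncated")
  } else {
    edge <- unique(c(lab[1, ], lab[d[1], ], lab[, 1], lab[, d[2]]))
  }
  border[setdiff(edge, 0L)] <- TRUE
  merged <- logical(k)
  for (m in labels$meta$components) {
    if (is.null(m$labels_final) || !length(m$labels_final)) next
    if (m$n_clusters > m$n_seeds || length(m$labels_final) < m$n_seeds)
      merged[m$labels_final] <- TRUE
  }
  labels$flags <- data.frame(label = seq_len(k), border_touching = border,
                             unresolved_merge = merged)
  labels
}

#' Measure per-nucleus volumes from a 3D label map
#'
#' Volume is voxel count times `dz * dy * dx`; centroids are physical
#' (micrometre) coordinates. QC flags from [filter_objects()] are attached
#' (and computed on the fly if absent); flagged objects are excluded from
#' the population summary printed by [nuclear_stats()].
#'
#' @param labels a 3D [label_map()]
#' @param voxel_size optional `c(dz, dy, dx)` um override; defaults to the
#'   map's own scale
#' @return data.frame of class `nucleus_measurements` with columns `label`,
#'   `volume_um3`, `cz`, `cy`, `cx`, `border_touching`, `unresolved_merge`
#' @export
measure_volumes <- function(labels, voxel_size = NULL) {
  stopifnot(inherits(labels, "label_map"))
  lab <- labels$labels
  if (length(dim(lab)) != 3)
    stop("measure_volumes: need a 3D label map")
  vs <- if (is.null(voxel_size)) labels$scale else as.numeric(voxel_size)
  if (length(vs) != 3 || any(vs <= 0))
    stop("measure_volumes: voxel size must be positive c(dz, dy, dx)")
  if (is.null(labels$flags)) labels <- filter_objects(labels)
  k <- max(lab)
  if (k == 0) {
    out <- data.frame(label = integer(0), volume_um3 = numeric(0),
                      cz = numeric(0), cy = numeric(0), cx = numeric(0),
                      border_touching = logical(0),
                      unresolved_merge = logical(0))
    class(out) <- c("nucleus_measurements", "data.frame")
    return(out)
  }
  idx <- which(lab > 0)
  li <- lab[idx]
  d <- dim(lab)
  zi <- (idx - 1) %% d[1]
  yi <- ((idx - 1) %/% d[1]) %% d[2]
  xi <- (idx - 1) %/% (d[1] * d[2])
  counts <- tabulate(li, nbins = k)
  out <- data.frame(
    label = seq_len(k),
    volume_um3 = counts * prod(vs),
    cz = tapply(zi, li, mean)[as.character(seq_len(k))] * vs[1],
    cy = tapply(yi, li, mean)[as.character(seq_len(k))] * vs[2],
    cx = tapply(xi, li, mean)[as.character(seq_len(k))] * vs[3],
    border_touching = labels$flags$border_touching,
    unresolved_merge = labels$flags$unresolved_merge,
    row.names = NULL)
  class(out) <- c("nucleus_measurements", "data.frame")
  out
}

#' Measure areas and circularities from a 2D label map
#'
#' @param labels a 2D [label_map()]
#' @param pixel_size optional um/px override
#' @return data.frame of class `nucleus_measurements` with `label`,
#'   `area_um2`, `perimeter_um`, `circularity`, centroid, flags
#' @export
measure_shapes_2d <- function(labels, pixel_size = NULL) {
  stopifnot(inherits(labels, "label_map"))
  lab <- labels$labels
  if (length(dim(lab)) != 2)
    stop("measure_shapes_2d: need a 2D label map")
  ps <- if (is.null(pixel_size)) labels$scale[1] else pixel_size
  if (is.null(labels$flags)) labels <- filter_objects(labels)
  k <- max(lab)
  rows <- lapply(seq_len(k), function(i) {
    mask <- lab == i
    cc <- tryCatch(circularity(mask, ps), error = function(e) NULL)
    ctr <- which(mask, arr.ind = TRUE)
    data.frame(label = i,
               area_um2 = if (is.null(cc)) sum(mask) * ps^2 else cc$area,
               perimeter_um = if (is.null(cc)) NA_real_ else cc$perimeter,
               circularity = if (is.null(cc)) NA_real_ else cc$circularity,
               cy = mean(ctr[, 1] - 1) * ps, cx = mean(ctr[, 2] - 1) * ps)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(label = integer(0), area_um2 = numeric(0),
                      perimeter_um = numeric(0), circularity = numeric(0),
                      cy = numeric(0), cx = numeric(0))
  out$border_touching <- labels$flags$border_touching[out$label]
  out$unresolved_merge <- labels$flags$unresolved_merge[out$label]
  class(out) <- c("nucleus_measurements", "data.frame")
  out
}

#' Population summary and group comparison of nucleus measurements
#'
#' Summarizes volume and/or circularity over unflagged objects (n, mean,
#' SD, median). With a second group, the two populations are compared by a
#' two-tailed unpaired Student's t-test.
#'
#' @param measurements a `nucleus_measurements` data.frame (or plain numeric
#'   vector of values)
#' @param reference optional second group for comparison
#' @param metric column to analyse when data.frames are given
#' @return list of class `nuclear_stats` with `n`, `mean`, `sd`, `median`
#'   and, for two groups, `t_test` (htest)
#' @export
nuclear_stats <- function(measurements, reference = NULL,
                          metric = c("volume_um3", "circularity",
                                     "area_um2")) {
  metric <- match.arg(metric)
  pull <- function(m) {
    if (is.numeric(m)) return(m[is.finite(m)])
    if (!metric %in% names(m))
      stop("nuclear_stats: metric '", metric, "' not present")
    keep <- !(m$border_touching | m$unresolved_merge)
    v <- m[[metric]][keep]
    v[is.finite(v)]
  }
  a <- pull(measurements)
  if (length(a) < 2)
    stop("nuclear_stats: need at least 2 unflagged objects")
  out <- list(n = length(a), mean = mean(a), sd = sd(a),
              median = median(a))
  if (!is.null(reference)) {
    b <- pull(reference)
    if (length(b) < 2)
      stop("nuclear_stats: need at least 2 unflagged reference objects")
    out$reference <- list(n = length(b), mean = mean(b), sd = sd(b),
                          median = median(b))
    out$t_test <- t.test(a, b, var.equal = TRUE)
  }
  class(out) <- "nuclear_stats"
  out
}

#' @export
print.nuclear_stats <- function(x, ...) {
  cat(sprintf("n = %d, mean = %.4g, sd = %.4g, median = %.4g\n",
              x$n, x$mean, x$sd, x$median))
  if (!is.null(x$t_test)) {
    r <- x$reference
    cat(sprintf("reference: n = %d, mean = %.4g, sd = %.4g\n",
                r$n, r$mean, r$sd))
    cat(sprintf("two-tailed unpaired t-test: t = %.3f, p = %.3g\n",
                x$t_test$statistic, x$t_test$p.value))
  }
  invisible(x)
}

#' Write nucleus measurements to CSV
#'
#' @param measurements a `nucleus_measurements` data.frame
#' @param path output CSV
#' @return the path, invisibly
#' @export
write_measurements <- function(measurements, path) {
  write.csv(as.data.frame(measurements), path, row.names = FALSE)
  invisible(path)
}
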