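#' Synthetic DAPI-like nuclei z-stack with known volumes
#'
#' Generates `n` randomly oriented ellipsoidal nuclei whose volumes follow
#' a lognormal distribution moment-matched to `(volume_mean, volume_sd)`
#' (lognormal keeps volumes positive with only two moments specified).
#' Nuclei are placed without overlap except for a controlled fraction of
#' deliberately touching pairs; the stack is blurred with an anisotropic
#' Gaussian PSF (axial sigma twice the lateral one) and corrupted with
#' Poisson-Gaussian noise at the requested SNR. The field is auto-sized to
#' hold the population unless `field_um` is given. Identical `(params,
#' seed)` give identical output.
#'
#' @param n number of nuclei
#' @param volume_mean,volume_sd population mean and SD of true volumes
#'   (um^3)
#' @param aspect_range range of prolate aspect ratios (long axis / short)
#' @param voxel_size `c(dz, dy, dx)` um; default `c(0.25, 0.1, 0.1)`, the
#'   reference confocal sampling
#' @param blur_sigma lateral PSF sigma in um (axial is twice this)
#' @param snr approximate foreground signal-to-noise ratio
#' @param touching_fraction fraction of nuclei placed in contact with a
#'   neighbour
#' @param field_um optional `c(z, y, x)` physical field size in um
#' @param seed RNG seed
#' @return list with `stack` (a [voxel_grid()]) and `truth` (data.frame of
#'   per-nucleus volume, semi-axes, centre, touching flag; plus the
#'   generation parameters as attributes)
#' @export
make_nuclei_scene <- function(n, volume_mean = 207, volume_sd = 58,
                              aspect_range = c(1, 1.6),
                              voxel_size = c(0.25, 0.1, 0.1),
                              blur_sigma = 0.2, snr = 10,
                              touching_fraction = 0.05, field_um = NULL,
                              seed = NULL) {
  if (volume_mean <= 0) stop("make_nuclei_scene: volume_mean must be > 0")
  if (volume_sd >= volume_mean)
    stop("make_nuclei_scene: need volume_sd < volume_mean ",
         "(lognormal parameterization)")
  with_seed(seed, {
    sig2 <- log(1 + (volume_sd / volume_mean)^2)
    vols <- rlnorm(n, meanlog = log(volume_mean) - sig2 / 2,
                   sdlog = sqrt(sig2))
    q <- runif(n, aspect_range[1], aspect_range[2])
    a <- (3 * vols / (4 * pi * q))^(1 / 3)  # a = b, c = q * a
    axes <- cbind(a, a, q * a)
    rmax <- q * a
    rots <- lapply(seq_len(n), function(i) {
      m <- matrix(rnorm(9), 3)
      qr_r <- qr(m)
      rr <- qr.Q(qr_r)
      rr * sign(diag(qr.R(qr_r)))[col(rr)]
    })
    margin <- 0.6
    if (is.null(field_um)) {
      lz <- 2 * max(rmax) + 2 * margin + 0.5
      lxy <- sqrt(sum(pi * (rmax + margin)^2) / 0.45)
      lxy <- max(lxy, 2 * (max(rmax) + margin) + 1)
      field_um <- c(lz, lxy, lxy)
    }
    n_touch <- round(n * touching_fraction)
    centers <- matrix(NA_real_, n, 3)
    ord <- order(-rmax)
    # the last n_touch nuclei in placement order are put in contact with a
    # previously placed partner
    touch_idx <- if (n_touch > 0 && n > 1) tail(ord, n_touch) else integer(0)
    placed <- integer(0)
    for (i in ord) {
      if (any(2 * (rmax[i] + margin) >= field_um))
        stop("make_nuclei_scene: packing failed after bounded attempts; ",
             "supply a larger field_um")
      want_touch <- i %in% touch_idx && length(placed) > 0
      ok <- FALSE
      for (try in seq_len(4000)) {
        if (want_touch) {
          j <- placed[sample.int(length(placed), 1)]
          dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
          d <- 0.95 * (min(axes[i, ]) + min(axes[j, ]))
          ctr <- centers[j, ] + dir * d
          if (any(ctr < rmax[i] + 0.1) ||
              any(ctr > field_um - rmax[i] - 0.1)) next
          dd <- sqrt(colSums((t(centers[setdiff(placed, j), ,
                                        drop = FALSE]) - ctr)^2))
          if (length(dd) &&
              any(dd < rmax[setdiff(placed, j)] + rmax[i] + 0.2)) next
        } else {
          ctr <- c(runif(1, rmax[i] + margin, field_um[1] - rmax[i] - margin),
                   runif(1, rmax[i] + margin, field_um[2] - rmax[i] - margin),
                   runif(1, rmax[i] + margin, field_um[3] - rmax[i] - margin))
          if (length(placed)) {
            dd <- sqrt(colSums((t(centers[placed, , drop = FALSE]) - ctr)^2))
            if (any(dd < rmax[placed] + rmax[i] + 0.2)) next
          }
        }
        centers[i, ] <- ctr
        placed <- c(placed, i)
        ok <- TRUE
        break
      }
      if (!ok)
        stop("make_nuclei_scene: packing failed after bounded attempts; ",
             "supply a larger field_um")
    }
    dims <- pmax(as.integer(ceiling(field_um / voxel_size)), 8L)
    img <- array(0, dims)
    brightness <- runif(n, 0.85, 1.15)
    grid_ax <- lapply(1:3, function(k) (seq_len(dims[k]) - 1) * voxel_size[k])
    for (i in seq_len(n)) {
      rng <- lapply(1:3, function(k) {
        which(grid_ax[[k]] >= centers[i, k] - rmax[i] - 0.3 &
              grid_ax[[k]] <= centers[i, k] + rmax[i] + 0.3)
      })
      if (any(vapply(rng, length, 1L) == 0)) next
      pz <- grid_ax[[1]][rng[[1]]] - centers[i, 1]
      py <- grid_ax[[2]][rng[[2]]] - centers[i, 2]
      px <- grid_ax[[3]][rng[[3]]] - centers[i, 3]
      pts <- cbind(rep(pz, times = length(py) * length(px)),
                   rep(rep(py, each = length(pz)), times = length(px)),
                   rep(px, each = length(pz) * length(py)))
      u <- pts %*% rots[[i]]
      inside <- (u[, 1] / axes[i, 1])^2 + (u[, 2] / axes[i, 2])^2 +
        (u[, 3] / axes[i, 3])^2 <= 1
      sub <- img[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
      sub_v <- as.vector(sub)
      sub_v[inside] <- pmax(sub_v[inside], brightness[i])
      img[rng[[1]], rng[[2]], rng[[3]]] <-
        array(sub_v, dim(sub))
    }
    if (blur_sigma > 0)
      img <- blur3d(img, blur_sigma, voxel_size,
                    sigma_z_um = 2 * blur_sigma)
    # Poisson-Gaussian noise: photon scale snr^2 at unit signal (normal
    # approximation once counts are large enough for it to be exact in
    # double precision)
    photons <- snr^2
    bg_frac <- 0.08
    lam <- photons * (img + bg_frac)
    counts <- if (photons > 1e6)
      lam + rnorm(length(lam), 0, sqrt(lam))
    else rpois(length(lam), lam)
    noisy <- counts + rnorm(length(lam), 0, 2)
    img <- array(pmax(noisy, 0) / photons, dims)
    truth <- data.frame(id = seq_len(n), volume_um3 = vols,
                        semi_a = axes[, 1], semi_b = axes[, 2],
                        semi_c = axes[, 3],
                        cz = centers[, 1], cy = centers[, 2],
                        cx = centers[, 3],
                        touching = seq_len(n) %in% touch_idx)
    attr(truth, "params") <- list(volume_mean = volume_mean,
                                  volume_sd = volume_sd, snr = snr,
                                  blur_sigma = blur_sigma,
                                  voxel_size = voxel_size,
                                  field_um = field_um, seed = seed)
    list(stack = voxel_grid(img, voxel_size), truth = truth)
  })
}

#' Segment and measure a synthetic nuclear population
#'
#' Convenience driver for parameter-recovery studies: generates `n` nuclei
#' at the stated volume distribution split across several stacks (a single
#' field cannot physically hold a large population at confocal sampling),
#' runs [segment_nuclei_3d()], [filter_objects()] and [measure_volumes()]
#' on each stack, and pools unflagged volumes.
#'
#' @param n total nuclei to simulate
#' @param volume_mean,volume_sd population parameters (um^3)
#' @param nuclei_per_scene nuclei per generated stack
#' @param seed base RNG seed; scene `i` uses `seed + i`
#' @param params a [segmentation_params()]
#' @param ... further arguments to [make_nuclei_scene()]
#' @return list with `volumes` (pooled unflagged estimates), `truth`
#'   (pooled true volumes), `truth_matched` (true volume of the nearest
#'   ground-truth nucleus for each kept estimate), `mean_estimate`,
#'   `n_measured`
#' @export
recover_volumes <- function(n = 60, volume_mean = 207, volume_sd = 58,
                            nuclei_per_scene = 10, seed = 1,
                            params = segmentation_params(), ...) {
  n_scenes <- ceiling(n / nuclei_per_scene)
  vols <- numeric(0)
  tv <- numeric(0)
  tm <- numeric(0)
  for (s in seq_len(n_scenes)) {
    n_here <- min(nuclei_per_scene, n - (s - 1) * nuclei_per_scene)
    sc <- make_nuclei_scene(n_here, volume_mean, volume_sd,
                            seed = seed + s, ...)
    lab <- segment_nuclei_3d(sc$stack, params)
    lab <- filter_objects(lab)
    m <- measure_volumes(lab)
    keep <- which(!(m$border_touching | m$unresolved_merge))
    vols <- c(vols, m$volume_um3[keep])
    tv <- c(tv, sc$truth$volume_um3)
    # pair each kept object with the nearest ground-truth centre
    d2 <- outer(m$cz[keep], sc$truth$cz, "-")^2 +
      outer(m$cy[keep], sc$truth$cy, "-")^2 +
      outer(m$cx[keep], sc$truth$cx, "-")^2
    tm <- c(tm, sc$truth$volume_um3[apply(d2, 1, which.min)])
  }
  list(volumes = vols, truth = tv, truth_matched = tm,
       mean_estimate = mean(vols), n_measured = length(vols))
}

#' Synthetic sensitized-emission FRET scene with known ground truth
#'
#' Builds a field of cells whose nuclear-envelope rings carry donor and
#' acceptor signal; the FRET channel is composed as
#' `x * D + y * A + se * A` inside the rings, so the true per-pixel index
#' is exactly `true_se_fraction` (0 emulates a headless / no-transfer
#' control). Matching donor-only and acceptor-only calibration scenes are
#' emitted. An optional multiplicative illumination gradient and an
#' inter-channel pixel shift (applied to the FRET and acceptor channels)
#' corrupt the scene after composition; Gaussian noise is added at the
#' stated SNR, plus a constant camera offset. A 0-based cell-free
#' `background_region` rectangle suitable for [background_spec()] is
#' returned with the truth.
#'
#' @param n_cells number of cells
#' @param true_se_fraction sensitized emission as a fraction of acceptor
#'   intensity (0 <= se < 1)
#' @param x,y true donor-leakage and cross-excitation fractions
#' @param gradient_amplitude relative illumination change across the field
#'   (0 = flat)
#' @param shift_px `c(dy, dx)` inter-channel shift in pixels
#' @param snr foreground signal-to-noise ratio
#' @param pixel_size um per pixel
#' @param seed RNG seed
#' @return list with `sensor`, `donor_only`, `acceptor_only` (raw
#'   [fret_acquisition()]s), `masks` (ring [label_map()]), `truth`
#' @export
make_fret_scene <- function(n_cells = 30, true_se_fraction = 0.15,
                            x = 0.25, y = 0.10, gradient_amplitude = 0,
                            shift_px = c(0, 0), snr = 20,
                            pixel_size = 0.2, seed = NULL) {
  if (true_se_fraction < 0 || true_se_fraction >= 1)
    stop("make_fret_scene: need 0 <= true_se_fraction < 1")
  with_seed(seed, {
    radii <- runif(n_cells, 2.8, 4.2)
    r_bound <- radii + 2.2
    side <- sqrt(sum(pi * r_bound^2) / 0.45)
    side <- max(side, 2 * max(r_bound) + 2)
    npx <- as.integer(ceiling(side / pixel_size))
    centers <- matrix(NA_real_, n_cells, 2)
    for (i in seq_len(n_cells)) {
      for (try in seq_len(4000)) {
        ctr <- runif(2, r_bound[i], side - r_bound[i])
        if (i > 1) {
          dd <- sqrt(colSums((t(centers[seq_len(i - 1), , drop = FALSE]) -
                                ctr)^2))
          if (any(dd < r_bound[i] + r_bound[seq_len(i - 1)] - 1.5)) next
        }
        centers[i, ] <- ctr
        break
      }
      if (anyNA(centers[i, ]))
        stop("make_fret_scene: packing failed; reduce n_cells")
    }
    yy <- (row(matrix(0, npx, npx)) - 0.5) * pixel_size
    xx <- (col(matrix(0, npx, npx)) - 0.5) * pixel_size
    rings <- matrix(0L, npx, npx)
    donor_amp <- runif(n_cells, 0.7, 1.3)
    acc_amp <- runif(n_cells, 0.7, 1.3)
    D <- matrix(0, npx, npx); A <- matrix(0, npx, npx)
    for (i in seq_len(n_cells)) {
      rr <- sqrt((yy - centers[i, 1])^2 + (xx - centers[i, 2])^2)
      ring <- rr >= radii[i] - 0.5 & rr <= radii[i] + 1.0
      rings[ring] <- i
      D[ring] <- donor_amp[i]
      A[ring] <- acc_amp[i]
    }
    base <- 500
    D <- D * base; A <- A * base
    F_se <- x * D + y * A + true_se_fraction * A
    grad <- 1 + gradient_amplitude * (xx / side - 0.5)
    offset <- 0.1 * base
    noise_sd <- base / snr
    finish <- function(sig, shift = c(0, 0)) {
      m <- sig * grad
      if (any(shift != 0)) {
        m <- translate_image(m, -shift[1], -shift[2], fill = 0)
      }
      m <- m + offset + matrix(rnorm(npx * npx, 0, noise_sd), npx)
      image2d(pmax(m, 0), pixel_size)
    }
    sensor <- fret_acquisition(
      donor = finish(D),
      fret = finish(F_se, shift_px),
      acceptor = finish(A, shift_px))
    # calibration scenes share the geometry but are independent samples
    d_cal <- D * runif(1, 0.8, 1.2)
    donor_only <- fret_acquisition(
      donor = finish(d_cal),
      fret = finish(x * d_cal, shift_px),
      acceptor = finish(matrix(0, npx, npx), shift_px))
    a_cal <- A * runif(1, 0.8, 1.2)
    acceptor_only <- fret_acquisition(
      donor = finish(matrix(0, npx, npx)),
      fret = finish(y * a_cal, shift_px),
      acceptor = finish(a_cal, shift_px))
    # cell rings stay >= 1.2 um clear of the field edge by construction,
    # so a thin full-width strip is reliably cell-free; its size keeps the
    # background-mean standard error negligible against the signal
    bg_rows <- max(4L, as.integer(floor(1.0 / pixel_size)))
    truth <- list(true_se_fraction = true_se_fraction, x = x, y = y,
                  gradient_amplitude = gradient_amplitude,
                  shift_px = shift_px, snr = snr, offset = offset,
                  background_region = c(0, 0, npx, bg_rows),
                  centers_um = centers, radii_um = radii)
    list(sensor = sensor, donor_only = donor_only,
         acceptor_only = acceptor_only,
         masks = label_map(rings, pixel_size), truth = truth)
  })
}

#' Reference FRAP acquisition schedule
#'
#' Three pre-bleach frames, a bleach gap, then 10 frames at 0.78 s
#' followed by 30 frames at 2 s intervals.
#'
#' @param n_prebleach pre-bleach frames
#' @param prebleach_dt interval between pre-bleach frames (s)
#' @param bleach_gap_s duration of the bleach interval (s)
#' @param n_fast,fast_dt,n_slow,slow_dt post-bleach schedule
#' @return list describing the schedule
#' @export
frap_schedule <- function(n_prebleach = 3, prebleach_dt = 0.78,
                          bleach_gap_s = 20, n_fast = 10, fast_dt = 0.78,
                          n_slow = 30, slow_dt = 2) {
  list(n_prebleach = n_prebleach, prebleach_dt = prebleach_dt,
       bleach_gap_s = bleach_gap_s, n_fast = n_fast, fast_dt = fast_dt,
       n_slow = n_slow, slow_dt = slow_dt)
}

#' Synthetic FRAP traces with known recovery parameters
#'
#' Post-bleach bleached-ROI signal follows
#' `base * decay(t) * (1 - bleach_depth * (1 - m * (1 - exp(-t'/tau))))`
#' with `t'` measured from the first post-bleach frame; the reference ROI
#' carries the same per-frame acquisition photobleaching `decay`, so the
#' double normalization cancels it exactly, and the noiseless normalized
#' curve is `m * (1 - exp(-t'/tau))` regardless of bleach depth.
#'
#' @param m true mobile fraction in `[0, 1]`
#' @param tau_s recovery time constant (s)
#' @param bleach_depth fractional signal loss at the bleach (0 < depth < 1)
#' @param acq_decay_per_frame fractional signal loss per acquired frame
#' @param noise_sd Gaussian noise SD added to each ROI trace, in units of
#'   the background-subtracted pre-bleach ROI1 signal
#' @param schedule a [frap_schedule()]
#' @param base,ref_base,bg pre-bleach ROI1/ROI2 signals and background
#' @param seed RNG seed
#' @return list with `series` (a [frap_series()]) and `truth`
#' @export
make_frap_traces <- function(m = 0.8, tau_s = 10, bleach_depth = 0.6,
                             acq_decay_per_frame = 0, noise_sd = 0,
                             schedule = frap_schedule(), base = 1000,
                             ref_base = 900, bg = 50, seed = NULL) {
  if (m < 0 || m > 1) stop("make_frap_traces: need 0 <= m <= 1")
  if (bleach_depth <= 0 || bleach_depth >= 1)
    stop("make_frap_traces: need 0 < bleach_depth < 1")
  with_seed(seed, {
    s <- schedule
    t_pre <- (seq_len(s$n_prebleach) - 1) * s$prebleach_dt
    t0 <- max(t_pre) + s$bleach_gap_s
    t_post <- t0 + c(seq_len(s$n_fast) - 1) * s$fast_dt
    t_slow <- max(t_post) + seq_len(s$n_slow) * s$slow_dt
    times <- c(t_pre, t_post, t_slow)
    nf <- length(times)
    decay <- (1 - acq_decay_per_frame)^(seq_len(nf) - 1)
    tp <- times - times[s$n_prebleach + 1]
    rec <- 1 - bleach_depth * (1 - m * (1 - exp(-pmax(tp, 0) / tau_s)))
    rec[seq_len(s$n_prebleach)] <- 1
    nz <- function() rnorm(nf, 0, noise_sd * base)
    roi1 <- base * decay * rec + bg + nz()
    roi2 <- ref_base * decay + bg + nz()
    roi3 <- bg + nz()
    series <- frap_series(times, roi1, roi2, roi3, s$n_prebleach)
    truth <- list(m = m, tau_s = tau_s, half_time_s = tau_s * log(2),
                  bleach_depth = bleach_depth,
                  acq_decay_per_frame = acq_decay_per_frame,
                  noise_sd = noise_sd, schedule = s, seed = seed)
    list(series = series, truth = truth)
  })
}

# fixed empirical log-linear mobility law shared by make_gel and tests
gel_mobility <- function(size_bp, top_px = 30, span_px = 340,
                         size_range = c(50, 20000)) {
  if (any(size_bp < size_range[1] | size_bp > size_range[2]))
    stop("gel_mobility: fragment size outside the mobility-law domain [",
         size_range[1], ", ", size_range[2], "] bp")
  lr <- log10(size_range)
  top_px + span_px * (lr[2] - log10(size_bp)) / (lr[2] - lr[1])
}

#' Synthetic agarose gel image with known fragment-size mixtures
#'
#' Each sample lane is a mixture of fragment sizes with stated weights;
#' band centres follow a fixed empirical log-linear mobility law, bands
#' are Gaussian in migration position with SD `spread`, and integrated
#' band intensity is proportional to mixture weight. A ladder lane is
#' included. A constant background offset and Gaussian noise are added.
#'
#' @param lanes list of mixtures; each element is a list with `sizes` (bp)
#'   and `weights` (summing to 1)
#' @param ladder_sizes ladder fragment sizes in bp, decreasing
#' @param spread Gaussian band SD in px
#' @param snr peak band signal-to-noise ratio
#' @param seed RNG seed
#' @return list with `gel` (an [image2d()]), `annotations` (`ladder_rect`,
#'   `lane_rects` as 0-based rectangles, `ladder_sizes`), and `truth`
#' @export
make_gel <- function(lanes,
                     ladder_sizes = c(10000, 3000, 1000, 500, 100),
                     spread = 5, snr = 30, seed = NULL) {
  for (ln in lanes) {
    if (abs(sum(ln$weights) - 1) > 1e-8)
      stop("make_gel: lane weights must sum to 1")
    gel_mobility(ln$sizes)  # validates domain
  }
  gel_mobility(ladder_sizes)
  with_seed(seed, {
    height <- 420L
    lane_w <- 24L; gap <- 16L
    n_lanes <- length(lanes) + 1
    width <- as.integer(n_lanes * (lane_w + gap) + gap)
    img <- matrix(0, height, width)
    rowpos <- seq_len(height) - 1
    peak <- 100
    paint <- function(img, x0, sizes, weights) {
      prof <- numeric(height)
      for (i in seq_along(sizes)) {
        mu <- gel_mobility(sizes[i])
        prof <- prof + weights[i] * exp(-(rowpos - mu)^2 / (2 * spread^2))
      }
      prof <- prof / max(prof) * peak
      img[, (x0 + 1):(x0 + lane_w)] <-
        img[, (x0 + 1):(x0 + lane_w)] + prof
      img
    }
    x0s <- gap + (seq_len(n_lanes) - 1) * (lane_w + gap)
    img <- paint(img, x0s[1], ladder_sizes,
                 rep(1 / length(ladder_sizes), length(ladder_sizes)))
    for (i in seq_along(lanes))
      img <- paint(img, x0s[i + 1], lanes[[i]]$sizes, lanes[[i]]$weights)
    img <- img + 20 + matrix(rnorm(length(img), 0, peak / snr),
                             height, width)
    rect <- function(x0) c(x0, 0, lane_w, height)
    truth <- list(lanes = lanes, ladder_sizes = ladder_sizes,
                  spread = spread, snr = snr, seed = seed,
                  mobility = gel_mobility)
    list(gel = image2d(pmax(img, 0), 1),
         annotations = list(ladder_rect = rect(x0s[1]),
                            lane_rects = lapply(x0s[-1], rect),
                            ladder_sizes = ladder_sizes),
         truth = truth)
  })
}
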