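test_that("circularity matches analytic values for canonical shapes", {
  expect_equal(circularity(disc_mask(50))$circularity, 1.00,
               tolerance = 0.02)
  expect_equal(circularity(square_mask(100))$circularity, pi / 4,
               tolerance = 0.02 / (pi / 4))
  # 2:1 ellipse against numeric perimeter quadrature
  a <- 100; b <- 50
  truth <- 4 * pi * (pi * a * b) / ellipse_perimeter(a, b)^2
  expect_equal(circularity(ellipse_mask(a, b))$circularity, truth,
               tolerance = 0.02 / truth)
})

test_that("circularity is scale-invariant and orders shapes correctly", {
  el <- ellipse_mask(60, 30)
  up <- el[rep(seq_len(nrow(el)), each = 2), rep(seq_len(ncol(el)),
                                                 each = 2)]
  expect_equal(circularity(el)$circularity, circularity(up)$circularity,
               tolerance = 0.02)
  disc <- circularity(disc_mask(40))$circularity
  sq <- circularity(square_mask(70))$circularity
  el3 <- circularity(ellipse_mask(90, 30))$circularity
  expect_true(disc > sq && sq > el3)
  # physical scaling enters area and perimeter but not the ratio
  cc <- circularity(disc_mask(30), pixel_size = 0.2)
  expect_equal(cc$area, sum(disc_mask(30)) * 0.04)
  expect_error(circularity(matrix(c(1, 1, 1, 0), 2)), "9 px")
})

test_that("2D segmentation labels discs and flags empty images", {
  img <- matrix(5, 128, 128)
  img[20:40, 20:40] <- 120
  img[80:110, 70:100] <- 140
  lab <- segment_nuclei_2d(image2d(img, 0.2),
                           segmentation_params(min_volume = 1))
  expect_equal(n_objects(lab), 2)
  expect_warning(empty <- segment_nuclei_2d(flat_image(0, 64)),
                 "no foreground")
  expect_equal(n_objects(empty), 0)
})

test_that("2D segmentation recovers a field of disc centroids", {
  set.seed(21)
  n <- 256
  img <- matrix(3, n, n)
  centers <- expand.grid(y = seq(25, 235, by = 52),
                         x = seq(25, 235, by = 52))[1:20, ]
  for (i in 1:20) {
    yy <- centers$y[i]; xx <- centers$x[i]
    sel <- (row(img) - yy)^2 + (col(img) - xx)^2 <= 81
    img[sel] <- 150
  }
  img <- img + matrix(rnorm(n^2, 0, 2), n)
  lab <- segment_nuclei_2d(image2d(img, 1),
                           segmentation_params(min_volume = 10))
  expect_equal(n_objects(lab), 20)
  meas <- measure_shapes_2d(lab)
  # match measured centroids to ground truth within 1 px
  d <- sqrt(outer(meas$cy, centers$y - 1, "-")^2 +
              outer(meas$cx, centers$x - 1, "-")^2)
  expect_lt(max(apply(d, 2, min)), 1)
})

test_that("3D segmentation keeps one label per isolated object and splits
           an overlapping pair with the seed diameter", {
  st <- shape_stack(matrix(c(5, 6, 6), 1), matrix(c(3.1, 4, 4), 1),
                    c(10, 12, 12))
  lab <- segment_nuclei_3d(st, segmentation_params(min_volume = 5))
  expect_equal(n_objects(lab), 1)
  pair <- shape_stack(rbind(c(5, 5, 5), c(5, 5, 10)),
                      rbind(c(3, 3, 3), c(3, 3, 3)), c(10, 10, 15))
  split <- segment_nuclei_3d(pair, segmentation_params(
    seed_point_diameter = 4, min_volume = 5))
  expect_equal(n_objects(split), 2)
  # watershed conserves foreground voxels: with a manual threshold and no
  # smoothing the labelled volume equals the thresholded union volume
  exact <- segment_nuclei_3d(pair, segmentation_params(
    threshold = 0.5, seed_point_diameter = 4, min_volume = 0,
    surface_smoothing = 0))
  vols <- measure_volumes(exact)
  expect_equal(sum(vols$volume_um3),
               sum(pair$voxels > 0.5) * prod(c(0.25, 0.1, 0.1)))
  expect_error(voxel_grid(array(0, c(2, 2, 2)), c(0, 0.1, 0.1)),
               "positive")
})

test_that("volume measurement matches closed forms on the reference grid", {
  r <- 3.68
  m <- measure_volumes(segment_nuclei_3d(sphere_stack(r),
                                         segmentation_params(min_volume = 5)))
  expect_equal(m$volume_um3[1], 4 / 3 * pi * r^3,
               tolerance = 0.05)
  el <- shape_stack(matrix(c(4.6, 5.5, 5.5), 1),
                    matrix(c(3.1, 4.0, 4.0), 1), c(9.2, 11, 11))
  m2 <- measure_volumes(segment_nuclei_3d(el,
                                          segmentation_params(min_volume = 5)))
  expect_equal(m2$volume_um3[1], 4 / 3 * pi * 4.0 * 4.0 * 3.1,
               tolerance = 0.05)
})

test_that("sphere volume error is < 5% and shrinks with radius", {
  errs <- vapply(c(2, 3, 4, 6), function(r) {
    m <- measure_volumes(segment_nuclei_3d(
      sphere_stack(r), segmentation_params(min_volume = 1)))
    abs(m$volume_um3[1] - 4 / 3 * pi * r^3) / (4 / 3 * pi * r^3)
  }, 0)
  expect_true(all(errs < 0.05))
  expect_true(all(diff(errs) < 0))
})

test_that("QC flags mark border-clipped and unsplittable objects", {
  clipped <- shape_stack(matrix(c(5, 1.2, 5), 1),
                         matrix(c(3, 3, 3), 1), c(10, 10, 10))
  lab <- filter_objects(segment_nuclei_3d(clipped,
                                          segmentation_params(min_volume = 5)))
  expect_true(lab$flags$border_touching[1])
  interior <- filter_objects(segment_nuclei_3d(
    sphere_stack(3), segmentation_params(min_volume = 5)))
  expect_false(interior$flags$border_touching[1])
  expect_false(interior$flags$unresolved_merge[1])
  # a strongly overlapping pair (distinct cores, one saddle) cannot be
  # split at this seed diameter -> flagged
  merged <- shape_stack(rbind(c(5, 5, 5), c(5, 5, 9)),
                        rbind(c(3, 3, 3), c(3, 3, 3)), c(10, 10, 14.5))
  lab2 <- filter_objects(segment_nuclei_3d(merged, segmentation_params(
    seed_point_diameter = 5, min_volume = 5)))
  expect_equal(n_objects(lab2), 1)
  expect_true(any(lab2$flags$unresolved_merge))
})

test_that("nuclear_stats summarizes and compares populations", {
  mk <- function(v) {
    d <- data.frame(label = seq_along(v), volume_um3 = v,
                    border_touching = FALSE, unresolved_merge = FALSE)
    class(d) <- c("nucleus_measurements", "data.frame")
    d
  }
  s <- nuclear_stats(mk(c(200, 210, 220)))
  expect_equal(s$mean, 210)
  expect_equal(s$sd, 10)
  same <- nuclear_stats(mk(c(200, 210, 220)), mk(c(200, 210, 220)))
  expect_equal(same$t_test$p.value, 1)
  expect_error(nuclear_stats(mk(300)), "at least 2")
  # flagged objects are excluded from the population
  d <- mk(c(100, 110, 120, 9999))
  d$border_touching[4] <- TRUE
  expect_equal(nuclear_stats(d)$n, 3)
})

test_that("synthetic population recovery approaches the generating mean", {
  res <- recover_volumes(n = 12, volume_mean = 207, volume_sd = 58,
                         nuclei_per_scene = 6, seed = 31)
  expect_gte(res$n_measured, 9)
  # estimates match their matched ground-truth nuclei closely in the mean
  expect_equal(res$mean_estimate, mean(res$truth_matched),
               tolerance = 0.05)
})
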