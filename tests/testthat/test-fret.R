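# build a calibration acquisition directly from pixel arrays
cal_acq <- function(reg, fret, other = NULL) {
  zero <- image2d(matrix(0, nrow(reg), ncol(reg)))
  fret_acquisition(donor = image2d(reg), fret = image2d(fret),
                   acceptor = if (is.null(other)) zero else image2d(other),
                   registered = TRUE)
}

test_that("bleed-through slope is exact on noiseless linear data", {
  set.seed(1)
  D <- matrix(runif(10000, 100, 1000), 100)
  acq <- cal_acq(D, 0.25 * D)
  cal <- fit_bleedthrough(acq, noise_floor = 50)
  expect_equal(cal$x, 0.25, tolerance = 1e-12)
  expect_equal(cal$intercept, 0, tolerance = 1e-9)
  # acceptor-free sample with F == 0 gives x = 0
  cal0 <- fit_bleedthrough(cal_acq(D, D * 0), noise_floor = 50)
  expect_equal(cal0$x, 0)
})

test_that("calibration slopes recover within 0.02 over the slope x SNR
           grid at 1e4 pixels", {
  set.seed(2)
  D <- matrix(runif(10000, 200, 1000), 100)
  for (true in c(0.1, 0.25, 0.5)) {
    for (snr in c(10, 20)) {
      noise_sd <- mean(D) / snr
      Fch <- true * D + matrix(rnorm(10000, 0, noise_sd), 100)
      est <- fit_bleedthrough(cal_acq(D, Fch), noise_floor = 100)
      expect_lt(abs(est$x - true), 0.02)
    }
  }
  # the y-side fit is the mirror operation on the acceptor channel
  A <- matrix(runif(10000, 200, 1000), 100)
  Fch <- 0.10 * A + matrix(rnorm(10000, 0, 5), 100)
  acq <- fret_acquisition(donor = image2d(matrix(0, 100, 100)),
                          fret = image2d(Fch), acceptor = image2d(A),
                          registered = TRUE)
  est_y <- fit_crossexcitation(acq, noise_floor = 100)
  expect_lt(abs(est_y$y - 0.10), 0.01)
})

test_that("unsuitable calibration samples and tiny foregrounds error", {
  set.seed(3)
  D <- matrix(runif(10000, 200, 1000), 100)
  garbage <- matrix(rnorm(10000, 300, 200), 100)  # unrelated to D
  expect_error(fit_bleedthrough(cal_acq(D, garbage), noise_floor = 100),
               "unsuitable")
  expect_error(fit_bleedthrough(cal_acq(D, 0.2 * D), noise_floor = 990),
               "1000")
  # contaminated acceptor-only sample warns
  A <- matrix(runif(10000, 200, 1000), 100)
  acq <- fret_acquisition(donor = image2d(0.5 * A),
                          fret = image2d(0.1 * A), acceptor = image2d(A),
                          registered = TRUE)
  expect_warning(fit_crossexcitation(acq, noise_floor = 100),
                 "not negligible")
})

test_that("the index map implements (F - xD - yA)/A with an acceptor
           floor", {
  set.seed(4)
  D <- matrix(runif(2500, 200, 800), 50)
  A <- matrix(runif(2500, 200, 800), 50)
  cal <- structure(list(x = 0.25, y = 0.10, n_pixels = 2500, r2 = 1,
                        intercept = 0, robust = FALSE),
                   class = "bleedthrough_calibration")
  # F composed exactly from leakage and cross-excitation: index == 0
  acq <- fret_acquisition(image2d(D), image2d(0.25 * D + 0.10 * A),
                          image2d(A), registered = TRUE)
  res <- fret_index_map(acq, cal, acceptor_floor = 10)
  expect_equal(max(abs(res$index_map)), 0, tolerance = 1e-12)
  # D = 0, F = 0.2 A, y = 0: index == 0.2 everywhere
  cal2 <- structure(list(x = 0.25, y = 0, n_pixels = 2500, r2 = 1,
                         intercept = 0, robust = FALSE),
                    class = "bleedthrough_calibration")
  acq2 <- fret_acquisition(image2d(matrix(0, 50, 50)), image2d(0.2 * A),
                           image2d(A), registered = TRUE)
  res2 <- fret_index_map(acq2, cal2, acceptor_floor = 10)
  expect_equal(range(res2$index_map), c(0.2, 0.2), tolerance = 1e-12)
  # pixels at or below the floor are NA, not zero
  A3 <- A; A3[1:10, 1:10] <- 1
  acq3 <- fret_acquisition(image2d(D), image2d(0.2 * A3), image2d(A3),
                           registered = TRUE)
  res3 <- fret_index_map(acq3, cal2, acceptor_floor = 10)
  expect_true(all(is.na(res3$index_map[1:10, 1:10])))
  # contract errors
  raw <- fret_acquisition(image2d(D), image2d(A), image2d(A))
  expect_error(fret_index_map(raw, cal), "registered")
  expect_error(fret_index_map(acq, fit_bleedthrough(cal_acq(D, 0.25 * D),
                                                    noise_floor = 50)),
               "complete")
})

test_that("the index is exactly invariant to global intensity scaling", {
  set.seed(5)
  D <- matrix(runif(2500, 100, 900), 50)
  A <- matrix(runif(2500, 100, 900), 50)
  Fch <- 0.25 * D + 0.10 * A + 0.15 * A
  cal <- structure(list(x = 0.25, y = 0.10, n_pixels = 2500, r2 = 1,
                        intercept = 0, robust = FALSE),
                   class = "bleedthrough_calibration")
  mk <- function(c) fret_acquisition(image2d(c * D), image2d(c * Fch),
                                     image2d(c * A), registered = TRUE)
  i1 <- fret_index_map(mk(1), cal, acceptor_floor = 0)$index_map
  i2 <- fret_index_map(mk(3.7), cal, acceptor_floor = 0)$index_map
  expect_equal(i1, i2, tolerance = 1e-12)
})

test_that("per-cell means average defined pixels and drop starved masks", {
  idx <- matrix(0.1, 40, 40)
  masks <- matrix(0L, 40, 40)
  masks[5:20, 5:20] <- 1L
  idx[25:40, 25:40] <- 0.2
  masks[25:40, 25:40] <- 2L
  res <- structure(list(index_map = idx, acceptor_floor = 0,
                        calibration = NULL), class = "fret_result")
  pc <- mean_fret_per_cell(res, masks)
  expect_equal(pc$mean_index, c(0.1, 0.2))
  # half 0 / half 0.2 mask averages to 0.1
  idx2 <- matrix(c(0, 0.2), 40, 40)
  res2 <- structure(list(index_map = idx2, acceptor_floor = 0,
                         calibration = NULL), class = "fret_result")
  expect_equal(mean_fret_per_cell(res2, masks)$mean_index[1], 0.1)
  # a mask with < 50 defined pixels is dropped with a warning
  idx3 <- idx; idx3[masks == 1L] <- NA; idx3[5:6, 5:10] <- 0.3
  res3 <- structure(list(index_map = idx3, acceptor_floor = 0,
                         calibration = NULL), class = "fret_result")
  expect_warning(pc3 <- mean_fret_per_cell(res3, masks), "dropping")
  expect_equal(pc3$cell, 2L)
})

test_that("end-to-end scene recovery: sensitized emission, headless
           baseline, self-consistency", {
  run_scene <- function(seed, se) {
    sc <- make_fret_scene(24, se, x = 0.25, y = 0.10,
                          gradient_amplitude = 0.3,
                          shift_px = c(1.5, -2), snr = 20, seed = seed)
    bg <- background_spec("region", region = sc$truth$background_region)
    cal <- combine_calibration(
      fit_bleedthrough(prepare_fret(sc$donor_only, background = bg)),
      fit_crossexcitation(prepare_fret(sc$acceptor_only, background = bg)))
    res <- fret_index_map(prepare_fret(sc$sensor, background = bg), cal)
    list(cal = cal,
         cells = mean_fret_per_cell(res, sc$masks))
  }
  ts <- run_scene(101, 0.15)
  expect_equal(mean(ts$cells$mean_index), 0.15, tolerance = 0.01 / 0.15)
  expect_lt(abs(ts$cal$x - 0.25), 0.02)
  expect_lt(abs(ts$cal$y - 0.10), 0.02)
  hl <- run_scene(102, 0)
  expect_lt(abs(mean(hl$cells$mean_index)), 0.01)
})

test_that("the index is robust to an illumination gradient and to the
           order of registration and smoothing", {
  sc <- make_fret_scene(24, 0.15, x = 0.25, y = 0.10,
                        gradient_amplitude = 0.4, snr = 30, seed = 77)
  bg <- background_spec("region", region = sc$truth$background_region)
  cal <- combine_calibration(
    fit_bleedthrough(prepare_fret(sc$donor_only, background = bg)),
    fit_crossexcitation(prepare_fret(sc$acceptor_only, background = bg)))
  base_mean <- mean(mean_fret_per_cell(
    fret_index_map(prepare_fret(sc$sensor, background = bg), cal),
    sc$masks)$mean_index)
  expect_equal(base_mean, 0.15, tolerance = 0.01 / 0.15)
  # permuting smoothing and registration barely moves the mean index
  sm_first <- prepare_fret(
    prepare_fret(sc$sensor, background = bg, register = FALSE),
    register = TRUE, smooth = FALSE, illumination = FALSE)
  perm_mean <- mean(mean_fret_per_cell(
    fret_index_map(sm_first, cal), sc$masks)$mean_index)
  expect_lt(abs(perm_mean - base_mean), 0.005)
})

test_that("groups separated as tension-sensor vs headless are detected", {
  # per-cell means at the measured noise scale; 30 cells per arm
  set.seed(6)
  hits <- vapply(1:200, function(i) {
    ts <- rnorm(30, 0.15, 0.05)
    hl <- rnorm(30, 0.00, 0.05)
    compare_fret_groups(ts, hl)$p.value < 1e-4
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("perinuclear ring masks surround nuclei without overlap", {
  lab <- matrix(0L, 80, 80)
  lab[20:30, 20:30] <- 1L
  lab[50:62, 45:60] <- 2L
  rings <- perinuclear_masks(label_map(lab, 0.2))
  expect_equal(sort(unique(as.vector(rings$labels))), c(0L, 1L, 2L))
  # rings sit strictly outside the nuclei themselves
  expect_equal(sum(rings$labels > 0 & lab > 0), 0)
})
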