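test_that("lane normalization implements (I_n - I_b)/I_total", {
  gelpx <- matrix(1, 60, 40)
  gelpx[, 16:25] <- 5  # uniform lane of 5 over background 1
  lp <- extract_lane_profile(image2d(gelpx), c(15, 0, 10, 60))
  expect_equal(lp$normalized, rep(1 / 60, 60))
  expect_equal(lp$i_total, sum(lp$raw - lp$background))
  # all-background lane errors
  expect_error(extract_lane_profile(image2d(matrix(1, 60, 40)),
                                    c(15, 0, 10, 60)), "empty lane")
  expect_error(extract_lane_profile(image2d(gelpx), c(35, 0, 10, 60)),
               "outside|background")
})

test_that("normalization conserves unit mass and ignores exposure", {
  set.seed(15)
  for (i in 1:20) {
    w <- runif(1, 0.2, 0.8)
    g <- make_gel(list(list(sizes = c(300, 3000), weights = c(w, 1 - w))),
                  seed = 600 + i)
    lp <- extract_lane_profile(g$gel, g$annotations$lane_rects[[1]])
    expect_equal(sum(lp$normalized), 1, tolerance = 1e-9)
  }
  g <- make_gel(list(list(sizes = 1000, weights = 1)), seed = 16)
  lp1 <- extract_lane_profile(g$gel, g$annotations$lane_rects[[1]])
  bright <- image2d(g$gel$pixels * 2.7, g$gel$pixel_size)
  lp2 <- extract_lane_profile(bright, g$annotations$lane_rects[[1]])
  expect_equal(lp2$normalized, lp1$normalized, tolerance = 1e-12)
})

test_that("equal-mass double bands integrate to half each", {
  g <- make_gel(list(list(sizes = c(400, 2500), weights = c(0.5, 0.5))),
                snr = 50, seed = 17)
  lp <- extract_lane_profile(g$gel, g$annotations$lane_rects[[1]])
  bw <- band_weights(lp)
  expect_equal(nrow(bw), 2)
  expect_equal(bw$weight, c(0.5, 0.5), tolerance = 0.01 / 0.5)
})

test_that("ladder calibration is log-linear within its span only", {
  lp <- structure(list(positions = 0:400,
                       normalized = rep(1 / 401, 401), raw = rep(1, 401),
                       background = 0, i_total = 1, clipped_fraction = 0),
                  class = "lane_profile")
  cal <- structure(list(ladder_positions = c(100, 200, 300),
                        ladder_sizes = c(3000, 1000, 300)),
                   class = "size_calibration")
  expect_equal(predict(cal, 150), sqrt(3000 * 1000), tolerance = 1e-6)
  expect_true(is.na(predict(cal, 50)))
  expect_true(is.na(predict(cal, 350)))
  expect_error(calibrate_sizes(lp, c(1000, 3000)), "decreasing")
})

test_that("ladder band detection recovers the mobility law", {
  g <- make_gel(list(list(sizes = 1000, weights = 1)), seed = 18)
  lad <- extract_lane_profile(g$gel, g$annotations$ladder_rect)
  cal <- calibrate_sizes(lad, g$annotations$ladder_sizes)
  expect_equal(length(cal$ladder_positions), 5)
  # mean |log10 size error| < 0.05 over in-span positions
  pos <- seq(min(cal$ladder_positions), max(cal$ladder_positions))
  true_size <- 10^(log10(20000) - (pos - 30) / 340 * (log10(20000) -
                                                        log10(50)))
  err <- abs(log10(predict(cal, pos)) - log10(true_size))
  expect_lt(mean(err), 0.05)
})

test_that("size re-binning concentrates single bands and conserves mass", {
  g <- make_gel(list(list(sizes = 1000, weights = 1)), snr = 50,
                seed = 19)
  lad <- extract_lane_profile(g$gel, g$annotations$ladder_rect)
  cal <- calibrate_sizes(lad, g$annotations$ladder_sizes)
  lp <- extract_lane_profile(g$gel, g$annotations$lane_rects[[1]])
  dist <- size_distribution(lp, cal)
  expect_equal(sum(dist$mass), dist$mass_in_span, tolerance = 1e-6)
  mode_bin <- which.max(dist$mass)
  expect_equal(dist$bin_centers[mode_bin], 1000,
               tolerance = 0.15)
  # uniform profile: re-binned mass equals in-span mass exactly
  up <- structure(list(positions = 0:400,
                       normalized = rep(1 / 401, 401), raw = rep(1, 401),
                       background = 0, i_total = 1, clipped_fraction = 0),
                  class = "lane_profile")
  cal2 <- structure(list(ladder_positions = c(50, 350),
                         ladder_sizes = c(10000, 100)),
                    class = "size_calibration")
  expect_warning(d2 <- size_distribution(up, cal2), "outside")
  expect_equal(sum(d2$mass), 301 / 401, tolerance = 1e-9)
})

test_that("a 70/30 size mixture is recovered within 3%", {
  g <- make_gel(list(list(sizes = c(200, 2000), weights = c(0.7, 0.3))),
                seed = 20)
  lp <- extract_lane_profile(g$gel, g$annotations$lane_rects[[1]])
  bw <- band_weights(lp)
  cal <- calibrate_sizes(extract_lane_profile(g$gel,
                                              g$annotations$ladder_rect),
                         g$annotations$ladder_sizes)
  sizes <- predict(cal, bw$position_px)
  w200 <- bw$weight[which.min(abs(sizes - 200))]
  expect_equal(w200, 0.7, tolerance = 0.03 / 0.7)
})

test_that("accessibility summary orders digested vs protected lanes", {
  g <- make_gel(list(list(sizes = c(300, 800), weights = c(0.6, 0.4)),
                     list(sizes = c(2000, 5000), weights = c(0.5, 0.5))),
                seed = 21)
  lad <- extract_lane_profile(g$gel, g$annotations$ladder_rect)
  cal <- calibrate_sizes(lad, g$annotations$ladder_sizes)
  edges <- 10^seq(2, 4, length.out = 41)
  dA <- size_distribution(extract_lane_profile(
    g$gel, g$annotations$lane_rects[[1]]), cal, bin_edges = edges)
  dB <- size_distribution(extract_lane_profile(
    g$gel, g$annotations$lane_rects[[2]]), cal, bin_edges = edges)
  cmp <- accessibility_summary(dA, dB)
  expect_gt(cmp$a$score, cmp$b$score)
  expect_lt(cmp$median_diff_bp, 0)
  same <- accessibility_summary(dA, dA)
  expect_equal(same$score_diff, 0)
  expect_equal(same$median_diff_bp, 0)
  dC <- size_distribution(extract_lane_profile(
    g$gel, g$annotations$lane_rects[[2]]), cal,
    bin_edges = 10^seq(2, 4, length.out = 21))
  expect_error(accessibility_summary(dA, dC), "grids")
})

test_that("the digestion contrast keeps its sign across noise seeds", {
  signs <- vapply(1:50, function(s) {
    g <- make_gel(list(list(sizes = c(500, 900), weights = c(0.4, 0.6)),
                       list(sizes = c(2500, 4000),
                            weights = c(0.5, 0.5))),
                  seed = 700 + s)
    cal <- calibrate_sizes(extract_lane_profile(
      g$gel, g$annotations$ladder_rect), g$annotations$ladder_sizes)
    edges <- 10^seq(2, 4, length.out = 41)
    dA <- size_distribution(extract_lane_profile(
      g$gel, g$annotations$lane_rects[[1]]), cal, bin_edges = edges)
    dB <- size_distribution(extract_lane_profile(
      g$gel, g$annotations$lane_rects[[2]]), cal, bin_edges = edges)
    sign(accessibility_summary(dA, dB)$score_diff)
  }, 0)
  expect_true(all(signs == 1))
})
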