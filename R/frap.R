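#' Raw three-ROI FRAP traces
#'
#' `roi1` is the bleached spot, `roi2` an unbleached reference nucleus
#' (tracking acquisition photobleaching), `roi3` the background. Times are
#' seconds from the first acquisition; frames acquired during the bleach
#' interval itself are absent by design, so the gap shows up as a jump in
#' the timestamps.
#'
#' @param times strictly increasing acquisition times (s)
#' @param roi1,roi2,roi3 equal-length intensity traces
#' @param n_prebleach number of pre-bleach frames (>= 1; the reference
#'   protocol uses 3)
#' @return an object of class `frap_series`
#' @export
frap_series <- function(times, roi1, roi2, roi3, n_prebleach = 3) {
  n <- length(times)
  if (length(roi1) != n || length(roi2) != n || length(roi3) != n)
    stop("frap_series: traces must have equal length")
  if (any(diff(times) <= 0))
    stop("frap_series: times must be strictly increasing")
  if (n_prebleach < 1) stop("frap_series: n_prebleach must be >= 1")
  if (n_prebleach >= n)
    stop("frap_series: no post-bleach frames")
  if (any(roi2 <= roi3))
    stop("frap_series: reference ROI must exceed background at every frame")
  structure(list(times = as.numeric(times), roi1 = as.numeric(roi1),
                 roi2 = as.numeric(roi2), roi3 = as.numeric(roi3),
                 n_prebleach = as.integer(n_prebleach)),
            class = "frap_series")
}

#' @export
print.frap_series <- function(x, ...) {
  cat(sprintf("<frap_series> %d frames (%d pre-bleach), t = %.2f..%.2f s\n",
              length(x$times), x$n_prebleach, min(x$times), max(x$times)))
  invisible(x)
}

#' Read FRAP traces from CSV
#'
#' Expects columns `time_s, roi1, roi2, roi3` (header required).
#'
#' @param path CSV file
#' @param n_prebleach number of pre-bleach frames
#' @return a [frap_series()]
#' @export
read_frap_csv <- function(path, n_prebleach = 3) {
  d <- read.csv(path)
  need <- c("time_s", "roi1", "roi2", "roi3")
  if (!all(need %in% names(d)))
    stop("read_frap_csv: need columns ", paste(need, collapse = ", "))
  frap_series(d$time_s, d$roi1, d$roi2, d$roi3, n_prebleach)
}

#' Double-normalize a FRAP series
#'
#' First each frame is corrected for background and acquisition
#' photobleaching via the reference ROI,
#' `I_t = (ROI1 - ROI3) / (ROI2 - ROI3)`; any intensity decay that affects
#' the bleached and reference nuclei equally cancels in this ratio. The
#' curve is then rescaled by the pre-bleach average `I_ave` (mean `I_t`
#' over the pre-bleach frames) and the first post-bleach value `I_4`:
#' `I = (I_t - I_4) / (I_ave - I_4)`. By construction `I` is exactly 0 at
#' the first post-bleach frame and averages exactly 1 over the pre-bleach
#' frames; full recovery corresponds to `I = 1`. Pre-bleach frames are
#' carried through the same transform rather than pinned to 1, so those
#' anchors are testable.
#'
#' @param series a [frap_series()]
#' @return an object of class `frap_curve` with `times`, `I`, `I_t`,
#'   `I_ave`, `I_4`, `n_prebleach`
#' @export
normalize_frap <- function(series) {
  stopifnot(inherits(series, "frap_series"))
  It <- (series$roi1 - series$roi3) / (series$roi2 - series$roi3)
  np <- series$n_prebleach
  I_ave <- mean(It[seq_len(np)])
  I_4 <- It[np + 1]
  if (I_ave <= I_4)
    stop("normalize_frap: no detectable bleach (I_ave <= I_4)")
  I <- (It - I_4) / (I_ave - I_4)
  structure(list(times = series$times, I = I, I_t = It, I_ave = I_ave,
                 I_4 = I_4, n_prebleach = np),
            class = "frap_curve")
}

#' @export
print.frap_curve <- function(x, ...) {
  post <- x$I[-seq_len(x$n_prebleach)]
  cat(sprintf(
    "<frap_curve> %d frames, I_ave = %.4f, I_4 = %.4f, plateau ~ %.3f\n",
    length(x$I), x$I_ave, x$I_4, mean(tail(post, 5))))
  invisible(x)
}

#' @export
plot.frap_curve <- function(x, ...) {
  plot(x$times, x$I, xlab = "time (s)", ylab = "normalized intensity I",
       pch = 16, ...)
  graphics::abline(h = c(0, 1), lty = 3)
  graphics::abline(v = x$times[x$n_prebleach + 1], lty = 2, col = "grey40")
  invisible(x)
}

#' Fit a single-exponential recovery and summarize mobility
#'
#' Fits `I(t') = m * (1 - exp(-t'/tau))` to the post-bleach frames by
#' nonlinear least squares, with `t'` zeroed at the first post-bleach
#' frame. `m` is the mobile fraction (plateau) and `tau * ln 2` the
#' recovery half-time. The single-exponential is the simplest model for
#' one bleached compartment and is used as a comparison statistic, not as
#' a diffusion model. Mobile fractions above 1 are flagged; above 1.2 the
#' fit is rejected.
#'
#' @param curve a [frap_curve()] with at least 10 post-bleach frames
#' @return object of class `frap_fit` with `mobile_fraction`, `tau`,
#'   `half_time`, `flagged`, and the underlying `nls` fit
#' @export
recovery_stats <- function(curve) {
  stopifnot(inherits(curve, "frap_curve"))
  np <- curve$n_prebleach
  post <- seq.int(np + 1, length(curve$I))
  if (length(post) < 10)
    stop("recovery_stats: need >= 10 post-bleach frames")
  tt <- curve$times[post] - curve$times[np + 1]
  yy <- curve$I[post]
  plateau <- mean(tail(yy, max(3, length(yy) %/% 5)))
  if (plateau <= 0.01) {
    # immobile sample: no recovery to fit
    out <- list(mobile_fraction = max(plateau, 0), tau = NA_real_,
                half_time = NA_real_, flagged = FALSE, fit = NULL,
                times = tt, I = yy)
    class(out) <- "frap_fit"
    return(out)
  }
  t_half_guess <- {
    above <- which(yy >= plateau / 2)
    if (length(above)) max(tt[above[1]], tt[2] / 2) else max(tt) / 4
  }
  start <- list(m = plateau, tau = t_half_guess / log(2))
  fit <- tryCatch(
    minpack.lm::nlsLM(yy ~ m * (1 - exp(-tt / tau)), start = start,
                      lower = c(m = 0, tau = 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    resid0 <- yy - start$m * (1 - exp(-tt / (start$tau)))
    stop("recovery_stats: recovery fit did not converge (", fit$message,
         "); residual SD at start values = ", signif(sd(resid0), 3))
  }
  cf <- coef(fit)
  if (cf[["m"]] > 1.2)
    stop("recovery_stats: fitted mobile fraction ", signif(cf[["m"]], 3),
         " exceeds 1.2; curve is not a plausible recovery")
  out <- list(mobile_fraction = unname(cf[["m"]]),
              tau = unname(cf[["tau"]]),
              half_time = unname(cf[["tau"]]) * log(2),
              flagged = cf[["m"]] > 1, fit = fit, times = tt, I = yy)
  class(out) <- "frap_fit"
  out
}

#' @export
print.frap_fit <- function(x, ...) {
  cat("<frap_fit> single-exponential recovery\n")
  cat(sprintf("  mobile fraction m : %.4f%s\n", x$mobile_fraction,
              if (isTRUE(x$flagged)) " (> 1, flagged)" else ""))
  if (is.finite(x$half_time))
    cat(sprintf("  half-time t1/2    : %.3f s (tau = %.3f s)\n",
                x$half_time, x$tau))
  else cat("  no recovery (immobile)\n")
  invisible(x)
}

#' @export
coef.frap_fit <- function(object, ...)
  c(mobile_fraction = object$mobile_fraction, tau = object$tau,
    half_time = object$half_time)

#' @export
predict.frap_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) times <- object$times
  if (!is.finite(object$tau)) return(rep(object$mobile_fraction,
                                         length(times)))
  object$mobile_fraction * (1 - exp(-times / object$tau))
}

#' @export
residuals.frap_fit <- function(object, ...)
  object$I - predict(object)

#' @export
plot.frap_fit <- function(x, ...) {
  plot(x$times, x$I, pch = 16, xlab = "time post-bleach (s)",
       ylab = "normalized intensity I", ...)
  tt <- seq(0, max(x$times), length.out = 200)
  graphics::lines(tt, predict(x, tt), col = "red3", lwd = 2)
  invisible(x)
}

#' Extract three-ROI traces from an image time series
#'
#' Computes the mean intensity of the bleach, reference and background
#' rectangles in every frame. The acquisition schedule is read from the
#' supplied timestamps, never assumed.
#'
#' @param frames list of [image2d()]s (or matrices), one per time point
#' @param times acquisition times in seconds
#' @param roi1,roi2,roi3 rectangles `c(x0, y0, width, height)`, 0-based
#'   pixel units; must be pairwise non-overlapping and inside the image
#' @param n_prebleach number of pre-bleach frames
#' @return a [frap_series()]
#' @export
extract_rois_from_images <- function(frames, times, roi1, roi2, roi3,
                                     n_prebleach = 3) {
  mats <- lapply(frames, function(f)
    if (inherits(f, "image2d")) f$pixels else as.matrix(f))
  dims <- dim(mats[[1]])
  rects <- list(roi1 = roi1, roi2 = roi2, roi3 = roi3)
  for (nm in names(rects)) {
    r <- rects[[nm]]
    if (length(r) != 4 || r[3] <= 0 || r[4] <= 0)
      stop("extract_rois_from_images: ", nm,
           " must be c(x0, y0, width, height)")
    if (r[1] < 0 || r[2] < 0 || r[1] + r[3] > dims[2] ||
        r[2] + r[4] > dims[1])
      stop("extract_rois_from_images: ", nm, " lies outside the image")
  }
  overlap <- function(a, b)
    a[1] < b[1] + b[3] && b[1] < a[1] + a[3] &&
    a[2] < b[2] + b[4] && b[2] < a[2] + a[4]
  if (overlap(roi1, roi2) || overlap(roi1, roi3) || overlap(roi2, roi3))
    stop("extract_rois_from_images: ROIs must not overlap")
  roi_mean <- function(m, r)
    mean(m[(r[2] + 1):(r[2] + r[4]), (r[1] + 1):(r[1] + r[3])])
  tr <- vapply(mats, function(m)
    c(roi_mean(m, roi1), roi_mean(m, roi2), roi_mean(m, roi3)),
    numeric(3))
  frap_series(times, tr[1, ], tr[2, ], tr[3, ], n_prebleach)
}

#' Write a normalized FRAP curve to CSV
#'
#' @param curve a [frap_curve()]
#' @param path output CSV
#' @return the path, invisibly
#' @export
write_frap_csv <- function(curve, path) {
  write.csv(data.frame(time_s = curve$times, I_t = curve$I_t, I = curve$I),
            path, row.names = FALSE)
  invisible(path)
}
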