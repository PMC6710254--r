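# Per-frame gel area measurement: gradient-based circle fitting or
# threshold segmentation, with smoothing of the resulting area signal.

# Gradient magnitude by central differences (edges one-sided).
gradient_magnitude <- function(frame) {
  h <- nrow(frame); w <- ncol(frame)
  gy <- frame; gx <- frame
  gy[2:(h - 1), ] <- (frame[3:h, ] - frame[1:(h - 2), ]) / 2
  gy[1, ] <- frame[2, ] - frame[1, ]; gy[h, ] <- frame[h, ] - frame[h - 1, ]
  gx[, 2:(w - 1)] <- (frame[, 3:w] - frame[, 1:(w - 2)]) / 2
  gx[, 1] <- frame[, 2] - frame[, 1]; gx[, w] <- frame[, w] - frame[, w - 1]
  sqrt(gx^2 + gy^2)
}

# Bilinear interpolation of matrix m at (row, col) points.
bilinear <- function(m, r, c) {
  h <- nrow(m); w <- ncol(m)
  r <- clip01(r, 1, h - 1e-9); c <- clip01(c, 1, w - 1e-9)
  r0 <- pmin(floor(r), h - 1); c0 <- pmin(floor(c), w - 1)
  fr <- r - r0; fc <- c - c0
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    m[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    m[cbind(r0 + 1, c0 + 1)] * fr * fc
}

#' Fit a circle to the gel outline by the gradient method
#'
#' Finds the circle whose perimeter maximizes the mean image-gradient
#' magnitude: the center is seeded at the gradient-weighted centroid, the
#' radius is scanned on a coarse grid, and (center, radius) are then
#' refined by Nelder-Mead. The fit fails (detection-failure error) when the
#' best perimeter-mean gradient does not exceed three times the global mean
#' gradient -- the case for edge-free (uniform or pure-noise) frames.
#'
#' @param frame 8-bit intensity matrix containing one roughly circular
#'   bright-vs-dark region.
#' @return A `circle_fit`: `center_x` (col), `center_y` (row), `radius`
#'   (px), `score` (perimeter-mean gradient) and `residual` (sd/mean of the
#'   gradient along the fitted perimeter; small for a clean circular edge).
#' @export
fit_circle <- function(frame) {
  g <- gradient_magnitude(frame)
  gsum <- sum(g)
  if (gsum <= 0) gs_stop("frame has no intensity edges", "detection_failure")
  h <- nrow(frame); w <- ncol(frame)
  cy <- sum(seq_len(h) * rowSums(g)) / gsum
  cx <- sum(seq_len(w) * colSums(g)) / gsum

  perim <- function(p) {
    n <- max(24L, ceiling(2 * pi * p[3]))
    a <- seq(0, 2 * pi, length.out = n + 1)[-1]
    bilinear(g, p[2] + p[3] * sin(a), p[1] + p[3] * cos(a))
  }
  score <- function(p) {
    if (p[3] < 3 || p[1] - p[3] < 1 || p[1] + p[3] > w ||
        p[2] - p[3] < 1 || p[2] + p[3] > h) return(-Inf)
    mean(perim(p))
  }
  radii <- seq(4, floor(min(h, w) / 2) - 1, by = 2)
  sc <- vapply(radii, function(r) score(c(cx, cy, r)), numeric(1))
  r0 <- radii[which.max(sc)]
  opt <- stats::optim(c(cx, cy, r0), function(p) -score(p),
                      method = "Nelder-Mead",
                      control = list(maxit = 400, reltol = 1e-8))
  p <- opt$par
  best <- score(p)
  floor_level <- 3 * mean(g)
  if (!is.finite(best) || best < floor_level || best < 1e-8)
    gs_stop("no circle with perimeter gradient above the noise floor",
            "detection_failure")
  pv <- perim(p)
  structure(list(center_x = p[1], center_y = p[2], radius = p[3],
                 score = best, residual = stats::sd(pv) / mean(pv)),
            class = "circle_fit")
}

#' Gel area by threshold segmentation
#'
#' Splits the frame into gel and background at an Otsu or fixed threshold
#' and returns the number of gel-side ("white") pixels as the area measure.
#' Polarity is auto-detected from the frame border (the border majority is
#' taken as background, the gel being an interior object) and can be
#' overridden.
#'
#' @param frame 8-bit intensity matrix.
#' @param method `"otsu"` or `"fixed"`.
#' @param fixed_level Threshold intensity, required for `method = "fixed"`.
#' @param gel_bright `TRUE`/`FALSE` to force polarity; `NA` (default)
#'   auto-detects from border pixels.
#' @return Integer pixel count. A frame with no intensity contrast returns
#'   `0`.
#' @export
threshold_area <- function(frame, method = c("otsu", "fixed"),
                           fixed_level = NULL, gel_bright = NA) {
  method <- match.arg(method)
  if (method == "fixed" && is.null(fixed_level))
    gs_stop("`fixed_level` is required for method = \"fixed\"",
            "invalid_parameter")
  rng <- range(frame)
  if (method == "otsu") {
    if (diff(rng) < 1e-9) return(0L)  # degenerate: no contrast to split
    thr <- EBImage::otsu(EBImage::Image(frame / 255), range = c(0, 1)) * 255
  } else thr <- fixed_level
  bright <- frame > thr
  if (is.na(gel_bright)) {
    border <- c(frame[1, ], frame[nrow(frame), ], frame[, 1], frame[, ncol(frame)])
    gel_bright <- mean(border > thr) < 0.5
  }
  sum(if (gel_bright) bright else !bright)
}

#' Track gel area over an aligned frame series
#'
#' Measures the projected gel area per frame with either the threshold
#' method (Otsu, the default; fast and used for cycling experiments) or the
#' gradient circle fit (`area = pi * radius^2`), converts to physical units
#' via the calibration, linearly interpolates failed frames (flagging
#' them), and Gaussian-smooths the area signal (sigma in samples; the
#' reference choice for 0.9 frames/s switching videos is sigma = 50).
#'
#' @param series An `aligned_series` (or a bare `frame_series`, in which
#'   case temperatures are absent).
#' @param method `"threshold"` or `"circle"`.
#' @param calibration A `calibration_result`, or a numeric pixel size; `NULL`
#'   uses the series' own pixel size (areas in px^2 if that is unknown).
#' @param sigma Smoothing sd in samples for `area_smooth`.
#' @param ... Passed to [threshold_area()] or [fit_circle()].
#' @return An `area_trace` with raw and smoothed areas, per-frame flags for
#'   interpolated frames, and temperatures when available. Fails
#'   (tracking-failure error) if more than 20% of frames cannot be
#'   measured.
#' @export
track_area <- function(series, method = c("threshold", "circle"),
                       calibration = NULL, sigma = 50, ...) {
  method <- match.arg(method)
  if (inherits(series, "aligned_series")) {
    fs <- series$frames; temps <- series$frame_temps
  } else if (inherits(series, "frame_series")) {
    fs <- series; temps <- NULL
  } else gs_stop("`series` must be a frame_series or aligned_series",
                 "invalid_parameter")
  px <- if (inherits(calibration, "calibration_result")) calibration$pixel_size
        else if (is.numeric(calibration)) calibration
        else fs$pixel_size
  unit_factor <- if (is.finite(px)) px^2 else 1

  n <- length(fs$frames)
  area <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    a <- tryCatch({
      if (method == "threshold") threshold_area(fs$frames[[i]], ...)
      else { cf <- fit_circle(fs$frames[[i]]); pi * cf$radius^2 }
    }, gelswitch_error = function(e) NA_real_)
    if (!is.na(a) && a <= 0) a <- NA_real_  # empty segmentation = failed frame
    area[i] <- a
  }
  flags <- is.na(area)
  if (mean(flags) > 0.2)
    gs_stop(sprintf("%.0f%% of frames failed area measurement", 100 * mean(flags)),
            "tracking_failure")
  area <- interp_na(area, fs$times) * unit_factor
  new_area_trace(fs$times, temps, area,
                 area_smooth = gaussian_smooth(area, sigma),
                 sigma_used = sigma, method_label = method, flags = flags)
}

#' Write an area trace as CSV
#'
#' Columns: `time_s`, `temperature_C` (NA when unaligned), `area_cm2_raw`,
#' `area_cm2_smooth`, `method`, `flag` (TRUE for interpolated frames).
#'
#' @param trace An `area_trace`.
#' @param path Output CSV path.
#' @export
write_area_trace <- function(trace, path) {
  utils::write.csv(data.frame(
    time_s = trace$times,
    temperature_C = if (is.null(trace$temps)) NA_real_ else trace$temps,
    area_cm2_raw = trace$area_raw,
    area_cm2_smooth = if (is.null(trace$area_smooth)) NA_real_ else trace$area_smooth,
    method = trace$method_label,
    flag = trace$flags
  ), path, row.names = FALSE)
  invisible(path)
}
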