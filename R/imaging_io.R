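# Image-sequence and temperature-log I/O, ROI cropping, brightness
# adjustment, pixel-size calibration and frame/temperature alignment.

DEFAULT_FPS <- 0.9  # camera acquisition rate, frames per second

read_one_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- tryCatch(
    switch(ext,
           png = png::readPNG(path),
           tif = ,
           tiff = tiff::readTIFF(path, all = TRUE),
           gs_stop(sprintf("unsupported image format '%s' (%s)", ext, path),
                   "io")),
    error = function(e)
      gs_stop(sprintf("cannot read image file '%s': %s", path,
                      conditionMessage(e)), "io"))
  if (is.list(img)) lapply(img, to_gray8) else list(to_gray8(img))
}

# Convert a [0,1] raster (possibly multi-channel) to 8-bit grayscale using
# ITU-R BT.601 luma weights.
to_gray8 <- function(img) {
  if (length(dim(img)) == 3) {
    nc <- dim(img)[3]
    img <- if (nc >= 3)
      0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    else img[, , 1]
  }
  round(clip01(img * 255, 0, 255))
}

#' Load an image sequence as a calibrated frame series
#'
#' Reads a directory of PNG/TIFF frames (sorted lexicographically), an
#' explicit vector of file paths, or a single (possibly multi-page) image
#' file; converts frames to 8-bit grayscale (BT.601 luma for color input),
#' crops to a region of interest and applies a constant brightness offset
#' with clipping to the 8-bit range. Frame times are taken from a sidecar
#' `frames.csv` (columns `frame_index`, `time_s`) next to the frames when
#' present, otherwise from the constant acquisition rate `fps` (default
#' 0.9 frames/s).
#'
#' @param source Directory, file pattern (glob), character vector of image
#'   paths, or a single multi-page TIFF.
#' @param roi Optional pixel rectangle `c(row_min, row_max, col_min,
#'   col_max)`; must lie inside the frame.
#' @param brightness_offset Constant added to all intensities, then clipped
#'   to \[0, 255\].
#' @param fps Acquisition rate used when no sidecar timing exists.
#' @param pixel_size Optional physical pixel size to attach (otherwise read
#'   from a sidecar `meta.json` if present, else `NA`).
#' @return A `frame_series`.
#' @export
load_frames <- function(source, roi = NULL, brightness_offset = 0,
                        fps = DEFAULT_FPS, pixel_size = NULL) {
  sidecar_dir <- NULL
  if (length(source) == 1 && dir.exists(source)) {
    sidecar_dir <- source
    files <- list.files(source, pattern = "\\.(png|tif|tiff)$",
                        ignore.case = TRUE, full.names = TRUE)
    files <- sort(files)
  } else if (length(source) == 1 && grepl("[*?]", source)) {
    files <- sort(Sys.glob(source))
    if (length(files)) sidecar_dir <- dirname(files[1])
  } else {
    files <- source
    if (length(files)) sidecar_dir <- dirname(files[1])
  }
  if (length(files) == 0 || !all(file.exists(files)))
    gs_stop(sprintf("no readable frames found for source '%s'",
                    paste(source, collapse = ", ")), "io")
  frames <- unlist(lapply(files, read_one_image), recursive = FALSE)

  if (!is.null(roi)) {
    d <- dim(frames[[1]])
    if (length(roi) != 4 || roi[1] < 1 || roi[3] < 1 ||
        roi[2] > d[1] || roi[4] > d[2] || roi[1] > roi[2] || roi[3] > roi[4])
      gs_stop("`roi` must be c(row_min, row_max, col_min, col_max) inside the frame",
              "invalid_parameter")
    frames <- lapply(frames, function(f) f[roi[1]:roi[2], roi[3]:roi[4], drop = FALSE])
  }
  if (brightness_offset != 0)
    frames <- lapply(frames, function(f) clip01(f + brightness_offset, 0, 255))

  n <- length(frames)
  times <- (seq_len(n) - 1) / fps
  meta <- list(source = paste(files[1], "..."), timing = "constant rate")
  sidecsv <- if (!is.null(sidecar_dir)) file.path(sidecar_dir, "frames.csv") else ""
  if (nzchar(sidecsv) && file.exists(sidecsv)) {
    sc <- utils::read.csv(sidecsv)
    if (!is.null(sc$time_s) && nrow(sc) >= n) {
      times <- sc$time_s[seq_len(n)]
      meta$timing <- "sidecar CSV"
    }
  }
  metajson <- if (!is.null(sidecar_dir)) file.path(sidecar_dir, "meta.json") else ""
  if (is.null(pixel_size) && nzchar(metajson) && file.exists(metajson)) {
    mj <- jsonlite::read_json(metajson)
    if (!is.null(mj$pixel_size)) pixel_size <- as.numeric(mj$pixel_size)
  }
  new_frame_series(frames, times,
                   pixel_size = if (is.null(pixel_size)) NA_real_ else pixel_size,
                   meta = meta)
}

#' Write a frame series to disk
#'
#' Writes numbered, zero-padded 8-bit grayscale PNG frames plus a sidecar
#' `frames.csv` (`frame_index`, `time_s` and, when available,
#' `temperature_C`) and a `meta.json` carrying the pixel size, seed and any
#' generator truth parameters.
#'
#' @param fs A `frame_series`.
#' @param dir Output directory (created if needed).
#' @param temps Optional per-frame temperatures for the sidecar.
#' @return Invisibly, the paths written.
#' @export
write_frames <- function(fs, dir, temps = NULL) {
  stopifnot(inherits(fs, "frame_series"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(fs$frames)
  paths <- file.path(dir, sprintf("frame_%05d.png", seq_len(n)))
  for (i in seq_len(n)) png::writePNG(fs$frames[[i]] / 255, paths[i])
  sc <- data.frame(frame_index = seq_len(n), time_s = fs$times)
  if (!is.null(temps)) sc$temperature_C <- temps
  utils::write.csv(sc, file.path(dir, "frames.csv"), row.names = FALSE)
  jsonlite::write_json(c(list(pixel_size = fs$pixel_size), fs$meta),
                       file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(c(paths, file.path(dir, c("frames.csv", "meta.json"))))
}

#' Calibrate physical pixel size from a reference object
#'
#' Determines the physical pixel size from a reference object of known
#' physical extent visible in a frame: either from a user-supplied bounding
#' box, or by automatically locating a dark, square, filled connected
#' component (the rendered calibration square). The area conversion factor
#' is `pixel_size^2`.
#'
#' @param frame 8-bit intensity matrix.
#' @param reference_extent_physical Known physical side length of the
#'   reference object (same unit as the returned pixel size).
#' @param locator `"auto"` or a bounding box `c(row_min, row_max, col_min,
#'   col_max)`.
#' @return A `calibration_result`: `pixel_size`, `reference_object_px`,
#'   `reference_object_physical`.
#' @export
calibrate <- function(frame, reference_extent_physical, locator = "auto") {
  if (reference_extent_physical <= 0)
    gs_stop("`reference_extent_physical` must be positive", "invalid_parameter")
  if (is.numeric(locator)) {
    if (length(locator) != 4 || locator[2] <= locator[1] || locator[4] <= locator[3])
      gs_stop("degenerate reference bounding box", "invalid_parameter")
    side_px <- mean(c(locator[2] - locator[1] + 1, locator[4] - locator[3] + 1))
  } else {
    # auto: scan candidate thresholds for a dark, square, filled blob
    rng <- max(frame) - min(frame)
    side_px <- NA_real_
    for (f in c(0.05, 0.1, 0.15, 0.25, 0.4)) {
      mask <- frame <= min(frame) + f * rng
      if (!any(mask) || mean(mask) > 0.5) next
      labm <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
      for (id in setdiff(unique(as.vector(labm)), 0)) {
        idx <- which(labm == id, arr.ind = TRUE)
        hh <- diff(range(idx[, 1])) + 1
        ww <- diff(range(idx[, 2])) + 1
        fill <- nrow(idx) / (hh * ww)
        aspect <- min(hh, ww) / max(hh, ww)
        if (fill >= 0.9 && aspect >= 0.85 && min(hh, ww) >= 4) {
          side_px <- mean(c(hh, ww)); break
        }
      }
      if (!is.na(side_px)) break
    }
    if (is.na(side_px))
      gs_stop("auto locator found no square reference candidate",
              "detection_failure")
  }
  structure(list(pixel_size = reference_extent_physical / side_px,
                 reference_object_px = side_px,
                 reference_object_physical = reference_extent_physical),
            class = "calibration_result")
}

#' Align a frame series with a temperature profile
#'
#' Assigns each frame the stage temperature at its timestamp by linear
#' interpolation of the temperature log. Frames outside the profile's time
#' span by more than one profile sampling interval raise an alignment
#' error; frames within that tolerance take the nearest endpoint value.
#'
#' @param frames A `frame_series`.
#' @param profile A `temperature_profile`.
#' @return An `aligned_series`: the frame series plus `frame_temps`.
#' @export
align_temperature <- function(frames, profile) {
  stopifnot(inherits(frames, "frame_series"),
            inherits(profile, "temperature_profile"))
  dtp <- stats::median(diff(profile$times))
  lo <- min(profile$times); hi <- max(profile$times)
  ft <- frames$times
  if (any(ft < lo - dtp) || any(ft > hi + dtp))
    gs_stop("frame times extend beyond the temperature profile span", "alignment")
  temps <- stats::approx(profile$times, profile$temps, xout = clip01(ft, lo, hi))$y
  structure(list(frames = frames, frame_temps = temps, profile = profile),
            class = "aligned_series")
}

#' Read / write a temperature log CSV
#'
#' The log dialect is a plain CSV with header `time_s,temperature_C`,
#' decimal point and comma separator.
#'
#' @param path File path.
#' @return For `read_temperature_log`, a `temperature_profile` (with an
#'   empty segment table).
#' @export
read_temperature_log <- function(path) {
  if (!file.exists(path)) gs_stop(sprintf("no such file '%s'", path), "io")
  d <- utils::read.csv(path)
  if (!all(c("time_s", "temperature_C") %in% names(d)))
    gs_stop("temperature log must have columns time_s,temperature_C", "format")
  new_temperature_profile(d$time_s, d$temperature_C,
                          protocol_label = basename(path),
                          segments = data.frame(kind = character(),
                                                cycle = integer(),
                                                t_start = numeric(),
                                                t_end = numeric()))
}

#' @rdname read_temperature_log
#' @param profile A `temperature_profile` to write.
#' @export
write_temperature_log <- function(profile, path) {
  utils::write.csv(data.frame(time_s = profile$times,
                              temperature_C = profile$temps),
                   path, row.names = FALSE)
  invisible(path)
}
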