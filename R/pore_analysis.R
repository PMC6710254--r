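# Pore-size analysis of fibril-network images: segmentation and greedy
# maximal-inscribed-circle ("bubble") decomposition of the interstitial
# space, with kernel-density summaries across temperature.

#' Segment fibrils in a network image
#'
#' Thresholds the image into fibrils (foreground) and pore space
#' (background) using Otsu's rule or a fixed level, removes foreground
#' specks smaller than `min_speck` pixels, and by default treats the bright
#' (stained) phase as fibrils.
#'
#' @param image 8-bit intensity matrix.
#' @param method `"otsu"` or `"fixed"`.
#' @param fixed_level Threshold for `method = "fixed"`.
#' @param fibrils_bright Polarity override; default `TRUE` (stained fibrils
#'   are the bright phase).
#' @param min_speck Minimum foreground component size kept, pixels.
#' @return Logical matrix, `TRUE` = fibril. A contrast-free image yields an
#'   all-background mask with a warning (attribute `degenerate = TRUE`),
#'   not an error.
#' @export
segment_fibrils <- function(image, method = c("otsu", "fixed"),
                            fixed_level = NULL, fibrils_bright = TRUE,
                            min_speck = 4L) {
  method <- match.arg(method)
  rng <- range(image)
  if (method == "otsu") {
    if (diff(rng) < 1e-9) {
      gs_warn("image has no contrast; returning all-background mask",
              "degenerate_threshold")
      return(structure(matrix(FALSE, nrow(image), ncol(image)),
                       degenerate = TRUE))
    }
    thr <- EBImage::otsu(EBImage::Image(image / 255), range = c(0, 1)) * 255
  } else {
    if (is.null(fixed_level))
      gs_stop("`fixed_level` is required for method = \"fixed\"",
              "invalid_parameter")
    thr <- fixed_level
  }
  mask <- if (fibrils_bright) image > thr else image < thr
  if (!any(mask)) {
    gs_warn("segmentation produced an empty foreground", "empty_foreground")
    return(structure(mask, degenerate = TRUE))
  }
  if (min_speck > 1) {
    lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_speck)
    mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  }
  mask
}

# Distance of each pixel center to the virtual obstacle ring just outside
# the frame (rows/cols 0 and n+1).
border_distance <- function(h, w) {
  rows <- seq_len(h); cols <- seq_len(w)
  outer(pmin(rows, h + 1 - rows), pmin(cols, w + 1 - cols), pmin)
}

#' Maximal-inscribed-circle decomposition of pore space
#'
#' Decomposes the pore space (background of a fibril mask) into "pores" by
#' the greedy maximal-inscribed-circle rule: repeatedly compute the
#' Euclidean distance transform of the unclaimed pore space (fibrils,
#' previously accepted circles and the frame boundary act as obstacles),
#' accept the largest inscribable circle (ties broken by smallest row, then
#' column, of the center), and claim its pixels, stopping once the largest
#' remaining circle falls below `r_min`. The radius of each accepted circle
#' is the pore size.
#'
#' With `border_policy = "exclude_touching"` (default), circles that would
#' touch the frame boundary are not eligible (they are truncated by the
#' field of view); with `"include"` they are kept, clipped to the frame, so
#' an obstacle-free mask yields a single pore of radius `min(W, H) / 2`
#' pixels.
#'
#' The alternative single-pass variant (`method = "maxima"`) returns all
#' 8-neighborhood local maxima of one distance transform instead; its
#' circles may overlap.
#'
#' @param mask Logical matrix, `TRUE` = fibril (obstacle).
#' @param pixel_size Physical pixel size, micrometers per pixel.
#' @param r_min Smallest accepted pore radius, micrometers; default two
#'   pixels (suppresses quantization pores). Must be at least one pixel.
#' @param border_policy `"exclude_touching"` or `"include"`.
#' @param method `"greedy"` (default) or `"maxima"`.
#' @return Data frame of pores in acceptance order: `center_x_um`,
#'   `center_y_um`, `radius_um` plus pixel-unit columns `center_row`,
#'   `center_col`, `radius_px`. Accepted radii are non-increasing.
#' @export
find_pores <- function(mask, pixel_size = 1, r_min = 2 * pixel_size,
                       border_policy = c("exclude_touching", "include"),
                       method = c("greedy", "maxima")) {
  border_policy <- match.arg(border_policy)
  method <- match.arg(method)
  if (pixel_size <= 0) gs_stop("`pixel_size` must be positive", "invalid_parameter")
  if (r_min < pixel_size)
    gs_stop("`r_min` must be at least one pixel", "invalid_parameter")
  mask <- mask != 0
  h <- nrow(mask); w <- ncol(mask)
  r_min_px <- r_min / pixel_size
  B <- border_distance(h, w)
  tol <- 1e-9

  radius_map <- function(free) {
    D <- EBImage::imageData(EBImage::distmap(EBImage::Image(free * 1)))
    if (border_policy == "include") pmin(D, B) else D * (D < B)
  }

  rows_mat <- matrix(seq_len(h), h, w)
  cols_mat <- matrix(seq_len(w), h, w, byrow = TRUE)

  pick_center <- function(rm) {
    m <- max(rm)
    cand <- which(rm >= m - tol, arr.ind = TRUE)
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    list(row = cand[1, 1], col = cand[1, 2], r = rm[cand[1, 1], cand[1, 2]])
  }

  out <- list()
  if (!any(mask)) {
    # obstacle-free mask: the only pore is the circle inscribed in the frame
    # (excluded under the default policy since it touches the boundary)
    if (border_policy == "include") {
      p <- pick_center(B)
      out[[1]] <- c(p$row, p$col, p$r)
    }
  } else if (method == "greedy") {
    free <- !mask
    repeat {
      if (!any(free)) break
      rm_ <- radius_map(free)
      rm_[!free] <- 0
      if (max(rm_) < r_min_px) break
      p <- pick_center(rm_)
      disk <- (rows_mat - p$row)^2 + (cols_mat - p$col)^2 < p$r^2 - tol
      # post-hoc overlap guard: the open disk must lie in unclaimed pore space
      if (any(disk & !free))
        gs_stop("internal error: accepted circle overlaps an obstacle",
                "detection_failure")
      free[disk] <- FALSE
      out[[length(out) + 1]] <- c(p$row, p$col, p$r)
    }
  } else {
    rm_ <- radius_map(!mask)
    rm_[mask] <- 0
    is_max <- rm_ >= r_min_px
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      shifted <- matrix(0, h, w)
      rs <- max(1, 1 + dr):min(h, h + dr)
      cs <- max(1, 1 + dc):min(w, w + dc)
      shifted[rs, cs] <- rm_[rs - dr, cs - dc]
      is_max <- is_max & (rm_ >= shifted)
    }
    # merge connected plateaus of equal distance into a single pore
    lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(is_max * 1)))
    out <- lapply(setdiff(unique(as.vector(lab)), 0), function(id) {
      cells <- which(lab == id, arr.ind = TRUE)
      v <- rm_[cells]
      cells <- cells[v >= max(v) - 1e-9, , drop = FALSE]
      cells <- cells[order(cells[, 1], cells[, 2]), , drop = FALSE]
      c(cells[1, 1], cells[1, 2], rm_[cells[1, 1], cells[1, 2]])
    })
    if (length(out)) {
      m0 <- do.call(rbind, out)
      out <- lapply(order(-m0[, 3], m0[, 1], m0[, 2]), function(i) m0[i, ])
    }
  }
  if (!length(out)) {
    return(data.frame(center_x_um = numeric(), center_y_um = numeric(),
                      radius_um = numeric(), center_row = integer(),
                      center_col = integer(), radius_px = numeric()))
  }
  m <- do.call(rbind, out)
  data.frame(center_x_um = (m[, 2] - 0.5) * pixel_size,
             center_y_um = (m[, 1] - 0.5) * pixel_size,
             radius_um = m[, 3] * pixel_size,
             center_row = as.integer(m[, 1]),
             center_col = as.integer(m[, 2]),
             radius_px = m[, 3])
}

#' Uniformly rescale a mask or intensity image
#'
#' Resizes the raster by an isotropic factor (bilinear interpolation),
#' re-binarizing at 0.5 when the input is logical. Used to construct
#' uniformly shrunk versions of a network, e.g. emulating gel contraction
#' between two imaging frames.
#'
#' @param img Matrix (logical mask or intensities).
#' @param factor Isotropic scale factor (> 0); e.g. `15 / 26` for the
#'   contraction-scale shrink.
#' @return The rescaled matrix (logical if the input was logical).
#' @export
rescale_mask <- function(img, factor) {
  if (!is.finite(factor) || factor <= 0)
    gs_stop("`factor` must be positive", "invalid_parameter")
  was_logical <- is.logical(img)
  m <- EBImage::imageData(EBImage::resize(
    EBImage::Image(img * 1),
    w = max(2, round(nrow(img) * factor)),
    h = max(2, round(ncol(img) * factor))))
  if (was_logical) m > 0.5 else m
}

#' Pore-size distribution and modal pore size
#'
#' Gaussian kernel density estimate over pore radii (Silverman's rule by
#' default), normalized so the density integrates to one over its grid. The
#' modal pore size `P_max` is the grid argmax of the density. Raw histogram
#' counts are returned alongside. With fewer than 5 pores only the radii
#' and histogram are returned (flagged; no density).
#'
#' @param pores Data frame from [find_pores()] (or numeric radii, um).
#' @param grid Optional density grid (um).
#' @param bandwidth `"auto"` (Silverman) or a numeric bandwidth, um.
#' @param temperature Optional temperature label, deg C.
#' @return A `pore_size_distribution`: `radii`, `density_x`, `density_y`,
#'   `P_max`, `bandwidth`, `n_pores`, `histogram`, `temperature`,
#'   `iqr`.
#' @export
pore_distribution <- function(pores, grid = NULL, bandwidth = "auto",
                              temperature = NA_real_) {
  radii <- if (is.data.frame(pores)) pores$radius_um else as.numeric(pores)
  n <- length(radii)
  hst <- if (n) graphics::hist(radii, plot = FALSE) else NULL
  base <- list(radii = radii, n_pores = n, temperature = temperature,
               histogram = hst, iqr = if (n) stats::IQR(radii) else NA_real_)
  if (n < 5) {
    return(structure(c(base, list(density_x = NULL, density_y = NULL,
                                  P_max = NA_real_, bandwidth = NA_real_,
                                  flagged = TRUE)),
                     class = "pore_size_distribution"))
  }
  bw <- if (identical(bandwidth, "auto")) stats::bw.nrd0(radii) else bandwidth
  if (!is.finite(bw) || bw <= 0) bw <- max(1e-6, 0.01 * mean(radii))
  if (is.null(grid))
    grid <- seq(max(0, min(radii) - 3 * bw), max(radii) + 3 * bw,
                length.out = 512)
  d <- stats::density(radii, bw = bw, from = min(grid), to = max(grid),
                      n = length(grid))
  # renormalize on the grid (trapezoid rule)
  dx <- diff(d$x)
  integral <- sum(dx * (d$y[-1] + d$y[-length(d$y)]) / 2)
  y <- d$y / integral
  structure(c(base, list(density_x = d$x, density_y = y,
                         P_max = d$x[which.max(y)], bandwidth = bw,
                         flagged = FALSE)),
            class = "pore_size_distribution")
}

#' Pore-size distributions across a temperature series
#'
#' Runs the full segmentation, maximal-inscribed-circle and density chain
#' on each frame of an aligned confocal series and tabulates the modal pore
#' size and distribution spread per temperature. Per-frame failures are
#' flagged (NA rows), not fatal.
#'
#' @param series An `aligned_series` of network images (pixel size in um).
#' @param pixel_size Physical pixel size (um/px); defaults to the series'.
#' @param r_min,border_policy,method Passed to [find_pores()]. For
#'   distribution statistics across temperature the `"maxima"` method is
#'   the default here: one circle per pore cell, so the radius density
#'   reflects pore geometry rather than the packing cascade of the greedy
#'   decomposition (whose small gap-filler circles dominate counts).
#' @param ... Passed to [segment_fibrils()].
#' @return List with `distributions` (one `pore_size_distribution` per
#'   frame) and `summary` (data frame `frame_index`, `temperature_C`,
#'   `n_pores`, `P_max_um`, `iqr_um`).
#' @export
pores_vs_temperature <- function(series, pixel_size = NULL,
                                 r_min = NULL, border_policy = "exclude_touching",
                                 method = "maxima", ...) {
  stopifnot(inherits(series, "aligned_series"))
  fs <- series$frames
  px <- if (is.null(pixel_size)) fs$pixel_size else pixel_size
  if (!is.finite(px)) gs_stop("pixel size must be supplied", "invalid_parameter")
  if (is.null(r_min)) r_min <- 2 * px
  n <- length(fs$frames)
  dists <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    res <- tryCatch({
      mask <- suppressWarnings(segment_fibrils(fs$frames[[i]], ...))
      pores <- find_pores(mask, pixel_size = px, r_min = r_min,
                          border_policy = border_policy, method = method)
      pore_distribution(pores, temperature = series$frame_temps[i])
    }, gelswitch_error = function(e) NULL)
    dists[[i]] <- res
    rows[[i]] <- data.frame(
      frame_index = i,
      temperature_C = series$frame_temps[i],
      n_pores = if (is.null(res)) NA_integer_ else res$n_pores,
      P_max_um = if (is.null(res)) NA_real_ else res$P_max,
      iqr_um = if (is.null(res)) NA_real_ else res$iqr)
  }
  list(distributions = dists, summary = do.call(rbind, rows))
}

#' Write pore tables and distribution summaries as CSV
#'
#' @param pores Data frame from [find_pores()].
#' @param path Output path.
#' @param frame_index,temperature Optional label columns.
#' @export
write_pore_table <- function(pores, path, frame_index = NA_integer_,
                             temperature = NA_real_) {
  utils::write.csv(data.frame(frame_index = frame_index,
                              temperature_C = temperature,
                              center_x_um = pores$center_x_um,
                              center_y_um = pores$center_y_um,
                              radius_um = pores$radius_um),
                   path, row.names = FALSE)
  invisible(path)
}

#' @export
print.pore_size_distribution <- function(x, ...) {
  cat(sprintf("<pore_size_distribution> n = %d pores, P_max = %s um, IQR = %.3g um\n",
              x$n_pores,
              if (is.na(x$P_max)) "NA (too few pores)" else sprintf("%.2f", x$P_max),
              x$iqr))
  invisible(x)
}
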