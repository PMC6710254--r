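# Synthetic-data generators: temperature protocols, contraction traces,
# rendered top-view gel videos, fibril-network images and CD spectra with
# known ground truth. These are phenomenological fixtures for validating the
# analysis chain, not physical simulations of gel mechanics.

new_temperature_profile <- function(times, temps, protocol_label, segments) {
  stopifnot(length(times) == length(temps), all(diff(times) > 0))
  structure(
    list(times = times, temps = temps, protocol_label = protocol_label,
         segments = segments),
    class = "temperature_profile"
  )
}

#' Construct a heating-stage temperature protocol
#'
#' Builds a piecewise-linear stage-temperature trajectory of the two kinds
#' used to characterize switching gels: a single up-then-down ramp
#' (heat from `t_low` to `t_high`, then cool back, e.g. 30 to 45 to 30 deg C)
#' or a cyclic protocol in which the temperature shuttles between `t_low`
#' and `t_high` for `n_cycles` cycles, dwelling `dwell` seconds at each
#' end (e.g. 28-42 deg C for twenty cycles with 5-minute dwells). Ramps run
#' at the given constant rate; the stage rate in the reference setup is
#' about 0.04 deg C per second.
#'
#' @param kind `"ramp"` or `"cyclic"`.
#' @param t_low,t_high Temperature end points, deg C. `t_low == t_high` is
#'   allowed for `"ramp"` and yields a degenerate constant trace.
#' @param rate Heating/cooling rate, deg C per second (> 0).
#' @param n_cycles Number of cycles (cyclic kind only, >= 1).
#' @param dwell Dwell time at each end point, seconds. For the ramp kind a
#'   single dwell is inserted at `t_high`.
#' @param sampling_dt Sensor sampling interval, seconds (> 0).
#' @return A `temperature_profile`: list with `times` (s, strictly
#'   increasing), `temps` (deg C) and `protocol_label`, plus a `segments`
#'   data frame (`kind`, `cycle`, `t_start`, `t_end`) describing the
#'   piecewise structure used downstream for cycle bookkeeping.
#' @examples
#' p <- make_temperature_profile("cyclic", 28, 42, rate = 0.04,
#'                               n_cycles = 3, dwell = 300, sampling_dt = 1)
#' range(p$temps)
#' @export
make_temperature_profile <- function(kind = c("ramp", "cyclic"),
                                     t_low, t_high, rate,
                                     n_cycles = 1L, dwell = 0,
                                     sampling_dt = 1) {
  kind <- match.arg(kind)
  if (!is.finite(sampling_dt) || sampling_dt <= 0)
    gs_stop("`sampling_dt` must be positive", "invalid_parameter")
  if (!is.finite(rate) || rate <= 0)
    gs_stop("`rate` must be positive", "invalid_parameter")
  if (t_low > t_high)
    gs_stop("`t_low` must not exceed `t_high`", "invalid_parameter")
  if (t_low < 0 || t_high > 100)
    gs_stop("temperatures must lie within [0, 100] deg C", "invalid_parameter")
  if (kind == "cyclic" && (n_cycles < 1 || dwell < 0))
    gs_stop("cyclic protocols need `n_cycles` >= 1 and `dwell` >= 0",
            "invalid_parameter")

  ramp_time <- (t_high - t_low) / rate
  bp_t <- 0; bp_T <- t_low
  seg <- list()
  add_seg <- function(kind, cycle, t0, t1)
    data.frame(kind = kind, cycle = cycle, t_start = t0, t_end = t1)
  if (kind == "ramp") {
    t <- 0
    seg[[1]] <- add_seg("heat", 1L, t, t + ramp_time)
    t <- t + ramp_time; bp_t <- c(bp_t, t); bp_T <- c(bp_T, t_high)
    if (dwell > 0) {
      seg[[length(seg) + 1]] <- add_seg("dwell_high", 1L, t, t + dwell)
      t <- t + dwell; bp_t <- c(bp_t, t); bp_T <- c(bp_T, t_high)
    }
    seg[[length(seg) + 1]] <- add_seg("cool", 1L, t, t + ramp_time)
    t <- t + ramp_time; bp_t <- c(bp_t, t); bp_T <- c(bp_T, t_low)
    label <- sprintf("ramp %g-%g-%g C at %g C/s", t_low, t_high, t_low, rate)
  } else {
    t <- 0
    for (k in seq_len(n_cycles)) {
      seg[[length(seg) + 1]] <- add_seg("heat", k, t, t + ramp_time)
      t <- t + ramp_time; bp_t <- c(bp_t, t); bp_T <- c(bp_T, t_high)
      if (dwell > 0) {
        seg[[length(seg) + 1]] <- add_seg("dwell_high", k, t, t + dwell)
        t <- t + dwell; bp_t <- c(bp_t, t); bp_T <- c(bp_T, t_high)
      }
      seg[[length(seg) + 1]] <- add_seg("cool", k, t, t + ramp_time)
      t <- t + ramp_time; bp_t <- c(bp_t, t); bp_T <- c(bp_T, t_low)
      if (dwell > 0) {
        seg[[length(seg) + 1]] <- add_seg("dwell_low", k, t, t + dwell)
        t <- t + dwell; bp_t <- c(bp_t, t); bp_T <- c(bp_T, t_low)
      }
    }
    label <- sprintf("cyclic %g-%g C x%d, dwell %g s, %g C/s",
                     t_low, t_high, n_cycles, dwell, rate)
  }
  segments <- do.call(rbind, seg)
  t_end <- max(bp_t)
  times <- seq(0, t_end, by = sampling_dt)
  if (times[length(times)] < t_end) times <- c(times, t_end)
  temps <- if (t_end == 0) rep(t_low, length(times)) else
    stats::approx(bp_t, bp_T, xout = times)$y
  new_temperature_profile(times, temps, label, segments)
}

#' Ground-truth parameters for a synthetic switching gel
#'
#' Collects the parameters of the synthetic contraction model: transition
#' midpoint `T_t`, area stroke (fractional area decrease across the
#' transition), transition width, per-cycle irreversible loss and initial
#' projected area. Defaults emulate a mid-dose gel: `T_t` 40 deg C (doses
#' map T_t linearly from 43 deg C at 50 kGy to 36 deg C at 90 kGy), stroke
#' 0.8 (an area decrease of more than 80% is typical), and a per-cycle
#' irreversible loss of 0.34%.
#'
#' @param T_t Transition midpoint, deg C.
#' @param stroke_area Fractional area decrease across the transition,
#'   in (0, 1).
#' @param width_w Transition sharpness (logistic scale parameter), deg C.
#' @param loss_per_cycle Irreversible fractional area loss per completed
#'   heating cycle, in \[0, 0.05).
#' @param A0 Initial projected area, cm^2.
#' @param seed Integer seed controlling all randomness tied to this truth.
#' @return A `synthetic_truth` list echoing the arguments.
#' @export
make_truth <- function(T_t = 40, stroke_area = 0.8, width_w = 0.7,
                       loss_per_cycle = 0.0034, A0 = 2, seed = 1L) {
  if (!(stroke_area > 0 && stroke_area < 1))
    gs_stop("`stroke_area` must lie in (0, 1)", "invalid_parameter")
  if (width_w <= 0)
    gs_stop("`width_w` must be positive", "invalid_parameter")
  if (loss_per_cycle < 0 || loss_per_cycle >= 0.05)
    gs_stop("`loss_per_cycle` must lie in [0, 0.05)", "invalid_parameter")
  if (A0 <= 0) gs_stop("`A0` must be positive", "invalid_parameter")
  structure(list(T_t = T_t, stroke_area = stroke_area, width_w = width_w,
                 loss_per_cycle = loss_per_cycle, A0 = A0,
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

new_area_trace <- function(times, temps, area_raw, area_smooth = NULL,
                           sigma_used = NA_real_, method_label = "synthetic",
                           flags = NULL) {
  structure(
    list(times = times, temps = temps, area_raw = area_raw,
         area_smooth = area_smooth, sigma_used = sigma_used,
         method_label = method_label,
         flags = if (is.null(flags)) rep(FALSE, length(times)) else flags),
    class = "area_trace"
  )
}

# Logistic transition response shared by the generator and its tests.
logistic_response <- function(temp, T_t, width_w) stats::plogis((temp - T_t) / width_w)

#' Simulate a projected-area trace for a temperature protocol
#'
#' Evaluates the synthetic contraction model
#' `A(t) = A0 * r(t) * (1 - stroke_area * S((T(t) - T_t) / width_w))`,
#' where `S` is the logistic function (chosen so the first derivative of
#' the transition is symmetric about the midpoint) and `r(t)` steps down by
#' a factor `(1 - loss_per_cycle)` each time a heating cycle completes
#' (end of a cooling ramp). Cooling retraces the same sigmoid, so apart
#' from the per-cycle loss the response is reversible. Multiplicative
#' Gaussian noise of relative scale `noise_sd` is applied last, under the
#' truth's seed.
#'
#' @param profile A `temperature_profile`.
#' @param truth A `synthetic_truth` (see [make_truth()]).
#' @param noise_sd Relative (multiplicative) Gaussian noise scale; `0` for
#'   a noiseless trace.
#' @return List with elements `trace` (an `area_trace`, areas in cm^2) and
#'   `truth` (the input truth, echoed).
#' @examples
#' p <- make_temperature_profile("ramp", 30, 45, rate = 0.04, sampling_dt = 5)
#' tr <- make_contraction_trace(p, make_truth(T_t = 40, loss_per_cycle = 0))
#' min(tr$trace$area_raw) / max(tr$trace$area_raw)
#' @export
make_contraction_trace <- function(profile, truth, noise_sd = 0) {
  stopifnot(inherits(profile, "temperature_profile"),
            inherits(truth, "synthetic_truth"))
  if (length(profile$times) < 2)
    gs_stop("profile must contain at least 2 samples", "invalid_parameter")
  if (noise_sd < 0)
    gs_stop("`noise_sd` must be non-negative", "invalid_parameter")
  temps <- profile$temps
  times <- profile$times
  cool_ends <- profile$segments$t_end[profile$segments$kind == "cool"]
  n_completed <- vapply(times, function(t) sum(cool_ends <= t), numeric(1))
  r <- (1 - truth$loss_per_cycle)^n_completed
  area <- truth$A0 * r *
    (1 - truth$stroke_area * logistic_response(temps, truth$T_t, truth$width_w))
  if (noise_sd > 0) {
    area <- with_seed(truth$seed,
                      area * (1 + stats::rnorm(length(area), 0, noise_sd)))
    area <- pmax(area, 0)
  }
  trace <- new_area_trace(times, temps, area)
  list(trace = trace, truth = truth)
}

new_frame_series <- function(frames, times, pixel_size, meta = list()) {
  stopifnot(length(frames) == length(times),
            is.na(pixel_size) || pixel_size > 0)
  structure(list(frames = frames, times = times, pixel_size = pixel_size,
                 meta = meta),
            class = "frame_series")
}

#' Render a contraction trace as a top-view video
#'
#' Renders each sample of an area trace as a filled bright disk (the gel in
#' top view) on a darker background, optionally with a dark square
#' reference object of known physical size in the top-left corner for
#' pixel-size calibration, small Gaussian random-walk drift of the disk
#' center (off by default) and additive Gaussian pixel noise. Intensities
#' are rounded and clipped to the 8-bit range.
#'
#' @param trace An `area_trace` with areas in cm^2.
#' @param image_shape Frame shape `c(rows, cols)` in pixels.
#' @param pixel_size Physical pixel size, cm per pixel.
#' @param background_level,gel_level Background and gel intensities (0-255).
#' @param noise_sd Additive pixel-noise standard deviation, intensity
#'   levels.
#' @param include_reference_object Add the calibration square?
#' @param reference_size Side length of the reference square, cm.
#' @param drift_sd Per-frame random-walk step sd in pixels (steps clipped
#'   to one pixel); `0` disables drift.
#' @param seed Integer seed for noise and drift.
#' @return A `frame_series`: list of 8-bit frames (numeric matrices),
#'   per-frame times, `pixel_size` and metadata.
#' @export
render_contraction_frames <- function(trace, image_shape = c(128L, 128L),
                                      pixel_size = 0.015,
                                      background_level = 30, gel_level = 200,
                                      noise_sd = 0,
                                      include_reference_object = FALSE,
                                      reference_size = 0.5,
                                      drift_sd = 0, seed = 1L) {
  stopifnot(inherits(trace, "area_trace"))
  if (pixel_size <= 0) gs_stop("`pixel_size` must be positive", "invalid_parameter")
  h <- image_shape[1]; w <- image_shape[2]
  r_px <- sqrt(pmax(trace$area_raw, 0) / pi) / pixel_size
  n <- length(r_px)
  cy0 <- (h + 1) / 2; cx0 <- (w + 1) / 2
  if (max(r_px) > min(cy0, h - cy0 + 1, cx0, w - cx0 + 1) - 1)
    gs_stop("gel disk does not fit inside the frame", "invalid_parameter")

  with_seed(seed, {
    if (drift_sd > 0) {
      step <- function() clip01(stats::rnorm(n, 0, drift_sd), -1, 1)
      dx <- cumsum(step()); dy <- cumsum(step())
    } else dx <- dy <- numeric(n)
    rows <- seq_len(h); cols <- seq_len(w)
    ref_px <- round(reference_size / pixel_size)
    frames <- vector("list", n)
    for (i in seq_len(n)) {
      f <- matrix(background_level, h, w)
      disk <- outer((rows - (cy0 + dy[i]))^2, (cols - (cx0 + dx[i]))^2, "+") <=
        r_px[i]^2
      f[disk] <- gel_level
      if (include_reference_object) {
        if (ref_px < 1 || ref_px + 4 > min(h, w))
          gs_stop("reference object does not fit inside the frame",
                  "invalid_parameter")
        f[3 + seq_len(ref_px), 3 + seq_len(ref_px)] <- 0
      }
      if (noise_sd > 0) f <- f + stats::rnorm(h * w, 0, noise_sd)
      frames[[i]] <- round(clip01(f, 0, 255))
    }
    new_frame_series(frames, trace$times, pixel_size,
                     meta = list(gel_level = gel_level,
                                 background_level = background_level,
                                 reference_size =
                                   if (include_reference_object) reference_size
                                   else NA_real_,
                                 seed = seed))
  })
}

#' Render a synthetic fibril-network image
#'
#' Draws `n_fibers` bright straight strokes of physical width `fiber_width`
#' across a dark background, emulating a confocal slice of a fluorescently
#' stained fibril network. Two layouts are available. `"mesh"` (default)
#' emulates the characteristic mesh size of a fibrillar gel: fibers are
#' split into two near-orthogonal families at jittered, roughly regular
#' spacings, so the interstitial pores have a well-defined typical size.
#' `"random"` places fibers as Poisson lines (uniform position and
#' orientation); note that Poisson-line cells have exponentially
#' distributed inscribed radii, i.e. no interior modal pore size. Fiber
#' placement is bit-reproducible under `seed`; an explicit fiber table can
#' also be supplied for geometric test constructions.
#'
#' @param image_shape Image shape `c(rows, cols)` in pixels.
#' @param pixel_size Physical pixel size, micrometers per pixel.
#' @param n_fibers Number of fibers (0 gives a uniform dark image).
#' @param fiber_width Fiber width, micrometers; must be at least one pixel.
#' @param seed Integer seed.
#' @param layout `"mesh"` or `"random"`.
#' @param fibers Optional data frame with columns `px`, `py` (a point on
#'   the fiber axis, pixels) and `theta` (orientation, radians) overriding
#'   random placement.
#' @param fg_level,bg_level Fiber and background intensities (0-255).
#' @return An 8-bit intensity matrix.
#' @examples
#' img <- make_fibril_image(c(64, 64), pixel_size = 1, n_fibers = 6,
#'                          fiber_width = 3, seed = 7)
#' @export
make_fibril_image <- function(image_shape = c(256L, 256L), pixel_size = 1,
                              n_fibers = 30L, fiber_width = 3,
                              seed = 1L, layout = c("mesh", "random"),
                              fibers = NULL,
                              fg_level = 200, bg_level = 20) {
  layout <- match.arg(layout)
  if (pixel_size <= 0) gs_stop("`pixel_size` must be positive", "invalid_parameter")
  if (fiber_width < pixel_size)
    gs_stop("`fiber_width` must be at least one pixel wide", "invalid_parameter")
  h <- image_shape[1]; w <- image_shape[2]
  if (is.null(fibers)) {
    fibers <- with_seed(seed, {
      if (layout == "random" || n_fibers < 2) {
        data.frame(px = stats::runif(n_fibers, 1, w),
                   py = stats::runif(n_fibers, 1, h),
                   theta = stats::runif(n_fibers, 0, pi))
      } else {
        n1 <- ceiling(n_fibers / 2); n2 <- n_fibers - n1
        s1 <- h / n1; s2 <- w / n2
        data.frame(
          px = c(rep(w / 2, n1),
                 (seq_len(n2) - 0.5) * s2 + stats::rnorm(n2, 0, 0.15 * s2)),
          py = c((seq_len(n1) - 0.5) * s1 + stats::rnorm(n1, 0, 0.15 * s1),
                 rep(h / 2, n2)),
          theta = c(stats::rnorm(n1, 0, 0.01),
                    stats::rnorm(n2, pi / 2, 0.01)))
      }
    })
  }
  img <- matrix(bg_level, h, w)
  if (nrow(fibers) > 0) {
    half_w <- (fiber_width / pixel_size) / 2
    ys <- matrix(seq_len(h), h, w)
    xs <- matrix(seq_len(w), h, w, byrow = TRUE)
    on_fiber <- matrix(FALSE, h, w)
    for (i in seq_len(nrow(fibers))) {
      d <- abs((xs - fibers$px[i]) * sin(fibers$theta[i]) -
                 (ys - fibers$py[i]) * cos(fibers$theta[i]))
      on_fiber <- on_fiber | (d <= half_w)
    }
    img[on_fiber] <- fg_level
  }
  round(clip01(img, 0, 255))
}

# --- CD spectrum generator -------------------------------------------------

#' Component basis bands for synthetic CD spectra
#'
#' Fixed Gaussian-shaped basis bands used by [make_cd_spectrum()]. The band
#' centers echo the canonical positions discussed for collagen/elastin
#' systems -- a positive collagen triple-helix band at 222 nm with a deep
#' negative coil band at 197 nm, an elastin negative Cotton band whose
#' center shifts from 203 nm toward 207 nm with increasing temperature, a
#' pure random-coil band at 197 nm and a positive beta-turn band at
#' 208 nm. The amplitudes and their temperature dependence are documented
#' fixture constants, not claims about real protein spectra.
#'
#' @param component One of `"collagen"`, `"elastin"`, `"coil"`,
#'   `"beta_turn"`.
#' @param wavelengths Wavelength grid, nm.
#' @param temperature Temperature, deg C.
#' @return Ellipticity contribution in mdeg at each wavelength.
#' @export
cd_basis <- function(component, wavelengths, temperature = 25) {
  g <- function(c0, s) exp(-(wavelengths - c0)^2 / (2 * s^2))
  switch(component,
    collagen = 3.0 * g(222, 5) * (1 - 0.15 * stats::plogis((temperature - 37) / 2)) -
      12 * g(197, 7),
    elastin = {
      centre <- 203 + 4 * stats::plogis((temperature - 35) / 3)
      amp <- 8 * (1 - 0.35 * stats::plogis((temperature - 35) / 3))
      -amp * exp(-(wavelengths - centre)^2 / (2 * 7^2)) - 1.5 * g(222, 9)
    },
    coil = -10 * g(197, 7),
    beta_turn = 2.5 * g(208, 5),
    gs_stop(sprintf("unknown CD component '%s'", component), "invalid_parameter")
  )
}

cd_wavelength_grid <- function() seq(250, 190, by = -0.2)

default_ht <- function(wavelengths) 200 + 360 * exp(-(wavelengths - 190) / 12)

new_cd_spectrum <- function(wavelengths, ellipticity, ht = NULL,
                            temperature = NA_real_, dose = NA_real_,
                            n_replicates = 1L, valid = NULL,
                            qc_pass = NA, meta = list()) {
  stopifnot(length(wavelengths) == length(ellipticity))
  d <- diff(wavelengths)
  if (!(all(d > 0) || all(d < 0)))
    gs_stop("wavelengths must be strictly monotone", "format")
  structure(list(wavelengths = wavelengths, ellipticity = ellipticity,
                 ht = ht, temperature = temperature, dose = dose,
                 n_replicates = as.integer(n_replicates),
                 valid = if (is.null(valid)) rep(TRUE, length(wavelengths))
                         else valid,
                 qc_pass = qc_pass, meta = meta),
            class = "cd_spectrum")
}

#' Generate a synthetic CD spectrum
#'
#' Builds an ellipticity spectrum on the instrument grid (250 to 190 nm in
#' 0.2 nm steps) as a weighted sum of the fixed component basis bands of
#' [cd_basis()] plus additive Gaussian noise. The HT (photomultiplier
#' high-tension) channel is generated as a curve increasing monotonically
#' toward 190 nm, or can be supplied explicitly.
#'
#' @param weights Named numeric vector of non-negative component weights
#'   (names must be `cd_basis()` components). All-zero weights give an
#'   identically zero spectrum.
#' @param temperature Temperature label, deg C (also drives the
#'   temperature-dependent band amplitudes).
#' @param noise_sd Additive noise sd, mdeg.
#' @param seed Integer seed.
#' @param dose Dose label, kGy.
#' @param ht Optional explicit HT channel (volts, same length as the grid).
#' @return A `cd_spectrum`.
#' @examples
#' s <- make_cd_spectrum(c(collagen = 2/3, elastin = 1/3), temperature = 25)
#' @export
make_cd_spectrum <- function(weights, temperature = 25, noise_sd = 0,
                             seed = 1L, dose = 0, ht = NULL) {
  if (any(weights < 0))
    gs_stop("component weights must be non-negative", "invalid_parameter")
  wl <- cd_wavelength_grid()
  ell <- numeric(length(wl))
  for (comp in names(weights))
    ell <- ell + weights[[comp]] * cd_basis(comp, wl, temperature)
  if (noise_sd > 0)
    ell <- with_seed(seed, ell + stats::rnorm(length(wl), 0, noise_sd))
  if (is.null(ht)) ht <- default_ht(wl)
  if (any(ht < 0)) gs_stop("HT voltages must be non-negative", "invalid_parameter")
  new_cd_spectrum(wl, ell, ht = ht, temperature = temperature, dose = dose,
                  meta = list(weights = as.list(weights), noise_sd = noise_sd,
                              seed = seed))
}

#' @export
print.temperature_profile <- function(x, ...) {
  cat(sprintf("<temperature_profile> %s\n  %d samples, %.0f s, %.1f-%.1f C\n",
              x$protocol_label, length(x$times), max(x$times),
              min(x$temps), max(x$temps)))
  invisible(x)
}

#' @export
print.area_trace <- function(x, ...) {
  cat(sprintf("<area_trace> %d samples (%s), area %.3g-%.3g cm^2%s\n",
              length(x$times), x$method_label,
              min(x$area_raw), max(x$area_raw),
              if (!is.null(x$area_smooth))
                sprintf(", smoothed (sigma=%g)", x$sigma_used) else ""))
  invisible(x)
}

#' @export
print.frame_series <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<frame_series> %d frames of %dx%d px, pixel_size %g\n",
              length(x$frames), d[1], d[2], x$pixel_size))
  invisible(x)
}
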