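# Transition-temperature, stroke, dose-response and cyclic-actuation
# metrics extracted from area traces.

# Longest run of non-decreasing temperature; returns index range.
heating_run <- function(temps) {
  nd <- c(TRUE, diff(temps) >= -1e-9)
  r <- rle(nd)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  # merge the sample preceding each TRUE-run (diff is between pairs)
  best <- c(1, 1)
  for (i in seq_along(r$lengths)) {
    if (!r$values[i]) next
    s <- max(1, starts[i] - 1); e <- ends[i]
    if (e - s > best[2] - best[1]) best <- c(s, e)
  }
  best
}

# Plateau-median stroke over an index window: medians of the first and last
# 5% (by time) of the window.
plateau_stroke <- function(area, times, idx) {
  tt <- times[idx]; aa <- area[idx]
  span <- diff(range(tt))
  lo <- tt <= tt[1] + 0.05 * span
  hi <- tt >= tt[length(tt)] - 0.05 * span
  a0 <- stats::median(aa[lo]); a1 <- stats::median(aa[hi])
  max(0, (a0 - a1) / a0)
}

#' Extract the transition temperature from an area trace
#'
#' On the Gaussian-smoothed trace restricted to the heating segment, the
#' derivative dA/dT is computed by central finite differences; the
#' transition temperature is the temperature of its most negative value.
#' The smoothing is boundary-guarded: if the kernel's 4-sigma support
#' reaches past the segment ends at the located peak (which folds the trace
#' back on itself and biases the peak position), sigma is shrunk so the
#' support fits the margin and the peak re-estimated
#' (for a symmetric sigmoidal transition this is the midpoint). The area
#' stroke is measured from 5%-tail plateau medians of the raw areas on the
#' same segment (the median supplies the noise robustness there), and
#' the heating rate from a linear fit of temperature versus time. A
#' no-transition error is raised when the deepest derivative excursion does
#' not exceed three times the derivative noise floor (1.4826 x MAD of
#' dA/dT away from the candidate transition).
#'
#' @param trace An `area_trace` carrying temperatures.
#' @param heating_segment `"auto"` (longest non-decreasing temperature run)
#'   or a time window `c(t0, t1)` in seconds.
#' @param sigma Optional smoothing sd (samples) overriding the trace's
#'   stored smooth; traces smoothed at track time are used as-is.
#' @param dose Optional dose label, kGy.
#' @return A `transition_result`: `T_t` (deg C), `derivative_peak`,
#'   `heating_rate` (deg C/s), `stroke_area`, `stroke_volume_est`
#'   (isotropic-shrinkage conversion `1 - (1 - stroke_area)^(3/2)`), `dose`.
#' @export
find_transition <- function(trace, heating_segment = "auto", sigma = NULL,
                            dose = NA_real_) {
  stopifnot(inherits(trace, "area_trace"))
  if (is.null(trace$temps))
    gs_stop("trace has no temperatures; align frames first", "invalid_parameter")
  if (identical(heating_segment, "auto")) {
    rg <- heating_run(trace$temps)
    idx <- rg[1]:rg[2]
  } else {
    idx <- which(trace$times >= heating_segment[1] &
                   trace$times <= heating_segment[2])
  }
  if (length(idx) < 5 || diff(range(trace$temps[idx])) < 2)
    gs_stop("heating segment must span at least 2 deg C", "no_transition")
  tt <- trace$temps[idx]; ts <- trace$times[idx]
  n <- length(idx)
  i2 <- 2:(n - 1)

  sigma_used <- if (!is.null(sigma)) sigma
    else if (is.finite(trace$sigma_used)) trace$sigma_used else 50

  deriv_peak <- function(sig) {
    aa <- gaussian_smooth(trace$area_raw, sig)[idx]
    dT <- tt[i2 + 1] - tt[i2 - 1]
    # exclude dwell/apex samples where the temperature barely moves: their
    # derivative is dominated by the vanishing denominator
    dT_floor <- 0.25 * stats::median(abs(dT))
    dAdT <- ifelse(abs(dT) > max(dT_floor, 1e-9),
                   (aa[i2 + 1] - aa[i2 - 1]) / dT, NA_real_)
    ok <- which(is.finite(dAdT))
    if (!length(ok)) gs_stop("no usable derivative samples", "no_transition")
    k <- ok[which.min(dAdT[ok])]
    list(T_t = tt[i2][k], peak = dAdT[k], dAdT = dAdT, ok = ok)
  }

  # boundary guard: a kernel whose 4-sigma support reaches past the segment
  # ends folds the trace back on itself and biases the derivative peak; after
  # a first pass, shrink sigma so the support fits the margin to the ends
  first <- deriv_peak(sigma_used)
  margin <- min(sum(tt > first$T_t), sum(tt < first$T_t))
  sigma_eff <- min(sigma_used, max(1, floor(margin / 4)))
  est <- if (sigma_eff < sigma_used) deriv_peak(sigma_eff) else first
  T_t <- est$T_t
  peak <- est$peak
  dAdT <- est$dAdT; ok <- est$ok
  span <- diff(range(tt))
  outside <- ok[abs(tt[i2][ok] - T_t) > 0.15 * span]
  floor_level <- if (length(outside) > 4)
    1.4826 * stats::mad(dAdT[outside], constant = 1) else 0
  if (!(peak < 0) || abs(peak) <= 3 * floor_level || abs(peak) < 1e-12)
    gs_stop("no negative-derivative excursion above the noise floor",
            "no_transition")
  # plateau medians are computed on the raw areas: the median already
  # provides the noise robustness, while heavy smoothing would bleed the
  # transition into short plateaus and bias the stroke low
  stroke <- plateau_stroke(trace$area_raw, trace$times, idx)
  rate <- unname(stats::coef(stats::lm(tt ~ ts))[2])
  structure(list(T_t = T_t, derivative_peak = peak, heating_rate = rate,
                 stroke_area = stroke,
                 stroke_volume_est = 1 - (1 - stroke)^(3 / 2),
                 dose = dose),
            class = "transition_result")
}

#' Stroke of an area trace
#'
#' The area stroke is the relative area decrease between the start and end
#' plateaus of the heating segment, each summarized as the median of the
#' first/last 5% of the segment by time, computed on the raw areas. The
#' volume stroke is a model-based estimate assuming isotropic shrinkage,
#' `1 - (1 - stroke_area)^(3/2)`, reported separately.
#'
#' @param trace An `area_trace`.
#' @return List with `stroke_area` and `stroke_volume_est`.
#' @export
compute_stroke <- function(trace) {
  stopifnot(inherits(trace, "area_trace"))
  if (length(trace$times) < 10)
    gs_stop("trace shorter than 10 samples", "invalid_parameter")
  area <- trace$area_raw
  idx <- if (!is.null(trace$temps)) {
    rg <- heating_run(trace$temps); rg[1]:rg[2]
  } else seq_along(trace$times)
  if (length(idx) < 10) idx <- seq_along(trace$times)
  s <- plateau_stroke(area, trace$times, idx)
  list(stroke_area = s, stroke_volume_est = 1 - (1 - s)^(3 / 2))
}

#' Cyclic-actuation metrics
#'
#' Uses the dwell structure of the temperature protocol to delimit cycles.
#' Per cycle, the hot- and cool-dwell areas are medians over the dwell
#' windows; the amplitude is `(A_cool - A_hot) / A_cool` (with the cool
#' dwell closing the cycle) and the irreversible per-cycle loss is
#' `1 - A_cool(k+1) / A_cool(k)`, reported as mean and sd over cycles.
#' Inflection points are the extrema of dA/dt within each heating and
#' cooling ramp.
#'
#' @param trace An `area_trace` covering the full cyclic protocol.
#' @param profile The cyclic `temperature_profile` the trace was recorded
#'   under (its segment table provides the cycle boundaries).
#' @param sigma Smoothing sd (samples) for the dA/dt inflection search.
#' @return A `cycle_metrics`: `n_cycles`, `inflection_times`,
#'   `inflection_temps`, `amplitude_per_cycle`, `loss_values`,
#'   `loss_per_cycle` (mean), `loss_per_cycle_sd`.
#' @export
analyze_cycles <- function(trace, profile, sigma = 5) {
  stopifnot(inherits(trace, "area_trace"),
            inherits(profile, "temperature_profile"))
  seg <- profile$segments
  if (is.null(seg) || !nrow(seg) || !any(seg$kind == "dwell_low"))
    gs_stop("cycle boundaries unrecoverable from profile (no dwell structure)",
            "alignment")
  n_cycles <- max(seg$cycle)
  if (n_cycles < 2)
    gs_stop("cyclic analysis needs at least 2 cycles", "invalid_parameter")
  t <- trace$times; a <- trace$area_raw

  dwell_median <- function(kind, k) {
    s <- seg[seg$kind == kind & seg$cycle == k, ]
    if (!nrow(s)) return(NA_real_)
    stats::median(a[t >= s$t_start & t <= s$t_end])
  }
  a_hot <- vapply(seq_len(n_cycles), function(k) dwell_median("dwell_high", k),
                  numeric(1))
  a_cool <- vapply(seq_len(n_cycles), function(k) dwell_median("dwell_low", k),
                   numeric(1))
  amplitude <- (a_cool - a_hot) / a_cool
  loss <- 1 - a_cool[-1] / a_cool[-n_cycles]

  # inflection points: extrema of dA/dt within each ramp
  asm <- gaussian_smooth(a, sigma)
  dadt <- c(NA, (asm[-(1:2)] - asm[1:(length(asm) - 2)]) /
              (t[-(1:2)] - t[1:(length(t) - 2)]), NA)
  infl_t <- infl_T <- numeric(0)
  ramps <- seg[seg$kind %in% c("heat", "cool"), ]
  for (i in seq_len(nrow(ramps))) {
    w <- which(t >= ramps$t_start[i] & t <= ramps$t_end[i] & is.finite(dadt))
    if (length(w) < 3) next
    j <- if (ramps$kind[i] == "heat") w[which.min(dadt[w])]
         else w[which.max(dadt[w])]
    infl_t <- c(infl_t, t[j])
    infl_T <- c(infl_T, if (!is.null(trace$temps)) trace$temps[j] else
      stats::approx(profile$times, profile$temps, xout = t[j])$y)
  }
  structure(list(n_cycles = n_cycles,
                 inflection_times = infl_t, inflection_temps = infl_T,
                 amplitude_per_cycle = amplitude,
                 loss_values = loss,
                 loss_per_cycle = mean(loss),
                 loss_per_cycle_sd = stats::sd(loss)),
            class = "cycle_metrics")
}

#' Dose dependence of the transition temperature
#'
#' Ordinary least-squares line of transition temperature versus electron
#' dose across a set of transition results (e.g. 43 deg C at 50 kGy falling
#' linearly to 36 deg C at 90 kGy corresponds to a slope of
#' -0.175 deg C/kGy).
#'
#' @param results List of `transition_result` objects (with dose labels),
#'   or a data frame with columns `dose` and `T_t`.
#' @return A `dose_response`: `doses`, `T_ts`, `slope` (deg C/kGy),
#'   `intercept`, `residual_sd`.
#' @export
dose_response <- function(results) {
  d <- if (is.data.frame(results)) results else
    data.frame(dose = vapply(results, `[[`, numeric(1), "dose"),
               T_t = vapply(results, `[[`, numeric(1), "T_t"))
  if (length(unique(d$dose)) < 2)
    gs_stop("dose-response fit needs at least 2 distinct doses",
            "invalid_parameter")
  fit <- stats::lm(T_t ~ dose, data = d)
  co <- stats::coef(fit)
  structure(list(doses = d$dose, T_ts = d$T_t,
                 slope = unname(co[2]), intercept = unname(co[1]),
                 residual_sd = stats::sd(stats::residuals(fit))),
            class = "dose_response")
}

#' @export
print.transition_result <- function(x, ...) {
  cat(sprintf(
    "<transition_result> T_t = %.2f C, stroke_area = %.3f (volume est. %.3f), rate = %.3g C/s\n",
    x$T_t, x$stroke_area, x$stroke_volume_est, x$heating_rate))
  invisible(x)
}

#' @export
print.cycle_metrics <- function(x, ...) {
  cat(sprintf(
    "<cycle_metrics> %d cycles, loss/cycle = %.3f%% +/- %.3f%%, mean amplitude = %.3f\n",
    x$n_cycles, 100 * x$loss_per_cycle, 100 * x$loss_per_cycle_sd,
    mean(x$amplitude_per_cycle)))
  invisible(x)
}

#' @export
print.dose_response <- function(x, ...) {
  cat(sprintf("<dose_response> slope = %.4f C/kGy, intercept = %.2f C (n = %d)\n",
              x$slope, x$intercept, length(x$doses)))
  invisible(x)
}
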