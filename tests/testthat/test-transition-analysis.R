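# Transition temperature, stroke, cyclic metrics and dose response.

test_that("the derivative peak of a noiseless logistic trace is its midpoint", {
  p <- make_temperature_profile("ramp", 30, 45, 0.04, sampling_dt = 5)
  truth <- make_truth(T_t = 38.5, stroke_area = 0.8, width_w = 0.7,
                      loss_per_cycle = 0)
  tr <- make_contraction_trace(p, truth, noise_sd = 0)$trace
  res <- find_transition(tr, sigma = TEST_SIGMA)
  # within one temperature sample (rate * dt = 0.2 C)
  expect_lte(abs(res$T_t - 38.5), 0.04 * 5)
  expect_lt(res$derivative_peak, 0)
  expect_equal(res$heating_rate, 0.04, tolerance = 1e-6)
})

test_that("trace-level transition recovery works across the dose range", {
  for (T_t in c(36, 40, 43)) {
    p <- make_temperature_profile("ramp", 30, 45, 0.04, sampling_dt = 5)
    truth <- make_truth(T_t = T_t, stroke_area = 0.8, width_w = 0.7,
                        loss_per_cycle = 0, seed = T_t)
    tr <- make_contraction_trace(p, truth, noise_sd = 0.005)$trace
    res <- find_transition(tr, sigma = TEST_SIGMA)
    expect_lte(abs(res$T_t - T_t), 0.5)
  }
})

test_that("constant traces raise a no-transition error", {
  p <- make_temperature_profile("ramp", 30, 45, 0.04, sampling_dt = 5)
  tr <- new_area_trace_for_test(rep(2, length(p$times)), times = p$times,
                                temps = p$temps)
  expect_error(find_transition(tr, sigma = TEST_SIGMA),
               class = "gelswitch_no_transition")
})

test_that("stroke is recovered from plateau medians and converts to volume", {
  p <- make_temperature_profile("ramp", 30, 45, 0.04, sampling_dt = 5)
  truth <- make_truth(T_t = 40, stroke_area = 0.8, width_w = 0.7,
                      loss_per_cycle = 0, seed = 3)
  tr <- make_contraction_trace(p, truth, noise_sd = 0.002)$trace
  st <- compute_stroke(tr)
  expect_gte(st$stroke_area, 0.78); expect_lte(st$stroke_area, 0.82)

  # constant trace: exactly zero
  cst <- new_area_trace_for_test(rep(1, 50), temps = rep(30, 50))
  expect_identical(compute_stroke(cst)$stroke_area, 0)
  expect_identical(compute_stroke(cst)$stroke_volume_est, 0)

  # the isotropic conversion inverts: area stroke 1 - 0.1^(2/3) -> volume 0.9
  s <- 1 - 0.1^(2 / 3)
  tr2 <- new_area_trace_for_test(c(rep(1, 25), rep(1 - s, 25)))
  expect_equal(compute_stroke(tr2)$stroke_volume_est, 0.9, tolerance = 1e-12)

  expect_error(compute_stroke(new_area_trace_for_test(rep(1, 5))),
               class = "gelswitch_invalid_parameter")
})

test_that("cycle analysis recovers amplitude and irreversible loss", {
  p <- make_temperature_profile("cyclic", 28, 42, 0.04, n_cycles = 20,
                                dwell = 300, sampling_dt = 5)
  # zero loss, zero noise: exactly zero loss with zero spread
  t0 <- make_truth(T_t = 35, stroke_area = 0.8, width_w = 0.7,
                   loss_per_cycle = 0)
  tr0 <- make_contraction_trace(p, t0, noise_sd = 0)$trace
  cm0 <- analyze_cycles(tr0, p)
  expect_identical(cm0$loss_per_cycle, 0)
  expect_identical(cm0$loss_per_cycle_sd, 0)
  expect_equal(cm0$n_cycles, 20)

  # truth loss 0.34%, noise 0.2%: recovered within the acceptance window
  t1 <- make_truth(T_t = 35, stroke_area = 0.8, width_w = 0.7,
                   loss_per_cycle = 0.0034, seed = 5)
  tr1 <- make_contraction_trace(p, t1, noise_sd = 0.002)$trace
  cm1 <- analyze_cycles(tr1, p)
  expect_gte(cm1$loss_per_cycle, 0.0029)
  expect_lte(cm1$loss_per_cycle, 0.0039)

  # truth amplitude ~0.5: every cycle within +/-0.02
  s_hi <- plogis((42 - 35) / 0.7); s_lo <- plogis((28 - 35) / 0.7)
  stroke_for_half <- 0.5 / s_hi
  t2 <- make_truth(T_t = 35, stroke_area = stroke_for_half, width_w = 0.7,
                   loss_per_cycle = 0, seed = 6)
  tr2 <- make_contraction_trace(p, t2, noise_sd = 0.002)$trace
  cm2 <- analyze_cycles(tr2, p)
  truth_amp <- 1 - (1 - stroke_for_half * s_hi) / (1 - stroke_for_half * s_lo)
  expect_true(all(abs(cm2$amplitude_per_cycle - truth_amp) <= 0.02))

  # inflection points: one per ramp, at temperatures near the midpoint
  expect_equal(length(cm1$inflection_times), 40)
  expect_equal(median(cm1$inflection_temps), 35, tolerance = 0.05)

  # profiles without dwell structure cannot be cycled
  pr <- make_temperature_profile("ramp", 30, 45, 0.04, sampling_dt = 5)
  expect_error(analyze_cycles(tr1, pr), class = "gelswitch_alignment")
})

test_that("dose response fits the printed end points", {
  # exact two-point line: (50 kGy, 43 C) and (90 kGy, 36 C)
  d2 <- dose_response(data.frame(dose = c(50, 90), T_t = c(43, 36)))
  expect_equal(d2$slope, -0.175, tolerance = 1e-12)

  # all equal transition temperatures: zero slope
  d0 <- dose_response(data.frame(dose = c(50, 70, 90), T_t = rep(40, 3)))
  expect_equal(d0$slope, 0, tolerance = 1e-12)

  expect_error(dose_response(data.frame(dose = c(60, 60), T_t = c(40, 40.5))),
               class = "gelswitch_invalid_parameter")

  # noisy replicated series recovers the slope window
  set.seed(1)
  doses <- rep(seq(50, 90, by = 5), each = 2)
  tts <- 43 - 0.175 * (doses - 50) + rnorm(length(doses), 0, 0.3)
  dr <- dose_response(data.frame(dose = doses, T_t = tts))
  expect_gte(dr$slope, -0.19); expect_lte(dr$slope, -0.16)
  expect_lt(dr$residual_sd, 0.6)
})

test_that("the analysis itself introduces no heating-rate bias", {
  # identical truth at rates differing 30x: recovered T_t differ < 0.3 C
  res <- lapply(c(0.04, 0.04 / 30), function(rate) {
    dt <- if (rate > 0.01) 5 else 150  # same temperature sampling per ramp
    p <- make_temperature_profile("ramp", 30, 45, rate, sampling_dt = dt)
    truth <- make_truth(T_t = 40, stroke_area = 0.8, width_w = 0.7,
                        loss_per_cycle = 0, seed = 8)
    tr <- make_contraction_trace(p, truth, noise_sd = 0.003)$trace
    find_transition(tr, sigma = TEST_SIGMA)$T_t
  })
  expect_lt(abs(res[[1]] - res[[2]]), 0.3)
})

test_that("stroke estimation is invariant to area scale and intensity shifts", {
  v <- make_test_video(T_t = 40, stroke = 0.8, seed = 13)
  base <- compute_stroke(track_test_video(v))$stroke_area

  # affine intensity change of every frame (through the full pipeline)
  v2 <- v
  v2$frames$frames <- lapply(v$frames$frames,
                             function(f) pmin(pmax(0.8 * f + 20, 0), 255))
  shifted <- compute_stroke(track_test_video(v2))$stroke_area
  expect_equal(shifted, base, tolerance = 0.02)

  # doubling A0 leaves the relative stroke unchanged (trace level)
  p <- make_temperature_profile("ramp", 30, 45, 0.04, sampling_dt = 5)
  for (A0 in c(1, 2)) {
    truth <- make_truth(T_t = 40, stroke_area = 0.8, width_w = 0.7,
                        loss_per_cycle = 0, A0 = A0, seed = 2)
    tr <- make_contraction_trace(p, truth, noise_sd = 0.002)$trace
    expect_equal(compute_stroke(tr)$stroke_area, 0.8, tolerance = 0.02)
  }
})
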