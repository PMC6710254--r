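# Synthetic-data generators: temperature protocols, contraction traces,
# rendered videos, fibril networks and CD spectra.

test_that("temperature profiles follow the requested protocol", {
  # twenty 28-42 C cycles with 5-min dwells
  p <- make_temperature_profile("cyclic", 28, 42, rate = 0.04,
                                n_cycles = 20, dwell = 300, sampling_dt = 1)
  expect_equal(range(p$temps), c(28, 42))
  expect_equal(p$temps[1], 28)
  expect_equal(p$temps[length(p$temps)], 28)  # cyclic starts and ends low
  expect_true(all(diff(p$times) > 0))
  expect_equal(max(p$segments$cycle), 20)
  expect_equal(sum(p$segments$kind == "cool"), 20)
  # 42 C is actually reached within one sampling step's worth of rate
  expect_lte(42 - max(p$temps), 1 * 0.04)

  # single up-then-down ramp
  r <- make_temperature_profile("ramp", 30, 45, rate = 0.04, sampling_dt = 1)
  expect_equal(max(r$temps), 45)
  expect_equal(r$temps[1], 30)
  expect_equal(r$temps[length(r$temps)], 30)
  expect_equal(diff(range(r$times)), 2 * 15 / 0.04)

  # degenerate zero-span ramp is a constant trace
  z <- make_temperature_profile("ramp", 30, 30, rate = 0.04, sampling_dt = 1)
  expect_true(all(z$temps == 30))

  expect_error(make_temperature_profile("ramp", 30, 45, 0.04, sampling_dt = 0),
               class = "gelswitch_invalid_parameter")
  expect_error(make_temperature_profile("ramp", 45, 30, 0.04),
               class = "gelswitch_invalid_parameter")
})

test_that("contraction traces follow the logistic area model exactly", {
  p <- make_temperature_profile("ramp", 30, 45, 0.04, sampling_dt = 5)
  truth <- make_truth(T_t = 40, stroke_area = 0.8, width_w = 0.7,
                      loss_per_cycle = 0, A0 = 2)
  tr <- make_contraction_trace(p, truth, noise_sd = 0)$trace
  # closed form: minimum at the hottest sample
  s_top <- plogis((45 - 40) / 0.7)
  expect_equal(min(tr$area_raw), 2 * (1 - 0.8 * s_top), tolerance = 1e-12)
  expect_equal(min(tr$area_raw) / max(tr$area_raw), 0.2, tolerance = 5e-3)

  # staying far below the midpoint gives a constant trace
  pl <- make_temperature_profile("ramp", 30, 33, 0.04, sampling_dt = 5)
  trl <- make_contraction_trace(pl, truth, noise_sd = 0)$trace  # T_t - 5w = 36.5
  expect_lt(diff(range(trl$area_raw)) / max(trl$area_raw), 1e-3)

  # linearity in A0 (noise off)
  t2 <- make_truth(T_t = 40, stroke_area = 0.8, width_w = 0.7,
                   loss_per_cycle = 0, A0 = 4)
  tr2 <- make_contraction_trace(p, t2, noise_sd = 0)$trace
  expect_equal(tr2$area_raw, 2 * tr$area_raw, tolerance = 1e-12)

  expect_error(
    make_contraction_trace(
      structure(list(times = 0, temps = 30,
                     segments = data.frame(kind = character(), cycle = integer(),
                                           t_start = numeric(), t_end = numeric()),
                     protocol_label = ""), class = "temperature_profile"),
      truth),
    class = "gelswitch_invalid_parameter")
})

test_that("per-cycle loss compounds at each completed heating cycle", {
  p <- make_temperature_profile("cyclic", 28, 42, 0.04, n_cycles = 20,
                                dwell = 300, sampling_dt = 5)
  truth <- make_truth(T_t = 35, stroke_area = 0.8, width_w = 0.7,
                      loss_per_cycle = 0.0034, A0 = 2, seed = 7)
  tr <- make_contraction_trace(p, truth, noise_sd = 0.002)$trace
  s_low <- plogis((28 - 35) / 0.7)
  seg <- p$segments
  for (k in c(1, 5, 10, 20)) {
    dw <- seg[seg$kind == "dwell_low" & seg$cycle == k, ]
    a_k <- median(tr$area_raw[tr$times >= dw$t_start & tr$times <= dw$t_end])
    expected <- 2 * (1 - 0.0034)^k * (1 - 0.8 * s_low)
    expect_equal(a_k, expected, tolerance = 2e-3)
  }
})

test_that("generators are bit-reproducible under a fixed seed", {
  p <- make_temperature_profile("ramp", 30, 45, 0.04, sampling_dt = 20)
  truth <- make_truth(seed = 42)
  a <- make_contraction_trace(p, truth, noise_sd = 0.01)$trace$area_raw
  b <- make_contraction_trace(p, truth, noise_sd = 0.01)$trace$area_raw
  expect_identical(a, b)

  i1 <- make_fibril_image(c(64, 64), 1, 8, 3, seed = 9)
  i2 <- make_fibril_image(c(64, 64), 1, 8, 3, seed = 9)
  expect_identical(i1, i2)

  tr <- make_contraction_trace(p, truth, noise_sd = 0)$trace
  f1 <- render_contraction_frames(tr, noise_sd = 4, seed = 5)
  f2 <- render_contraction_frames(tr, noise_sd = 4, seed = 5)
  expect_identical(f1$frames, f2$frames)

  s1 <- make_cd_spectrum(c(collagen = 1), noise_sd = 0.5, seed = 3)
  s2 <- make_cd_spectrum(c(collagen = 1), noise_sd = 0.5, seed = 3)
  expect_identical(s1$ellipticity, s2$ellipticity)
})

test_that("rendered disks reproduce the requested areas", {
  # constant-area trace, no noise: every frame identical, calibrated pixel
  # count within 2% of the analytic area (radius ~42 px)
  tr <- new_area_trace_for_test(rep(2, 5))
  fs <- render_contraction_frames(tr, pixel_size = 0.015, noise_sd = 0)
  expect_true(all(vapply(fs$frames[-1], identical, logical(1), fs$frames[[1]])))
  count <- sum(fs$frames[[1]] > 100)
  expect_equal(count * 0.015^2, 2, tolerance = 0.02)

  # stroke 0.8: final pixel count ~ 0.2 x initial
  tr2 <- new_area_trace_for_test(c(2, 2 * 0.2))
  fs2 <- render_contraction_frames(tr2, noise_sd = 0)
  counts <- vapply(fs2$frames, function(f) sum(f > 100), numeric(1))
  expect_equal(counts[2] / counts[1], 0.2, tolerance = 0.03)

  # reference object: 0.5 cm at 0.01 cm/px occupies a 50x50 px block
  tr3 <- new_area_trace_for_test(0.5)
  fs3 <- render_contraction_frames(tr3, image_shape = c(256, 256),
                                   pixel_size = 0.01, noise_sd = 0,
                                   include_reference_object = TRUE,
                                   reference_size = 0.5)
  expect_equal(sum(fs3$frames[[1]] == 0), 50 * 50)

  # disk that cannot fit raises an invalid-parameter error
  expect_error(render_contraction_frames(new_area_trace_for_test(50)),
               class = "gelswitch_invalid_parameter")
})

test_that("fibril images honor geometry and degenerate inputs", {
  # no fibers: uniform dark image
  img0 <- make_fibril_image(c(32, 32), 1, 0, 3, seed = 1)
  expect_true(all(img0 == img0[1, 1]))

  # sub-pixel fiber width is rejected
  expect_error(make_fibril_image(c(32, 32), 2, 5, 1, seed = 1),
               class = "gelswitch_invalid_parameter")

  # explicit fiber table: two horizontal fibers at known rows
  fib <- data.frame(px = c(16, 16), py = c(8, 24), theta = c(0, 0))
  img <- make_fibril_image(c(32, 32), 1, 2, 3, fibers = fib)
  expect_true(all(img[8, ] > 100) && all(img[24, ] > 100))
  expect_true(all(img[16, ] < 100))
})

test_that("CD spectra are linear mixtures of the basis bands", {
  wl <- seq(250, 190, by = -0.2)
  z <- make_cd_spectrum(c(collagen = 0, elastin = 0), noise_sd = 0)
  expect_identical(z$ellipticity, numeric(length(wl)))

  c1 <- make_cd_spectrum(c(collagen = 1), temperature = 25, noise_sd = 0)
  expect_equal(c1$ellipticity, cd_basis("collagen", wl, 25), tolerance = 1e-12)

  mix <- make_cd_spectrum(c(collagen = 2 / 3, elastin = 1 / 3),
                          temperature = 25, noise_sd = 0)
  e1 <- make_cd_spectrum(c(elastin = 1), temperature = 25, noise_sd = 0)
  expect_equal(mix$ellipticity,
               2 / 3 * c1$ellipticity + 1 / 3 * e1$ellipticity,
               tolerance = 1e-12)

  expect_error(make_cd_spectrum(c(collagen = -0.1)),
               class = "gelswitch_invalid_parameter")
  # HT channel increases monotonically toward 190 nm
  expect_true(all(diff(mix$ht) > 0))  # grid runs 250 -> 190
})
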