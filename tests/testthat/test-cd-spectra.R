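# CD spectra: I/O, preprocessing pipeline, HT masking, band features and
# superposition fits.

test_that("CD files round-trip bit-exactly and validate their grid", {
  s <- make_cd_spectrum(c(collagen = 0.5, elastin = 0.5), temperature = 30,
                        noise_sd = 0.4, seed = 8, dose = 60)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cd(s, path)
  back <- read_cd(path)[[1]]
  expect_identical(back$wavelengths, s$wavelengths)
  expect_identical(back$ellipticity, s$ellipticity)
  expect_identical(back$ht, s$ht)
  expect_equal(back$temperature, 30)
  expect_equal(back$dose, 60)

  # two concatenated spectra parse as two blocks
  write_cd(make_cd_spectrum(c(elastin = 1), temperature = 45), path,
           append = TRUE)
  both <- read_cd(path)
  expect_length(both, 2)
  expect_equal(both[[2]]$temperature, 45)

  # a 300-row file (grid not reaching 190 nm) is rejected
  short <- s; short$wavelengths <- s$wavelengths[1:300]
  short$ellipticity <- s$ellipticity[1:300]; short$ht <- s$ht[1:300]
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_cd(short, p2)
  expect_error(read_cd(p2), class = "gelswitch_format")

  # non-monotone wavelengths are reported with their line number
  lines <- readLines(path)[1:305]
  lines[c(10, 11)] <- lines[c(11, 10)]
  p3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(lines, p3)
  err <- tryCatch(read_cd(p3), error = function(e) conditionMessage(e))
  expect_match(err, "line 1[01]")
})

test_that("preprocessing follows the fixed order and its contracts", {
  s <- make_cd_spectrum(c(collagen = 1), temperature = 25, noise_sd = 0)
  zero_ref <- make_cd_spectrum(c(collagen = 0), noise_sd = 0)

  # identity case: identical replicates, zero reference, sigma 0
  out <- preprocess_cd(s, reference = zero_ref, replicates = list(s, s),
                       normalize = FALSE, sigma = 0)
  expect_equal(out$ellipticity, s$ellipticity, tolerance = 1e-12)

  # normalization contract: unit Euclidean norm over valid samples
  nrm <- preprocess_cd(s, normalize = TRUE, sigma = 0)
  expect_equal(sqrt(sum(nrm$ellipticity[nrm$valid]^2)), 1, tolerance = 1e-9)

  # idempotency: a second pass with sigma 0 + normalize changes nothing
  twice <- preprocess_cd(nrm, normalize = TRUE, sigma = 0)
  expect_equal(twice$ellipticity, nrm$ellipticity, tolerance = 1e-12)

  # replicate grids must match
  off <- s; off$wavelengths <- s$wavelengths + 0.1
  expect_error(preprocess_cd(s, replicates = list(off)),
               class = "gelswitch_alignment")
})

test_that("triplicate averaging reduces the noise residual by about 1/sqrt(3)", {
  truth <- make_cd_spectrum(c(collagen = 0.6, elastin = 0.4),
                            noise_sd = 0)$ellipticity
  rms1 <- rms3 <- numeric(20)
  for (s in 1:20) {
    reps <- lapply(1:3, function(i)
      make_cd_spectrum(c(collagen = 0.6, elastin = 0.4), noise_sd = 0.5,
                       seed = 100 * s + i))
    one <- preprocess_cd(reps[[1]], sigma = 0)
    avg <- preprocess_cd(reps[[1]], replicates = reps[-1], sigma = 0)
    rms1[s] <- sqrt(mean((one$ellipticity - truth)^2))
    rms3[s] <- sqrt(mean((avg$ellipticity - truth)^2))
  }
  expect_equal(mean(rms3) / mean(rms1), 1 / sqrt(3), tolerance = 0.05)
})

test_that("HT masking applies the 600 V / 195 nm acquisition rule", {
  wl <- seq(250, 190, by = -0.2)
  mk_ht <- function(cross_nm) ifelse(wl <= cross_nm, 650, 400)

  ok <- ht_mask(make_cd_spectrum(c(collagen = 1), ht = rep(400, length(wl))))
  expect_true(all(ok$valid)); expect_true(ok$qc_pass)

  below <- ht_mask(make_cd_spectrum(c(collagen = 1), ht = mk_ht(193)))
  expect_true(below$qc_pass)
  expect_true(all(below$wavelengths[!below$valid] <= 193))

  above <- ht_mask(make_cd_spectrum(c(collagen = 1), ht = mk_ht(199)))
  expect_false(above$qc_pass)
  expect_false(any(above$valid & above$wavelengths < 199 - 0.1))
})

test_that("band features locate constructed extrema", {
  wl <- seq(250, 190, by = -0.2)
  # single negative band at 203 nm
  s <- new_cd_for_test(wl, -5 * exp(-(wl - 203)^2 / (2 * 4^2)))
  bf <- band_features(s)
  expect_equal(nrow(bf$minima), 1)
  expect_lte(abs(bf$minima$wavelength_nm - 203), 0.2)
  expect_equal(bf$value_at[["203"]], -5, tolerance = 1e-6)

  # flat zero spectrum: no extrema
  flat <- band_features(new_cd_for_test(wl, numeric(length(wl))))
  expect_equal(nrow(flat$minima), 0)
  expect_equal(nrow(flat$maxima), 0)

  # temperature series: generator shifts the elastin band 203 -> 207 nm;
  # the extracted minimum tracks the shift within 0.4 nm
  temps <- c(25, 30, 35, 40, 45, 50)
  centers <- vapply(temps, function(temp) {
    sp <- preprocess_cd(make_cd_spectrum(c(elastin = 1), temperature = temp),
                        sigma = 10)
    mins <- band_features(sp)$minima
    mins$wavelength_nm[which.min(abs(mins$wavelength_nm - 205))]
  }, numeric(1))
  # truth: dense-grid argmin of the noiseless basis itself
  fine <- seq(195, 215, by = 0.01)
  truth_centers <- vapply(temps, function(temp)
    fine[which.min(cd_basis("elastin", fine, temp))], numeric(1))
  expect_true(all(abs(centers - truth_centers) <= 0.4))
  expect_gt(centers[length(temps)] - centers[1], 3)  # the 203 -> 207 shift

  # fully masked spectrum cannot deliver features
  dead <- s; dead$valid[] <- FALSE
  expect_error(band_features(dead), class = "gelswitch_feature_extraction")
})

test_that("smoothing at sigma 10 preserves band positions", {
  wl <- seq(250, 190, by = -0.2)
  s <- new_cd_for_test(wl, -5 * exp(-(wl - 203)^2 / (2 * 4^2)))
  sm <- preprocess_cd(s, sigma = 10)
  bf <- band_features(sm)
  expect_lte(abs(bf$minima$wavelength_nm[1] - 203), 0.2)
})

test_that("superposition fits recover mixture weights", {
  c1 <- make_cd_spectrum(c(collagen = 1), noise_sd = 0)
  c2 <- make_cd_spectrum(c(elastin = 1), noise_sd = 0)
  target <- c1
  target$ellipticity <- 0.6 * c1$ellipticity + 0.4 * c2$ellipticity

  fit <- fit_superposition(target, list(c1, c2),
                           labels = c("collagen", "elastin"))
  expect_equal(unname(fit$weights), c(0.6, 0.4), tolerance = 1e-9)
  expect_lt(fit$residual_rms, 1e-10)

  # residual orthogonal to the component span
  noisy <- target
  noisy$ellipticity <- target$ellipticity + rnorm(301, 0, 0.5)
  fit2 <- fit_superposition(noisy, list(c1, c2))
  res <- noisy$ellipticity - (fit2$weights[1] * c1$ellipticity +
                                fit2$weights[2] * c2$ellipticity)
  expect_lt(abs(sum(res * c1$ellipticity)) /
              sqrt(sum(res^2) * sum(c1$ellipticity^2)), 1e-8)

  # identical components are rank deficient
  expect_error(fit_superposition(target, list(c1, c1)),
               class = "gelswitch_fit")

  # fixed-weight superposition skips fitting
  fixed <- fit_superposition(target, list(c1, c2), weights = c(2 / 3, 1 / 3))
  expect_equal(unname(fixed$weights), c(2 / 3, 1 / 3))
  expect_gt(fixed$residual_rms, 0)
})

test_that("band extremum wavelengths are unchanged by normalization", {
  s <- make_cd_spectrum(c(collagen = 0.7, elastin = 0.3), noise_sd = 0)
  raw <- band_features(preprocess_cd(s, sigma = 10))
  nrm <- band_features(preprocess_cd(s, sigma = 10, normalize = TRUE))
  expect_equal(raw$minima$wavelength_nm, nrm$minima$wavelength_nm)
  expect_equal(raw$maxima$wavelength_nm, nrm$maxima$wavelength_nm)
})
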