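# Shared fixtures and independent oracles used across test files.

# Brute-force maximal-inscribed-circle oracle: distances are computed by
# direct enumeration over all obstacle pixels (no distance transform), with
# the same greedy/claiming semantics as find_pores(). Independent of the
# EBImage-based implementation path.
oracle_find_pores <- function(mask, r_min_px = 2,
                              border_policy = "exclude_touching") {
  mask <- mask != 0
  h <- nrow(mask); w <- ncol(mask)
  rows_mat <- matrix(seq_len(h), h, w)
  cols_mat <- matrix(seq_len(w), h, w, byrow = TRUE)
  B <- outer(pmin(seq_len(h), h + 1 - seq_len(h)),
             pmin(seq_len(w), w + 1 - seq_len(w)), pmin)
  free <- !mask
  res <- list()
  # squared distance of every pixel to the nearest obstacle pixel, by direct
  # enumeration; obstacles only grow, so updates are pmin over new obstacles
  dmin2 <- matrix(Inf, h, w)
  add_obstacles <- function(pix) {
    for (j in seq_len(nrow(pix)))
      dmin2 <<- pmin(dmin2, (rows_mat - pix[j, 1])^2 + (cols_mat - pix[j, 2])^2)
  }
  if (any(mask)) add_obstacles(which(mask, arr.ind = TRUE))
  repeat {
    if (!any(free)) break
    D <- sqrt(dmin2)
    rmap <- if (border_policy == "include") pmin(D, B) else D * (D < B)
    rmap[!free] <- 0
    m <- max(rmap)
    if (m < r_min_px) break
    cand <- which(rmap >= m - 1e-9, arr.ind = TRUE)
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    cy <- unname(cand[1, 1]); cx <- unname(cand[1, 2]); r <- rmap[cy, cx]
    res[[length(res) + 1]] <- c(row = cy, col = cx, r = r)
    claimed <- (rows_mat - cy)^2 + (cols_mat - cx)^2 < r^2 - 1e-9
    free[claimed] <- FALSE
    add_obstacles(which(claimed, arr.ind = TRUE))
  }
  if (!length(res)) return(NULL)
  do.call(rbind, res)
}

# Random binary obstacle mask with isolated pixels and small blobs.
random_mask <- function(h, w, density = 0.08, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::runif(h * w) < density, h, w)
  nb <- round(h * w * density / 30)
  for (i in seq_len(nb)) {
    r0 <- sample(2:(h - 2), 1); c0 <- sample(2:(w - 2), 1)
    m[r0 + (-1:1), c0 + (-1:1)] <- TRUE
  }
  m
}

# Bare area_trace built from a vector of areas (cm^2), for rendering tests.
new_area_trace_for_test <- function(areas, times = (seq_along(areas) - 1) * 5,
                                    temps = NULL) {
  structure(list(times = times, temps = temps, area_raw = areas,
                 area_smooth = NULL, sigma_used = NA_real_,
                 method_label = "synthetic",
                 flags = rep(FALSE, length(areas))),
            class = "area_trace")
}

# Bare cd_spectrum with explicit values, for feature tests.
new_cd_for_test <- function(wavelengths, ellipticity, ht = NULL) {
  structure(list(wavelengths = wavelengths, ellipticity = ellipticity,
                 ht = ht, temperature = NA_real_, dose = NA_real_,
                 n_replicates = 1L,
                 valid = rep(TRUE, length(wavelengths)), qc_pass = NA,
                 meta = list()),
            class = "cd_spectrum")
}

# Bare frame_series of constant frames at given times.
new_frame_series_for_test <- function(n, times, shape = c(8, 8),
                                      pixel_size = 0.01) {
  structure(list(frames = replicate(n, matrix(100, shape[1], shape[2]),
                                    simplify = FALSE),
                 times = times, pixel_size = pixel_size, meta = list()),
            class = "frame_series")
}

# Standard ramp-protocol synthetic video at the compressed test scale
# (one frame per 5 s, i.e. 0.2 fps; smoothing sigma scaled accordingly).
TEST_FPS_DT <- 5
TEST_SIGMA <- 11  # = 50 samples at 0.9 fps, expressed at 0.2 fps

make_test_video <- function(T_t = 40, stroke = 0.8, width_w = 0.7,
                            noise_trace = 0.005, noise_px = 5, seed = 1,
                            t_low = 30, t_high = 45, rate = 0.04) {
  profile <- make_temperature_profile("ramp", t_low, t_high, rate,
                                      sampling_dt = TEST_FPS_DT)
  truth <- make_truth(T_t = T_t, stroke_area = stroke, width_w = width_w,
                      loss_per_cycle = 0, seed = seed)
  sim <- make_contraction_trace(profile, truth, noise_sd = noise_trace)
  fs <- render_contraction_frames(sim$trace, noise_sd = noise_px, seed = seed)
  list(profile = profile, truth = truth, trace = sim$trace, frames = fs)
}

# Full image pipeline: frames -> aligned -> tracked area trace.
track_test_video <- function(v, sigma = TEST_SIGMA, method = "threshold") {
  aligned <- align_temperature(v$frames, v$profile)
  track_area(aligned, method = method, calibration = v$frames$pixel_size,
             sigma = sigma)
}
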