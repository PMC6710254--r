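# Circular-dichroism spectra: file I/O, preprocessing (replicate
# averaging, reference subtraction, HT masking, smoothing, normalization),
# band-feature extraction and two-component superposition fitting.

#' Write a CD spectrum as CSV
#'
#' Dialect: '#' header lines carrying `key=value` metadata
#' (`temperature_C`, `dose_kGy`, `replicate`), then comma-separated columns
#' `wavelength_nm`, `ellipticity_mdeg`, `ht_V`. Values are written at full
#' double precision so a write/read round trip is bit-exact.
#'
#' @param spectrum A `cd_spectrum`.
#' @param path Output path.
#' @param append Append to an existing file (multi-spectrum files).
#' @export
write_cd <- function(spectrum, path, append = FALSE) {
  stopifnot(inherits(spectrum, "cd_spectrum"))
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# temperature_C=%s", fmt_num(spectrum$temperature)),
    sprintf("# dose_kGy=%s", fmt_num(spectrum$dose)),
    sprintf("# replicate=%d", spectrum$n_replicates),
    "wavelength_nm,ellipticity_mdeg,ht_V"
  ), con)
  ht <- if (is.null(spectrum$ht)) rep(NA_real_, length(spectrum$wavelengths))
        else spectrum$ht
  writeLines(paste(fmt_num(spectrum$wavelengths),
                   fmt_num(spectrum$ellipticity),
                   fmt_num(ht), sep = ","), con)
  invisible(path)
}

#' Read CD spectra from CSV
#'
#' Parses the dialect written by [write_cd()] (and a whitespace-separated
#' variant). A file may contain several concatenated spectra, each
#' introduced by its '#' metadata block. The wavelength grid is validated:
#' strictly monotone (a violation is reported with its line number), 0.2 nm
#' spacing, covering 250 to 190 nm (301 samples).
#'
#' @param path Input path.
#' @param strict Enforce the full instrument grid (250-190 nm, 0.2 nm)?
#' @return List of `cd_spectrum` objects.
#' @export
read_cd <- function(path, strict = TRUE) {
  if (!file.exists(path)) gs_stop(sprintf("no such file '%s'", path), "io")
  lines <- readLines(path)
  is_comment <- grepl("^\\s*#", lines)
  is_header <- grepl("wavelength", lines, ignore.case = TRUE)
  is_data <- !is_comment & !is_header & nzchar(trimws(lines))

  # block starts: first line, and any comment line following a data line
  starts <- 1L
  for (i in seq_along(lines)[-1])
    if (is_comment[i] && is_data[i - 1]) starts <- c(starts, i)
  ends <- c(starts[-1] - 1L, length(lines))

  parse_block <- function(s, e) {
    bl <- s:e
    meta <- list(temperature_C = NA_real_, dose_kGy = NA_real_, replicate = 1L)
    for (cl in lines[bl][is_comment[bl]]) {
      kv <- regmatches(cl, regexec("#\\s*([A-Za-z_]+)\\s*=\\s*(\\S+)", cl))[[1]]
      if (length(kv) == 3) meta[[kv[2]]] <- as.numeric(kv[3])
    }
    data_idx <- bl[is_data[bl]]
    if (!length(data_idx)) gs_stop("CD block contains no data rows", "format")
    rows <- lines[data_idx]
    sep <- if (grepl(",", rows[1])) "," else "\\s+"
    parts <- strsplit(trimws(rows), sep)
    nc <- lengths(parts)
    if (any(nc < 2))
      gs_stop(sprintf("malformed CD row at line %d", data_idx[which(nc < 2)[1]]),
              "format")
    wl <- as.numeric(vapply(parts, `[`, "", 1))
    ell <- as.numeric(vapply(parts, `[`, "", 2))
    ht <- if (all(nc >= 3)) as.numeric(vapply(parts, `[`, "", 3)) else NULL
    d <- diff(wl)
    if (!(all(d > 0) || all(d < 0))) {
      bad <- which(if (d[1] > 0) d <= 0 else d >= 0)[1]
      gs_stop(sprintf("wavelength column not strictly monotone at line %d",
                      data_idx[bad + 1]), "format")
    }
    if (strict) {
      if (any(abs(abs(d) - 0.2) > 1e-6))
        gs_stop("wavelength grid spacing is not 0.2 nm", "format")
      if (length(wl) != 301 || !setequal(range(wl), c(190, 250)))
        gs_stop(sprintf(
          "expected the 250-190 nm grid at 0.2 nm (301 rows), got %d rows spanning %g-%g nm",
          length(wl), min(wl), max(wl)), "format")
    }
    if (!is.null(ht) && all(is.na(ht))) ht <- NULL
    new_cd_spectrum(wl, ell, ht = ht, temperature = meta$temperature_C,
                    dose = meta$dose_kGy, n_replicates = meta$replicate)
  }
  lapply(seq_along(starts), function(i) parse_block(starts[i], ends[i]))
}

check_same_grid <- function(a, b) {
  if (length(a$wavelengths) != length(b$wavelengths) ||
      any(abs(a$wavelengths - b$wavelengths) > 1e-9))
    gs_stop("spectra are not on the same wavelength grid", "alignment")
}

#' Mask wavelengths with excessive HT voltage
#'
#' Marks wavelengths where the photomultiplier high-tension voltage reaches
#' `v_max` as invalid; they are excluded from norms, band features and
#' fits. A spectrum whose HT crosses `v_max` at a wavelength above
#' `lambda_floor` fails acquisition QC (flag, not error): the acquisition
#' rule is that HT stays below 600 V down to 195 nm.
#'
#' @param spectrum A `cd_spectrum` with an HT channel.
#' @param v_max HT validity ceiling, volts.
#' @param lambda_floor Wavelength down to which HT must stay valid, nm.
#' @return The spectrum with updated `valid` mask and `qc_pass` flag.
#' @export
ht_mask <- function(spectrum, v_max = 600, lambda_floor = 195) {
  stopifnot(inherits(spectrum, "cd_spectrum"))
  if (is.null(spectrum$ht)) {
    spectrum$qc_pass <- NA
    return(spectrum)
  }
  bad <- spectrum$ht >= v_max
  spectrum$valid <- spectrum$valid & !bad
  spectrum$qc_pass <- !any(bad & spectrum$wavelengths > lambda_floor)
  spectrum
}

#' Preprocess a CD spectrum
#'
#' Fixed pipeline order (recorded in the output metadata):
#' replicate averaging, water-reference subtraction, HT validity masking,
#' Gaussian smoothing (default sigma 10 samples -- small, to preserve the
#' curve shape), then optional division by the Euclidean norm of the
#' ellipticity over the valid (unmasked) samples.
#'
#' @param spectrum A `cd_spectrum`.
#' @param reference Optional water-reference `cd_spectrum` on the same
#'   grid, subtracted from the averaged spectrum.
#' @param replicates Optional list of replicate `cd_spectrum`s averaged
#'   together with `spectrum`.
#' @param normalize Divide by the Euclidean norm over valid samples?
#' @param sigma Smoothing sd in samples (`0` disables smoothing).
#' @param v_max,lambda_floor HT masking parameters (see [ht_mask()]);
#'   masking is skipped when the spectrum has no HT channel.
#' @return The preprocessed `cd_spectrum`.
#' @export
preprocess_cd <- function(spectrum, reference = NULL, replicates = NULL,
                          normalize = FALSE, sigma = 10,
                          v_max = 600, lambda_floor = 195) {
  stopifnot(inherits(spectrum, "cd_spectrum"))
  s <- spectrum
  if (!is.null(replicates)) {
    all_reps <- c(list(spectrum), replicates)
    for (r in all_reps[-1]) check_same_grid(all_reps[[1]], r)
    s$ellipticity <- rowMeans(vapply(all_reps, `[[`, s$ellipticity, "ellipticity"))
    s$n_replicates <- length(all_reps)
  }
  if (!is.null(reference)) {
    check_same_grid(s, reference)
    s$ellipticity <- s$ellipticity - reference$ellipticity
  }
  s <- ht_mask(s, v_max = v_max, lambda_floor = lambda_floor)
  if (sigma > 0) s$ellipticity <- gaussian_smooth(s$ellipticity, sigma)
  if (normalize) {
    nrm <- sqrt(sum(s$ellipticity[s$valid]^2))
    if (nrm > 0) s$ellipticity <- s$ellipticity / nrm
  }
  s$meta$pipeline <- sprintf(
    "mean(%d reps) -> subtract ref (%s) -> HT mask -> smooth (sigma=%g) -> normalize (%s)",
    s$n_replicates, !is.null(reference), sigma, normalize)
  s
}

#' Band features of a CD spectrum
#'
#' Local minima and maxima of the (preprocessed) spectrum over its valid
#' range, detected from sign changes of the first difference with a
#' prominence floor, plus the ellipticity read off the grid at the
#' canonical collagen/elastin wavelengths 197, 203, 207, 220 and 222 nm
#' (coil, elastin Cotton band, beta-turn-shifted band, PPII and triple
#' helix, respectively).
#'
#' @param spectrum A `cd_spectrum`.
#' @param prominence Minimum extremum prominence (mdeg); default 2% of the
#'   spectrum's dynamic range.
#' @return A `band_features` list: `minima` and `maxima` data frames
#'   (`wavelength_nm`, `ellipticity_mdeg`) and `value_at`, a named vector
#'   at the canonical wavelengths.
#' @export
band_features <- function(spectrum, prominence = NULL) {
  stopifnot(inherits(spectrum, "cd_spectrum"))
  keep <- spectrum$valid
  if (!any(keep)) gs_stop("spectrum is fully masked", "feature_extraction")
  ord <- order(spectrum$wavelengths[keep])
  wl <- spectrum$wavelengths[keep][ord]
  ell <- spectrum$ellipticity[keep][ord]
  n <- length(wl)
  rng <- diff(range(ell))
  if (is.null(prominence)) prominence <- 0.02 * rng

  find_extrema <- function(y, minima) {
    if (rng == 0) return(integer(0))
    v <- if (minima) -y else y
    cand <- which(v[2:(n - 1)] >= v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n] &
                    (v[2:(n - 1)] > v[1:(n - 2)] | v[2:(n - 1)] > v[3:n])) + 1
    keep_c <- vapply(cand, function(i) {
      base <- max(min(v[1:i]), min(v[i:n]))  # higher of the two valley floors
      (v[i] - base) >= prominence
    }, logical(1))
    cand[keep_c]
  }
  mins <- find_extrema(ell, TRUE)
  maxs <- find_extrema(ell, FALSE)
  canon <- c(197, 203, 207, 220, 222)
  value_at <- vapply(canon, function(l0) {
    i <- which.min(abs(wl - l0))
    if (abs(wl[i] - l0) > 0.5) NA_real_ else ell[i]
  }, numeric(1))
  names(value_at) <- as.character(canon)
  structure(list(
    minima = data.frame(wavelength_nm = wl[mins], ellipticity_mdeg = ell[mins]),
    maxima = data.frame(wavelength_nm = wl[maxs], ellipticity_mdeg = ell[maxs]),
    value_at = value_at),
    class = "band_features")
}

#' Fit a spectrum as a superposition of component spectra
#'
#' Least-squares weights reproducing the target spectrum as a linear
#' combination of component spectra over the common valid wavelength
#' support (e.g. a collagen/elastin gel approximated by the superposition
#' of the individual collagen and elastin curves). Weights are
#' unconstrained by default; `nonneg = TRUE` restricts them to be
#' non-negative. Supplying `weights` skips fitting and evaluates the
#' fixed-weight superposition (e.g. the 2:1 collagen:elastin mass ratio).
#'
#' @param target A `cd_spectrum`.
#' @param components List of component `cd_spectrum`s on the same grid.
#' @param labels Component names (default `component_1`, ...).
#' @param nonneg Constrain weights to be non-negative?
#' @param weights Optional fixed weights (no fitting).
#' @return A `superposition_fit`: `weights`, `residual_rms` (mdeg),
#'   `components`, `fitted` (on the full grid, NA where masked).
#' @export
fit_superposition <- function(target, components, labels = NULL,
                              nonneg = FALSE, weights = NULL) {
  stopifnot(inherits(target, "cd_spectrum"))
  for (cc in components) check_same_grid(target, cc)
  if (is.null(labels))
    labels <- paste0("component_", seq_along(components))
  valid <- Reduce(`&`, lapply(components, `[[`, "valid"), target$valid)
  if (sum(valid) < length(components) + 1)
    gs_stop("no common valid wavelength support", "alignment")
  X <- vapply(components, function(s) s$ellipticity[valid],
              numeric(sum(valid)))
  y <- target$ellipticity[valid]
  if (is.null(weights)) {
    if (qr(X)$rank < ncol(X))
      gs_stop("component set is rank deficient", "fit")
    w <- qr.solve(X, y)
    if (nonneg && any(w < 0)) {
      obj <- function(p) sum((y - X %*% p)^2)
      w <- stats::optim(pmax(w, 0), obj, method = "L-BFGS-B",
                        lower = rep(0, ncol(X)))$par
    }
  } else {
    if (length(weights) != length(components))
      gs_stop("one weight per component required", "invalid_parameter")
    w <- weights
  }
  res <- y - as.numeric(X %*% w)
  fitted <- rep(NA_real_, length(target$wavelengths))
  fitted[valid] <- as.numeric(X %*% w)
  names(w) <- labels
  structure(list(weights = w, residual_rms = sqrt(mean(res^2)),
                 components = labels, fitted = fitted, valid = valid),
            class = "superposition_fit")
}

#' @export
print.cd_spectrum <- function(x, ...) {
  cat(sprintf(
    "<cd_spectrum> %g-%g nm (%d pts), T = %g C, dose = %g kGy, %d rep(s), %d masked%s\n",
    max(x$wavelengths), min(x$wavelengths), length(x$wavelengths),
    x$temperature, x$dose, x$n_replicates, sum(!x$valid),
    if (is.na(x$qc_pass)) "" else sprintf(", QC %s",
                                          if (x$qc_pass) "pass" else "FAIL")))
  invisible(x)
}

#' @export
print.superposition_fit <- function(x, ...) {
  cat("<superposition_fit>",
      paste(sprintf("%s = %.4f", names(x$weights), x$weights), collapse = ", "),
      sprintf("| residual RMS = %.4g mdeg\n", x$residual_rms))
  invisible(x)
}
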