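# End-to-end orchestration: config validation, stage execution, manifest.

#' Default pipeline configuration
#'
#' Returns the full configuration tree with every tunable of the pipeline.
#' Numeric defaults follow the reference acquisition and analysis settings:
#' camera rate 0.9 frames/s, trace-smoothing sigma 50 samples, CD-smoothing
#' sigma 10 samples, HT ceiling 600 V with a 195 nm validity floor, stage
#' rate 0.04 deg C/s, ramp 30-45 deg C and cyclic 28-42 deg C protocols
#' with 5-minute dwells.
#'
#' @return Nested list of defaults; see the fields themselves.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    outdir = "gelswitch_out",
    stages = c("simulate", "track", "transition"),
    input = list(frames = NULL, temperature_log = NULL, cd_files = NULL),
    simulate = list(
      protocol = "ramp",
      t_low = 30, t_high = 45, rate = 0.04,
      n_cycles = 20L, dwell = 300, sampling_dt = 5,
      truth = list(T_t = 40, stroke_area = 0.8, width_w = 0.7,
                   loss_per_cycle = 0.0034, A0 = 2),
      noise_sd = 0.005,
      render = list(enabled = TRUE, image_shape = c(128L, 128L),
                    pixel_size = 0.015, background_level = 30,
                    gel_level = 200, noise_sd = 5,
                    include_reference_object = TRUE, reference_size = 0.5)
    ),
    track = list(method = "threshold", sigma = 50, fps = 0.9),
    transition = list(heating_segment = "auto", dose = NA_real_),
    cycles = list(sigma = 5),
    pores = list(image_shape = c(192L, 192L), pixel_size = 2,
                 n_fibers = 40L, fiber_width = 6, r_min = NULL,
                 border_policy = "exclude_touching"),
    cd = list(sigma = 10, v_max = 600, lambda_floor = 195,
              normalize = TRUE, noise_sd = 0.2, n_replicates = 3L,
              temperature = 25),
    log_level = "info"
  )
}

# Recursively check cfg against the default template; unknown keys are
# rejected by (dotted) name; known keys override defaults.
merge_config <- function(defaults, cfg, path = "") {
  if (is.null(cfg)) return(defaults)
  if (!is.list(cfg) || !is.list(defaults)) return(cfg)
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    gs_stop(sprintf("unknown config key%s: %s",
                    if (length(unknown) > 1) "s" else "",
                    paste0(path, unknown, collapse = ", ")),
            "invalid_parameter")
  out <- defaults
  for (k in names(cfg)) {
    out[[k]] <- if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])))
      merge_config(defaults[[k]], cfg[[k]], paste0(path, k, "."))
    else cfg[[k]]
  }
  out
}

#' Validate a pipeline configuration
#'
#' Merges a partial configuration (a nested list, or the path of a YAML
#' file) onto [default_config()]. Unknown keys raise an invalid-parameter
#' error naming the key.
#'
#' @param config Nested list or YAML file path; `NULL` gives the defaults.
#' @return The complete, validated configuration list.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) {
    if (!file.exists(config))
      gs_stop(sprintf("config file '%s' not found", config), "io")
    config <- yaml::read_yaml(config)
  }
  cfg <- merge_config(default_config(), config)
  bad_stage <- setdiff(cfg$stages,
                       c("simulate", "track", "transition", "cycles",
                         "pores", "cd"))
  if (length(bad_stage))
    gs_stop(sprintf("unknown stage(s): %s", paste(bad_stage, collapse = ", ")),
            "invalid_parameter")
  cfg
}

log_msg <- function(cfg, level, ...) {
  levels <- c(debug = 1, info = 2, warn = 3)
  if (levels[[level]] >= levels[[cfg$log_level %||% "info"]])
    message(sprintf("[gelswitch %s] %s", level, sprintf(...)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the analysis pipeline
#'
#' Executes the requested stages in order (`simulate`, `track`,
#' `transition`, `cycles`, `pores`, `cd`), writing every artifact under the
#' configured output directory together with a `manifest.json` listing each
#' output file with its MD5 hash, the full parameter set, the seed and the
#' package version. Outputs are bit-reproducible for a fixed seed.
#'
#' @param config Partial configuration (list or YAML path); see
#'   [validate_config()] and [default_config()].
#' @param ... Individual config overrides applied on top of `config`
#'   (e.g. `seed = 7`, `outdir = "run1"`).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = NULL, ...) {
  cfg <- validate_config(config)
  overrides <- list(...)
  if (length(overrides)) cfg <- merge_config(cfg, overrides)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character(0)
  state <- new.env(parent = emptyenv())
  t_start <- proc.time()[["elapsed"]]
  timings <- list()

  add <- function(path) artifacts <<- c(artifacts, path)

  for (stage in cfg$stages) {
    t0 <- proc.time()[["elapsed"]]
    log_msg(cfg, "info", "stage '%s' starting", stage)
    switch(stage,
      simulate = {
        sc <- cfg$simulate
        profile <- if (sc$protocol == "cyclic")
          make_temperature_profile("cyclic", sc$t_low, sc$t_high, sc$rate,
                                   sc$n_cycles, sc$dwell, sc$sampling_dt)
        else
          make_temperature_profile("ramp", sc$t_low, sc$t_high, sc$rate,
                                   dwell = 0, sampling_dt = sc$sampling_dt)
        truth <- make_truth(T_t = sc$truth$T_t,
                            stroke_area = sc$truth$stroke_area,
                            width_w = sc$truth$width_w,
                            loss_per_cycle = sc$truth$loss_per_cycle,
                            A0 = sc$truth$A0, seed = cfg$seed)
        sim <- make_contraction_trace(profile, truth, sc$noise_sd)
        state$profile <- profile; state$truth <- truth
        state$sim_trace <- sim$trace
        p1 <- file.path(cfg$outdir, "temperature_log.csv")
        write_temperature_log(profile, p1); add(p1)
        p2 <- file.path(cfg$outdir, "simulated_trace.csv")
        write_area_trace(sim$trace, p2); add(p2)
        if (isTRUE(sc$render$enabled)) {
          r <- sc$render
          fs <- render_contraction_frames(
            sim$trace, image_shape = r$image_shape,
            pixel_size = r$pixel_size,
            background_level = r$background_level, gel_level = r$gel_level,
            noise_sd = r$noise_sd,
            include_reference_object = r$include_reference_object,
            reference_size = r$reference_size, seed = cfg$seed)
          fdir <- file.path(cfg$outdir, "frames")
          add(write_frames(fs, fdir, temps = sim$trace$temps))
          state$frames_dir <- fdir
        }
      },
      track = {
        src <- cfg$input$frames %||% state$frames_dir
        if (is.null(src))
          gs_stop("track stage needs input frames (run simulate or set input$frames)",
                  "invalid_parameter")
        fs <- load_frames(src, fps = cfg$track$fps)
        cal <- tryCatch(
          calibrate(fs$frames[[1]],
                    cfg$simulate$render$reference_size, locator = "auto"),
          gelswitch_error = function(e) NULL)
        profile <- state$profile %||% {
          if (!is.null(cfg$input$temperature_log))
            read_temperature_log(cfg$input$temperature_log)
          else gs_stop("track stage needs a temperature log", "invalid_parameter")
        }
        aligned <- align_temperature(fs, profile)
        trace <- track_area(aligned, method = cfg$track$method,
                            calibration = cal, sigma = cfg$track$sigma)
        state$trace <- trace
        p <- file.path(cfg$outdir, "tracked_trace.csv")
        write_area_trace(trace, p); add(p)
      },
      transition = {
        trace <- state$trace %||% state$sim_trace
        if (is.null(trace))
          gs_stop("transition stage needs a trace", "invalid_parameter")
        if (is.null(trace$area_smooth))
          trace$area_smooth <- gaussian_smooth(trace$area_raw, cfg$track$sigma)
        res <- find_transition(trace, cfg$transition$heating_segment,
                               dose = cfg$transition$dose)
        p <- file.path(cfg$outdir, "transition.json")
        jsonlite::write_json(unclass(res), p, auto_unbox = TRUE, digits = NA,
                             null = "null", na = "null")
        add(p)
      },
      cycles = {
        trace <- state$trace %||% state$sim_trace
        if (is.null(trace) || is.null(state$profile))
          gs_stop("cycles stage needs a simulated cyclic run", "invalid_parameter")
        cm <- analyze_cycles(trace, state$profile, sigma = cfg$cycles$sigma)
        p <- file.path(cfg$outdir, "cycles.json")
        jsonlite::write_json(unclass(cm), p, auto_unbox = TRUE, digits = NA,
                             null = "null", na = "null")
        add(p)
      },
      pores = {
        pc <- cfg$pores
        img <- make_fibril_image(pc$image_shape, pc$pixel_size, pc$n_fibers,
                                 pc$fiber_width, seed = cfg$seed)
        mask <- segment_fibrils(img)
        pores <- find_pores(mask, pixel_size = pc$pixel_size,
                            r_min = pc$r_min %||% (2 * pc$pixel_size),
                            border_policy = pc$border_policy)
        pd <- pore_distribution(pores)
        p1 <- file.path(cfg$outdir, "pore_table.csv")
        write_pore_table(pores, p1, frame_index = 1L); add(p1)
        p2 <- file.path(cfg$outdir, "pore_summary.csv")
        utils::write.csv(data.frame(temperature_C = NA_real_,
                                    n_pores = pd$n_pores,
                                    P_max_um = pd$P_max, iqr_um = pd$iqr),
                         p2, row.names = FALSE)
        add(p2)
      },
      cd = {
        cc <- cfg$cd
        mk <- function(w, sd_offset)
          make_cd_spectrum(w, temperature = cc$temperature,
                           noise_sd = cc$noise_sd,
                           seed = cfg$seed + sd_offset)
        reps <- lapply(seq_len(cc$n_replicates) - 1L,
                       function(i) mk(c(collagen = 2 / 3, elastin = 1 / 3), i))
        gel <- preprocess_cd(reps[[1]], replicates = reps[-1],
                             normalize = cc$normalize, sigma = cc$sigma,
                             v_max = cc$v_max, lambda_floor = cc$lambda_floor)
        coll <- preprocess_cd(make_cd_spectrum(c(collagen = 1),
                                               temperature = cc$temperature),
                              sigma = cc$sigma)
        elas <- preprocess_cd(make_cd_spectrum(c(elastin = 1),
                                               temperature = cc$temperature),
                              sigma = cc$sigma)
        fit <- fit_superposition(gel, list(coll, elas),
                                 labels = c("collagen", "elastin"))
        feats <- band_features(gel)
        p1 <- file.path(cfg$outdir, "cd_gel.csv"); write_cd(gel, p1); add(p1)
        p2 <- file.path(cfg$outdir, "cd_features.json")
        jsonlite::write_json(
          list(minima = feats$minima, maxima = feats$maxima,
               value_at = as.list(feats$value_at),
               superposition_weights = as.list(fit$weights),
               residual_rms = fit$residual_rms,
               qc_pass = gel$qc_pass),
          p2, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
        add(p2)
      }
    )
    timings[[stage]] <- round(proc.time()[["elapsed"]] - t0, 3)
    log_msg(cfg, "info", "stage '%s' done in %.2f s", stage, timings[[stage]])
  }

  manifest <- list(
    package = "gelswitch",
    version = as.character(utils::packageVersion("gelswitch")),
    seed = cfg$seed,
    stages = cfg$stages,
    parameters = cfg,
    timings_s = timings,
    files = lapply(artifacts, function(f)
      list(path = f, md5 = unname(tools::md5sum(f))))
  )
  mp <- file.path(cfg$outdir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  log_msg(cfg, "info", "wrote %d artifacts and manifest in %.2f s",
          length(artifacts), proc.time()[["elapsed"]] - t_start)
  invisible(manifest)
}
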