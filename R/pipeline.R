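default_pipeline_config <- function() {
  list(
    seed = 1L,
    out_dir = "retroflux_out",
    simulate = list(
      n_cells = 3L,
      image_shape = c(512L, 512L),
      n_frames = 120L,
      frame_interval_s = 180,
      shot_noise = FALSE,
      read_noise_sd = 0,
      sir_drift = 0.1,
      kinetics = list(rho = 2, phi_dynamic = 0.5, k_cleave = 0.03,
                      k_retro = 0.002, half_life_h = 24, k_sec = 3e-4)
    ),
    quantify = list(
      input_dir = NULL,
      channels = list(gfp = 1L, red = 2L, lyso = 3L),
      thresholds = "auto",
      fit_window_min = c(90, 360),
      condition = "control"
    ),
    partition = list(
      remaining_6h = 0.41, rho = 2, half_life_h = 24,
      exo_frac_wcl = 0.06, mvb_frac = 0.62, window_h = 6,
      convention = "ilv_pool"
    )
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read and validate a pipeline configuration
#'
#' Loads a YAML configuration, fills every missing field with the package
#' default, and validates the result. Every pipeline run writes back the
#' fully resolved configuration (seed included) so it can be reproduced
#' exactly.
#'
#' @param path Path to a YAML file, or `NULL` for the defaults.
#' @param overrides Named list applied on top of the file (flags win over
#'   the file, the file wins over defaults).
#' @return A validated configuration list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path = NULL, overrides = list()) {
  cfg <- default_pipeline_config()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      abort(sprintf("Config file not found: %s", path),
            class = "retroflux_config_error")
    }
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  cfg <- merge_config(cfg, overrides)
  ch <- unlist(cfg$quantify$channels)
  if (length(ch) != 3L || anyDuplicated(ch) > 0 ||
      !all(c("gfp", "red", "lyso") %in% names(ch))) {
    abort("Channel mapping must assign distinct indices to gfp, red, lyso.",
          class = "retroflux_config_error")
  }
  w <- cfg$quantify$fit_window_min
  if (length(w) != 2L || w[1] >= w[2] || w[1] < 0) {
    abort("`fit_window_min` must be an increasing pair of non-negative times.",
          class = "retroflux_config_error")
  }
  span <- (cfg$simulate$n_frames - 1) * cfg$simulate$frame_interval_s / 60
  if (is.null(cfg$quantify$input_dir) && w[1] >= span) {
    abort(sprintf("Fit window starts at %g min but the acquisition spans only %g min.",
                  w[1], span),
          class = "retroflux_config_error")
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Write a multichannel stack as per-channel 16-bit TIFF files
#'
#' @param stack Numeric array `rows x cols x channel x frame` in camera
#'   counts (must fit in 16 bits).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths (one multi-page TIFF per
#'   channel, named after the channel).
#' @export
write_stack_tiff <- function(stack, dir) {
  stopifnot(length(dim(stack)) == 4L)
  if (max(stack) > 65535) {
    abort("Stack intensities exceed the 16-bit range.",
          class = "retroflux_data_error")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(dimnames(stack)[[3]], function(ch) {
    pages <- lapply(seq_len(dim(stack)[4]), function(i) stack[, , ch, i] / 65535)
    p <- file.path(dir, paste0(ch, ".tif"))
    tiff::writeTIFF(pages, p, bits.per.sample = 16L)
    p
  }, character(1))
  invisible(paths)
}

#' Read a per-channel TIFF stack written by [write_stack_tiff()]
#'
#' @param dir Directory holding `gfp.tif`, `red.tif`, `lyso.tif`.
#' @return A numeric array `rows x cols x channel x frame` in counts.
#' @export
read_stack_tiff <- function(dir) {
  channels <- c("gfp", "red", "lyso")
  paths <- file.path(dir, paste0(channels, ".tif"))
  if (!all(file.exists(paths))) {
    abort(sprintf("Missing channel TIFFs in %s.", dir),
          class = "retroflux_data_error")
  }
  pages <- lapply(paths, function(p) {
    tryCatch(tiff::readTIFF(p, all = TRUE),
             error = function(e) {
               abort(sprintf("Cannot read TIFF %s: %s", p, conditionMessage(e)),
                     class = "retroflux_data_error")
             })
  })
  n <- length(pages[[1]])
  if (!all(vapply(pages, length, integer(1)) == n)) {
    abort("Channel TIFFs have different frame counts.",
          class = "retroflux_data_error")
  }
  sh <- dim(pages[[1]][[1]])
  stack <- array(0, dim = c(sh[1], sh[2], 3, n),
                 dimnames = list(NULL, NULL, channels, NULL))
  for (c_i in 1:3) {
    for (f_i in seq_len(n)) {
      stack[, , c_i, f_i] <- pages[[c_i]][[f_i]] * 65535
    }
  }
  stack
}

#' Simulate a time-lapse experiment to disk
#'
#' Generates geometry, kinetics and the three-channel stack from the
#' configuration, then writes per-channel TIFFs, the ground-truth pool
#' trajectory and EL trace as CSV, the geometry tables, and the resolved
#' configuration.
#'
#' @param config A [read_pipeline_config()] object (or `NULL` for defaults).
#' @param out_dir Output directory; defaults to the config's `out_dir`.
#' @return Invisibly, the `retro_sim` object with a `files` attribute.
#' @export
run_simulate <- function(config = NULL, out_dir = NULL) {
  config <- config %||% read_pipeline_config()
  out_dir <- out_dir %||% config$out_dir
  sc <- config$simulate
  kin <- do.call(kinetic_params, sc$kinetics)
  geo <- generate_geometry(sc$n_cells, seed = config$seed,
                           image_shape = sc$image_shape)
  acq <- acquisition_params(frame_interval_s = sc$frame_interval_s,
                            n_frames = sc$n_frames,
                            shot_noise = isTRUE(sc$shot_noise),
                            read_noise_sd = sc$read_noise_sd,
                            sir_drift = sc$sir_drift,
                            rng_seed = config$seed)
  sim <- generate_timelapse(geo, kin, acq)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_stack_tiff(sim$stack, out_dir)
  readr::write_csv(sim$truth$pools, file.path(out_dir, "ground_truth_pools.csv"))
  readr::write_csv(sim$truth$trace, file.path(out_dir, "ground_truth_trace.csv"))
  readr::write_csv(geo$cells, file.path(out_dir, "geometry_cells.csv"))
  readr::write_csv(geo$endolysosomes, file.path(out_dir, "geometry_endolysosomes.csv"))
  yaml::write_yaml(unclass(config), file.path(out_dir, "resolved_config.yaml"))
  attr(sim, "files") <- list.files(out_dir, full.names = TRUE)
  invisible(sim)
}

#' Quantify a time-lapse stack end to end
#'
#' Runs the full measurement pipeline: segmentation with interpolated
#' thresholds (explicit or automatic Otsu), per-frame intensity measurement,
#' cytosol-background subtraction with first-frame normalization, slope-A
#' fitting and remaining-fraction readouts. All intermediates, the thresholds
#' actually applied per frame, and the resolved configuration are written to
#' `out_dir`.
#'
#' @param config A [read_pipeline_config()] object (or `NULL` for defaults).
#' @param stack Optional in-memory stack (array `rows x cols x channel x
#'   frame`); when `NULL` the stack is read from
#'   `config$quantify$input_dir`.
#' @param out_dir Output directory; defaults to the config's `out_dir`.
#' @return Invisibly, a list with `intensities` (tibble), `curve`
#'   ([decay_curve()]), `summary` (one-row tibble) and `thresholds`.
#' @export
run_quantify <- function(config = NULL, stack = NULL, out_dir = NULL) {
  config <- config %||% read_pipeline_config()
  out_dir <- out_dir %||% config$out_dir
  qc <- config$quantify
  if (is.null(stack)) {
    if (is.null(qc$input_dir)) {
      abort("No stack supplied and no `quantify$input_dir` configured.",
            class = "retroflux_config_error")
    }
    stack <- read_stack_tiff(qc$input_dir)
  }
  spec <- if (identical(qc$thresholds, "auto")) {
    auto_threshold_spec(stack)
  } else {
    threshold_spec(el = unlist(qc$thresholds$el), nuc = qc$thresholds$nuc,
                   pm = unlist(qc$thresholds$pm))
  }
  masks <- segment_stack(stack, spec)
  n_frames <- length(masks)
  n_empty <- sum(vapply(masks, function(m) !any(m$EL), logical(1)))
  if (n_empty > n_frames / 2) {
    abort(sprintf("Empty endolysosome mask on %d of %d frames; check the EL threshold.",
                  n_empty, n_frames),
          class = "retroflux_data_error")
  }
  tab <- measure_intensities(stack, masks, config$simulate$frame_interval_s)
  el <- filter(tab, .data$compartment == "EL", .data$channel == "gfp")
  cyto <- filter(tab, .data$compartment == "CYTO", .data$channel == "gfp")
  curve <- background_subtract_normalize(el$median, cyto$median,
                                         time_min = el$time_min,
                                         condition_label = qc$condition)
  slope <- fit_slope_A(curve, window = qc$fit_window_min)
  rem6 <- if (max(curve$time_min) >= 360) remaining_fraction(curve, 360) else NA_real_
  rem9 <- if (max(curve$time_min) >= 540) remaining_fraction(curve, 540) else NA_real_
  summary <- mutate(slope, remaining_6h = rem6, remaining_9h = rem9)
  thr_log <- bind_rows(lapply(masks, function(m) {
    tibble(frame = m$frame_idx, threshold_EL = m$thresholds[["EL"]],
           threshold_N = m$thresholds[["N"]], threshold_PM = m$thresholds[["PM"]])
  }))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(tab, file.path(out_dir, "intensity_table.csv"))
  readr::write_csv(as_tibble(curve), file.path(out_dir, "decay_curve.csv"))
  readr::write_csv(summary, file.path(out_dir, "condition_summary.csv"))
  readr::write_csv(thr_log, file.path(out_dir, "thresholds_used.csv"))
  yaml::write_yaml(unclass(config), file.path(out_dir, "resolved_config.yaml"))
  invisible(list(intensities = tab, curve = curve, summary = summary,
                 thresholds = thr_log))
}

#' Compute and report the ILV fate partition
#'
#' Runs the downstream scalar analyses from the configured inputs (and, when
#' table paths are configured, derives the half-life from a pulse-chase CSV)
#' and writes the fate breakdown as JSON and CSV with the inputs echoed.
#'
#' @param config A [read_pipeline_config()] object (or `NULL` for defaults).
#' @param out_dir Output directory; defaults to the config's `out_dir`.
#' @return Invisibly, the report list (inputs and `fate_breakdown` tibble).
#' @export
run_partition <- function(config = NULL, out_dir = NULL) {
  config <- config %||% read_pipeline_config()
  out_dir <- out_dir %||% config$out_dir
  pc <- config$partition
  if (!is.null(pc$pulse_chase_csv)) {
    tab <- readr::read_csv(pc$pulse_chase_csv, show_col_types = FALSE)
    pc$half_life_h <- half_life_from_pulse_chase(tab)$half_life_h
  }
  breakdown <- retrofusion_lower_bound(
    remaining_6h = pc$remaining_6h, rho = pc$rho,
    half_life_h = pc$half_life_h, exo_frac_wcl = pc$exo_frac_wcl,
    mvb_frac = pc$mvb_frac, window_h = pc$window_h,
    convention = pc$convention
  )
  report <- list(inputs = pc[c("remaining_6h", "rho", "half_life_h",
                               "exo_frac_wcl", "mvb_frac", "window_h",
                               "convention")],
                 fate_breakdown = as.list(breakdown[1, ]))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report, file.path(out_dir, "fate_breakdown.json"),
                       auto_unbox = TRUE, digits = NA)
  readr::write_csv(breakdown, file.path(out_dir, "fate_breakdown.csv"))
  invisible(list(inputs = report$inputs, fate_breakdown = breakdown))
}
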