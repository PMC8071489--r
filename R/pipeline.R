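#' Run one stage of the simulation/quantification pipeline
#'
#' Orchestrates the end-to-end chain with file artifacts between stages:
#' \describe{
#'   \item{`design`}{emits `layout.csv` (the gradient layout).}
#'   \item{`calibrate`}{emits `calibration.csv` (the monochromator-scan
#'     wavelength/MICP curve).}
#'   \item{`simulate-assay`}{emits `manifest.yaml` plus one trace CSV and
#'     one spectrum CSV per measurement.}
#'   \item{`quantify`}{reads the calibration and dataset artifacts and emits
#'     `dose_response_<channel>.csv` and `report.yaml` (slope, intercept,
#'     R^2, noise, LOD, conventions) per channel.}
#'   \item{`compare`}{reads both dose-response tables and emits
#'     `comparison.yaml`.}
#' }
#' Downstream commands fail with a dependency error naming the missing
#' artifact. Every random draw derives from the config seed, so re-running a
#' command with the same config reproduces its outputs exactly.
#'
#' @param command One of `"design"`, `"calibrate"`, `"simulate-assay"`,
#'   `"quantify"`, `"compare"`.
#' @param config A [load_config()] result.
#' @param out_dir Artifact directory (default: the config's `output$dir`).
#' @param no_noise Disable all simulated noise regardless of the config.
#' @return Invisibly, a list of produced artifact paths (and, for
#'   `quantify`/`compare`, the computed results).
#' @export
run_pipeline <- function(command = c("design", "calibrate", "simulate-assay",
                                     "quantify", "compare"),
                         config = load_config(), out_dir = NULL,
                         no_noise = FALSE) {
  command <- match.arg(command)
  stopifnot(inherits(config, "ggp_run_config"))
  if (is.null(out_dir)) out_dir <- config$output$dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)

  if (command == "design") {
    sys <- build_system(config)
    write_layout_csv(sys$layout, p("layout.csv"))
    return(invisible(list(layout = p("layout.csv"))))
  }

  if (command == "calibrate") {
    sys <- build_system(config)
    cal <- config$calibration
    curve <- build_calibration_curve(sys$tm,
                                     scan_range = c(cal$scan_start, cal$scan_stop),
                                     scan_step = cal$step,
                                     linewidth = cal$linewidth,
                                     noise = if (no_noise) NULL else sys$noise)
    write_calibration_csv(curve, p("calibration.csv"))
    return(invisible(list(calibration = p("calibration.csv"))))
  }

  if (command == "simulate-assay") {
    sys <- build_system(config)
    assay <- assay_preset(config$assay$preset, seed = config$seed)
    plan <- assay$plan
    if (!is.null(config$assay$concentrations))
      plan <- sample_plan(unlist(config$assay$concentrations),
                          unit = assay$unit,
                          include_blank = plan$include_blank,
                          replicates_per_run = config$assay$replicates_per_run,
                          n_runs = config$assay$n_runs, seed = config$seed)
    else {
      plan$n_runs <- as.integer(config$assay$n_runs)
      plan$replicates_per_run <- as.integer(config$assay$replicates_per_run)
      plan$seed <- config$seed
    }
    ds <- generate_dataset(plan, assay, sys$tm,
                           noise = if (no_noise) NULL else sys$noise,
                           spectrometer_noise_sd =
                             if (no_noise) 0 else config$assay$spectrometer_noise_sd,
                           spectrometer_gain_jitter_sd =
                             if (no_noise) 0 else config$assay$spectrometer_gain_jitter_sd)
    files <- lapply(ds$index$id, function(id) {
      tp <- p(sprintf("trace_%03d.csv", id))
      sp <- p(sprintf("spectrum_%03d.csv", id))
      write_trace_csv(ds$traces[[id]], tp)
      write_spectrum_csv(ds$spectra[[id]], sp)
      list(trace = basename(tp), spectrum = basename(sp))
    })
    manifest <- list(preset = assay$name, unit = assay$unit,
                     kinetic = !is.null(assay$kinetics),
                     seed = plan$seed, n_runs = plan$n_runs,
                     concentrations = plan$concentrations,
                     index = lapply(seq_len(nrow(ds$index)), function(i)
                       c(as.list(ds$index[i, ]), files[[i]])))
    yaml::write_yaml(manifest, p("manifest.yaml"))
    return(invisible(list(manifest = p("manifest.yaml"))))
  }

  if (command == "quantify") {
    for (f in c("calibration.csv", "manifest.yaml"))
      if (!file.exists(p(f)))
        stop_ggp(sprintf("missing upstream artifact: %s (run the %s stage first)",
                         p(f), if (f == "calibration.csv") "calibrate"
                               else "simulate-assay"),
                 "ggpgmr_dependency_error")
    curve <- read_calibration_csv(p("calibration.csv"))
    manifest <- yaml::read_yaml(p("manifest.yaml"))
    assay <- assay_preset(manifest$preset)
    meas <- do.call(rbind, lapply(manifest$index, function(rec) {
      tr <- read_trace_csv(p(rec$trace))
      sp <- read_spectrum_csv(p(rec$spectrum))
      base <- data.frame(run = rec$run, replicate = rec$replicate,
                         concentration = rec$concentration,
                         timepoint = rec$timepoint)
      if (manifest$kinetic) {
        px <- as.integer(round(wavelength_to_pixel(curve,
                                                   assay$model$led_center)))
        sbin <- which.min(abs(sp$wavelength_nm - assay$model$led_center))
        rbind(cbind(base, channel = "ggp-gmr",
                    intensity = tr$intensity[match(px, tr$pixel)]),
              cbind(base, channel = "spectrometer",
                    intensity = sp$intensity[sbin]))
      } else {
        mg <- tryCatch(extract_measurement(tr, curve),
                       ggpgmr_no_dip_error = function(e) NULL)
        ms <- extract_measurement(sp)
        rbind(cbind(base, channel = "ggp-gmr",
                    intensity = if (is.null(mg)) NA_real_ else mg$intensity,
                    micp_pixel = if (is.null(mg)) NA_integer_ else mg$micp_pixel,
                    trace = rec$trace),
              cbind(base, channel = "spectrometer", intensity = ms$intensity,
                    micp_pixel = NA_integer_, trace = NA_character_))
      }
    }))
    # fixed-peak fluorescent assays are read at the run's reference MICP
    # pixel (see measure_dataset); other assays only fall back to it for
    # dim traces with no detectable dip
    reference_read <- !manifest$kinetic && assay$type == "fluorescent" &&
      assay$model$peak_shift_per_decade == 0
    if (!manifest$kinetic && (reference_read || anyNA(meas$intensity))) {
      cmax <- max(meas$concentration)
      for (r in unique(meas$run)) {
        sel <- meas$channel == "ggp-gmr" & meas$run == r
        ref_px <- meas$micp_pixel[sel & meas$concentration == cmax][1]
        if (is.na(ref_px))
          stop_ggp(sprintf("run %s: no dip even at the highest concentration", r),
                   "ggpgmr_no_dip_error")
        redo <- if (reference_read) which(sel)
                else which(sel & is.na(meas$intensity))
        for (i in redo) {
          tr <- read_trace_csv(p(meas$trace[i]))
          meas$intensity[i] <- tr$intensity[match(ref_px, tr$pixel)]
        }
      }
    }
    report <- list()
    out <- list()
    for (ch in c("ggp-gmr", "spectrometer")) {
      tab <- build_dose_response(meas[meas$channel == ch, ],
                                 kinetic = manifest$kinetic)
      fit <- if (manifest$preset == "albumin-bcg")
        fit_dose_response(tab, lowest = 3) else fit_dose_response(tab)
      lod <- tryCatch(estimate_lod(tab, fit),
                      ggpgmr_insufficient_data_error = function(e) NULL)
      fpath <- p(sprintf("dose_response_%s.csv",
                         sub("-", "_", ch, fixed = TRUE)))
      write_num_csv(cbind(as.data.frame(tab)[, c("run", "concentration")],
                          unit = manifest$unit, channel = ch,
                          as.data.frame(tab)[, c("raw_intensity",
                                                 "normalized_intensity")]),
                    fpath)
      report[[ch]] <- list(slope_per_10_units = fit$slope,
                           intercept = fit$intercept,
                           r_squared = fit$r_squared,
                           noise_3sd = if (is.null(lod)) NA else lod$noise,
                           lod = if (is.null(lod)) NA else lod$lod,
                           unit = manifest$unit,
                           sensitivity_convention = "normalized intensity per 10 concentration units",
                           noise_definition = "pooled within-concentration SD",
                           local_linear_lowest = if (manifest$preset == "albumin-bcg") 3 else NULL)
      out[[ch]] <- list(table = tab, fit = fit, lod = lod)
    }
    yaml::write_yaml(report, p("report.yaml"))
    return(invisible(c(out, list(report = p("report.yaml")))))
  }

  # compare
  fa <- p("dose_response_ggp_gmr.csv")
  fb <- p("dose_response_spectrometer.csv")
  for (f in c(fa, fb))
    if (!file.exists(f))
      stop_ggp(sprintf("missing upstream artifact: %s (run the quantify stage first)", f),
               "ggpgmr_dependency_error")
  cols <- c("run", "concentration", "unit", "channel", "raw_intensity",
            "normalized_intensity")
  rd <- function(f) {
    df <- read.csv(f)
    if (!identical(names(df), cols))
      stop_ggp(sprintf("%s: unexpected dose-response schema", f),
               "ggpgmr_format_error")
    structure(df[, c("run", "concentration", "raw_intensity",
                     "normalized_intensity")],
              class = c("ggp_dose_response", "data.frame"))
  }
  cmp <- compare_instruments(rd(fa), rd(fb))
  yaml::write_yaml(cmp, p("comparison.yaml"))
  invisible(c(cmp, list(comparison = p("comparison.yaml"))))
}
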