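# strict CSV plumbing shared by all readers: exact header, numeric cells,
# row-numbered diagnostics
read_checked_csv <- function(path, columns) {
  if (!file.exists(path))
    stop_ggp(sprintf("file not found: %s", path), "ggpgmr_dependency_error")
  df <- read.csv(path, check.names = FALSE, colClasses = "character")
  if (!identical(names(df), columns))
    stop_ggp(sprintf("%s: header must be exactly `%s` (found `%s`)",
                     path, paste(columns, collapse = ","),
                     paste(names(df), collapse = ",")),
             "ggpgmr_format_error")
  for (col in columns) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop_ggp(sprintf("%s: non-numeric value in column `%s`, row %d",
                       path, col, bad[1]), "ggpgmr_format_error")
    df[[col]] <- v
  }
  df
}

write_num_csv <- function(df, path) {
  out <- as.data.frame(lapply(df, function(v)
    if (is.numeric(v)) format(v, digits = 15, trim = TRUE, scientific = FALSE)
    else v))
  names(out) <- names(df)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Spectrum and trace CSV round trips
#'
#' Spectra use header `wavelength_nm,intensity`, traces `pixel,intensity`;
#' comma-separated, `.` decimal, header mandatory, values written with 15
#' significant digits so a write-then-read round trip preserves them.
#' Readers validate the schema (format error naming the row for non-numeric
#' cells), the strictly increasing wavelength grid and non-negative
#' intensities.
#'
#' @param spectrum,trace Objects to write.
#' @param path File path.
#' @return The read object, or `path` invisibly for writers.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "ggp_spectrum"))
  write_num_csv(as.data.frame(spectrum), path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  df <- read_checked_csv(path, c("wavelength_nm", "intensity"))
  if (any(diff(df$wavelength_nm) <= 0))
    stop_ggp(sprintf("%s: wavelength grid not strictly increasing", path),
             "ggpgmr_format_error")
  neg <- which(df$intensity < 0)
  if (length(neg))
    stop_ggp(sprintf("%s: negative intensity at row %d", path, neg[1]),
             "ggpgmr_format_error")
  spectrum_sample(df$wavelength_nm, df$intensity)
}

#' @rdname write_spectrum_csv
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "ggp_ccd_trace"))
  write_num_csv(as.data.frame(trace), path)
}

#' @rdname write_spectrum_csv
#' @export
read_trace_csv <- function(path) {
  df <- read_checked_csv(path, c("pixel", "intensity"))
  neg <- which(df$intensity < 0)
  if (length(neg))
    stop_ggp(sprintf("%s: negative intensity at row %d", path, neg[1]),
             "ggpgmr_format_error")
  ccd_trace(df$pixel, df$intensity)
}

config_defaults <- function() {
  list(
    device = list(period_start = 250, period_end = 550, period_step = 2,
                  cycles_per_period = 100, duty_cycle = 0.5,
                  grating_depth = 85, coating_thickness = 130,
                  band = c(500, 700), neff_model = "slab",
                  materials = list(
                    coating = list(model = "cauchy", A = 2.24, B = 3.0e4),
                    adhesive = list(model = "constant", n = 1.54),
                    substrate = list(model = "constant", n = 1.57),
                    superstrate = list(model = "constant", n = 1.0))),
    instrument = list(anchor = list(pixel1 = 2073, wavelength1 = 500,
                                    pixel2 = 2361, wavelength2 = 700),
                      n_pixels = 3000,
                      lineshape = list(depth = 0.9, fwhm = 3,
                                       shape = "lorentzian"),
                      noise = list(read_noise_sd = 0, shot_noise_scale = 0,
                                   dark_offset = 0)),
    calibration = list(scan_start = 500, scan_stop = 699, step = 1,
                       linewidth = 2.5),
    assay = list(preset = "hsa-fluorescent", n_runs = 3,
                 replicates_per_run = 1, concentrations = NULL,
                 spectrometer_noise_sd = 0, spectrometer_gain_jitter_sd = 0),
    output = list(dir = "."),
    seed = 1
  )
}

merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  extra <- setdiff(names(user), names(defaults))
  if (length(extra))
    stop_ggp(sprintf("unknown config key `%s%s`", path, extra[1]),
             "ggpgmr_config_error")
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && is.list(user[[k]]))
      merge_config(defaults[[k]], user[[k]], paste0(path, k, "."))
    else user[[k]]
  }
  defaults
}

material_from_config <- function(cfg) {
  do.call(material, cfg)
}

#' Load and validate a run configuration
#'
#' YAML configuration with sections `device` (grating design + materials +
#' resonance band + effective-index model), `instrument` (CCD anchoring,
#' lineshape, noise), `calibration` (scan range/step/linewidth), `assay`
#' (preset plus plan overrides), `output` and the global `seed`. Unknown
#' keys are rejected by name; every value is validated by the corresponding
#' constructor at load time. A missing file, or `path = NULL`, yields the
#' full default configuration.
#'
#' @param path YAML file, or `NULL` for defaults.
#' @return A validated `ggp_run_config` list.
#' @export
load_config <- function(path = NULL) {
  user <- if (is.null(path)) list() else {
    if (!file.exists(path))
      stop_ggp(sprintf("config file not found: %s", path),
               "ggpgmr_dependency_error")
    yaml::read_yaml(path)
  }
  cfg <- merge_config(config_defaults(), user)
  # validate eagerly so errors surface at load time and name the key
  d <- cfg$device
  design <- grating_design(d$period_start, d$period_end, d$period_step,
                           d$cycles_per_period, d$duty_cycle,
                           d$grating_depth, d$coating_thickness)
  materials <- material_set(material_from_config(d$materials$coating),
                            material_from_config(d$materials$adhesive),
                            material_from_config(d$materials$substrate),
                            material_from_config(d$materials$superstrate))
  resonance_lineshape(cfg$instrument$lineshape$depth,
                      cfg$instrument$lineshape$fwhm,
                      cfg$instrument$lineshape$shape)
  noise_params(cfg$instrument$noise$read_noise_sd,
               cfg$instrument$noise$shot_noise_scale,
               cfg$instrument$noise$dark_offset)
  if (!cfg$assay$preset %in% c("tamra", "hsa-fluorescent", "creatinine-jaffe",
                               "albumin-bcg"))
    stop_ggp(sprintf("unknown assay preset `%s`", cfg$assay$preset),
             "ggpgmr_config_error")
  cfg$design <- design
  cfg$materials <- materials
  structure(cfg, class = "ggp_run_config")
}

#' Assemble the simulated instrument from a configuration
#'
#' Builds the band-restricted layout, the anchored CCD, the lineshape and
#' the transmission matrix --- the objects every pipeline stage shares.
#'
#' @param config A [load_config()] result.
#' @return List with `layout`, `ccd`, `lineshape`, `tm`, `noise`, `grid`.
#' @export
build_system <- function(config = load_config()) {
  stopifnot(inherits(config, "ggp_run_config"))
  layout <- build_layout(config$design, config$materials,
                         band = unlist(config$device$band),
                         model = config$device$neff_model)
  a <- config$instrument$anchor
  ccd <- anchor_ccd(layout, a$pixel1, a$wavelength1, a$pixel2, a$wavelength2,
                    n_pixels = config$instrument$n_pixels)
  ls <- resonance_lineshape(config$instrument$lineshape$depth,
                            config$instrument$lineshape$fwhm,
                            config$instrument$lineshape$shape)
  grid <- default_wavelength_grid()
  tm <- build_transmission_matrix(layout, ccd, ls, grid)
  ns <- config$instrument$noise
  noise <- if (ns$read_noise_sd > 0 || ns$shot_noise_scale > 0 ||
               ns$dark_offset > 0)
    noise_params(ns$read_noise_sd, ns$shot_noise_scale, ns$dark_offset,
                 seed = config$seed) else NULL
  list(layout = layout, ccd = ccd, lineshape = ls, tm = tm, noise = noise,
       grid = grid)
}
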