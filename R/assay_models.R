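#' Fluorophore emission model
#'
#' Gaussian emission whose peak wavelength drifts logarithmically with
#' concentration (peak = `base_peak` + `peak_shift_per_decade` *
#' log10(c / `reference_concentration`), clamped to the evaluation grid) and
#' whose amplitude follows either a linear law
#' (`amplitude_scale * c / reference_concentration`) or a saturating law
#' (`amplitude_scale * c / (c + saturation_constant)`), plus a constant
#' background. The logarithmic peak drift reproduces the
#' reabsorption/inner-filter blue shift concentrated dye solutions show on
#' dilution.
#'
#' @param base_peak Peak wavelength at the reference concentration, nm.
#' @param peak_shift_per_decade Peak drift, nm per decade of concentration.
#' @param reference_concentration Concentration at which the peak sits at
#'   `base_peak` (same unit as the concentrations fed in).
#' @param emission_fwhm Emission FWHM, nm.
#' @param amplitude_law `"linear"` or `"saturating"`.
#' @param amplitude_scale Peak amplitude scale (intensity units).
#' @param saturation_constant Half-saturation concentration (saturating law).
#' @param background Constant background intensity (stray light).
#' @param unit Concentration unit tag carried through downstream tables.
#' @return A `ggp_fluorophore` object.
#' @export
fluorophore_model <- function(base_peak, peak_shift_per_decade = 0,
                              reference_concentration = 1,
                              emission_fwhm = 35,
                              amplitude_law = c("linear", "saturating"),
                              amplitude_scale = 1, saturation_constant = NULL,
                              background = 0, unit = "mg/L") {
  amplitude_law <- match.arg(amplitude_law)
  assert_scalar_num(base_peak, "base_peak", lower = 0, strict_lower = TRUE)
  assert_scalar_num(emission_fwhm, "emission_fwhm", lower = 0, strict_lower = TRUE)
  assert_scalar_num(reference_concentration, "reference_concentration",
                    lower = 0, strict_lower = TRUE)
  assert_scalar_num(background, "background", lower = 0)
  if (amplitude_law == "saturating")
    assert_scalar_num(saturation_constant, "saturation_constant", lower = 0,
                      strict_lower = TRUE)
  structure(list(base_peak = base_peak,
                 peak_shift_per_decade = peak_shift_per_decade,
                 reference_concentration = reference_concentration,
                 emission_fwhm = emission_fwhm, amplitude_law = amplitude_law,
                 amplitude_scale = amplitude_scale,
                 saturation_constant = saturation_constant,
                 background = background, unit = unit),
            class = "ggp_fluorophore")
}

fluor_peak <- function(model, concentration) {
  model$base_peak + model$peak_shift_per_decade *
    log10(concentration / model$reference_concentration)
}

fluor_amplitude <- function(model, concentration) {
  if (concentration <= 0) return(0)
  switch(model$amplitude_law,
         linear = model$amplitude_scale * concentration /
           model$reference_concentration,
         saturating = model$amplitude_scale * concentration /
           (concentration + model$saturation_constant))
}

#' Fluorescence emission spectrum at one concentration
#'
#' @param model A [fluorophore_model()].
#' @param concentration Analyte concentration (>= 0; 0 gives background
#'   only).
#' @param grid Wavelength grid, nm.
#' @return A [spectrum_sample()]; attribute `truth` records the generated
#'   peak wavelength and amplitude.
#' @export
fluorescence_spectrum <- function(model, concentration,
                                  grid = default_wavelength_grid()) {
  stopifnot(inherits(model, "ggp_fluorophore"))
  if (concentration < 0)
    stop_ggp("concentration must be non-negative", "ggpgmr_validation_error")
  amp <- fluor_amplitude(model, concentration)
  if (concentration <= 0 || amp == 0) {
    sp <- spectrum_sample(grid, rep(model$background, length(grid)))
    attr(sp, "truth") <- list(peak_nm = NA_real_, amplitude = 0)
    return(sp)
  }
  peak <- min(max(fluor_peak(model, concentration), min(grid)), max(grid))
  sigma <- model$emission_fwhm / (2 * sqrt(2 * log(2)))
  sp <- spectrum_sample(grid, amp * exp(-0.5 * ((grid - peak) / sigma)^2) +
                          model$background)
  attr(sp, "truth") <- list(peak_nm = peak, amplitude = amp)
  sp
}

#' Chromogen (Beer-Lambert) model under LED illumination
#'
#' The transmitted spectrum is the LED Gaussian attenuated by
#' \eqn{10^{-A(\lambda)}} with
#' \eqn{A(\lambda) = \epsilon\,\ell\,c\,g(\lambda)} where `g` is a unit-peak
#' Gaussian absorbance band at `absorbance_peak`.
#'
#' @param absorbance_peak Absorbance band centre, nm.
#' @param absorbance_fwhm Absorbance band FWHM, nm.
#' @param molar_absorptivity_scale Absorbance per (concentration unit x cm)
#'   at the band peak.
#' @param path_length Optical path, cm.
#' @param led_center,led_fwhm,led_amplitude LED emission parameters (nm, nm,
#'   intensity).
#' @param unit Concentration unit tag.
#' @return A `ggp_chromogen` object.
#' @export
chromogen_model <- function(absorbance_peak, absorbance_fwhm = 50,
                            molar_absorptivity_scale, path_length = 1,
                            led_center, led_fwhm = 20, led_amplitude = 1,
                            unit = "mg/L") {
  for (nm in c("absorbance_peak", "absorbance_fwhm", "molar_absorptivity_scale",
               "path_length", "led_center", "led_fwhm", "led_amplitude"))
    assert_scalar_num(get(nm), nm, lower = 0, strict_lower = TRUE)
  structure(list(absorbance_peak = absorbance_peak,
                 absorbance_fwhm = absorbance_fwhm,
                 molar_absorptivity_scale = molar_absorptivity_scale,
                 path_length = path_length, led_center = led_center,
                 led_fwhm = led_fwhm, led_amplitude = led_amplitude,
                 unit = unit),
            class = "ggp_chromogen")
}

led_spectrum <- function(model, grid) {
  sigma <- model$led_fwhm / (2 * sqrt(2 * log(2)))
  model$led_amplitude * exp(-0.5 * ((grid - model$led_center) / sigma)^2)
}

#' Transmitted spectrum of a chromogenic sample
#'
#' @param model A [chromogen_model()].
#' @param effective_concentration Concentration of the absorbing complex
#'   (>= 0).
#' @param grid Wavelength grid, nm.
#' @return A [spectrum_sample()].
#' @export
transmitted_spectrum <- function(model, effective_concentration,
                                 grid = default_wavelength_grid()) {
  stopifnot(inherits(model, "ggp_chromogen"))
  if (effective_concentration < 0)
    stop_ggp("concentration must be non-negative", "ggpgmr_validation_error")
  band <- exp(-4 * log(2) * ((grid - model$absorbance_peak) /
                               model$absorbance_fwhm)^2)
  A <- model$molar_absorptivity_scale * model$path_length *
    effective_concentration * band
  spectrum_sample(grid, led_spectrum(model, grid) * 10^(-A))
}

#' First-order colour-development kinetics
#'
#' The absorbing complex forms as
#' \eqn{c_{eff}(t) = c\,(1 - e^{-kt})}; readouts are taken at `read_times`
#' (minutes), by default immediately after reagent loading (0 min) and after
#' 5 min of incubation.
#'
#' @param rate_constant Formation rate `k`, per minute (>= 0).
#' @param read_times Non-decreasing read times, minutes.
#' @return A `ggp_kinetics` object.
#' @export
kinetic_model <- function(rate_constant = 0.24, read_times = c(0, 5)) {
  assert_scalar_num(rate_constant, "rate_constant", lower = 0)
  if (any(diff(read_times) < 0))
    stop_ggp("read_times must be non-decreasing", "ggpgmr_validation_error")
  structure(list(rate_constant = rate_constant, read_times = read_times),
            class = "ggp_kinetics")
}

#' Transmitted spectra at the kinetic read times
#'
#' @param chromogen A [chromogen_model()].
#' @param kinetics A [kinetic_model()].
#' @param concentration Analyte concentration (>= 0).
#' @param grid Wavelength grid, nm.
#' @return Named list of [spectrum_sample()]s, one per read time
#'   (`"t0"`, `"t5"`, ...).
#' @export
kinetic_pair <- function(chromogen, kinetics, concentration,
                         grid = default_wavelength_grid()) {
  stopifnot(inherits(kinetics, "ggp_kinetics"))
  out <- lapply(kinetics$read_times, function(t) {
    ceff <- concentration * (1 - exp(-kinetics$rate_constant * t))
    transmitted_spectrum(chromogen, ceff, grid)
  })
  names(out) <- paste0("t", kinetics$read_times)
  out
}

#' Stock assay presets
#'
#' Four presets covering the measured assay classes:
#' \describe{
#'   \item{`"tamra"`}{Rhodamine-like dye in methanol, 1e-3 to 1e-7 M; peak
#'     600 nm at 1e-3 M shifting -34/3 nm per decade (566 nm at 1e-6 M),
#'     saturating amplitude.}
#'   \item{`"hsa-fluorescent"`}{Albumin blue 580 + human serum albumin;
#'     peak fixed at 610 nm (centre of the observed 608--612 nm band),
#'     linear amplitude over 6.25--200 mg/L plus blank.}
#'   \item{`"creatinine-jaffe"`}{Kinetic picrate assay: absorbance band at
#'     510 nm read with a 535-nm LED at 0 and 5 min; first-order development
#'     reaching ~70\% of asymptote at 5 min; 50--500 mg/L plus blank.}
#'   \item{`"albumin-bcg"`}{Bromocresol-green albumin: absorbance band at
#'     620 nm read with a 625-nm LED; strongly saturating response over
#'     5--50 mg/mL plus blank.}
#' }
#'
#' @param name Preset name.
#' @param seed Seed stored in the preset's sampling plan.
#' @return A `ggp_assay` list: `name`, `type` (`"fluorescent"` or
#'   `"colorimetric"`), `model`, `kinetics` (or NULL), `plan`, `unit`.
#' @export
assay_preset <- function(name = c("tamra", "hsa-fluorescent",
                                  "creatinine-jaffe", "albumin-bcg"),
                         seed = 1) {
  name <- match.arg(name)
  out <- switch(name,
    "tamra" = list(
      type = "fluorescent",
      model = fluorophore_model(base_peak = 600,
                                peak_shift_per_decade = 34 / 3,
                                reference_concentration = 1e-3,
                                emission_fwhm = 40,
                                amplitude_law = "saturating",
                                amplitude_scale = 1,
                                saturation_constant = 1e-4,
                                background = 0, unit = "M"),
      kinetics = NULL,
      plan = sample_plan(10^-(3:7), unit = "M", include_blank = FALSE,
                         seed = seed)),
    "hsa-fluorescent" = list(
      type = "fluorescent",
      model = fluorophore_model(base_peak = 610, peak_shift_per_decade = 0,
                                reference_concentration = 200,
                                emission_fwhm = 35,
                                amplitude_law = "linear",
                                amplitude_scale = 1, background = 0.002,
                                unit = "mg/L"),
      kinetics = NULL,
      plan = sample_plan(c(200, 150, 100, 50, 25, 12.5, 6.25), unit = "mg/L",
                         include_blank = TRUE, seed = seed)),
    "creatinine-jaffe" = list(
      type = "colorimetric",
      model = chromogen_model(absorbance_peak = 510, absorbance_fwhm = 60,
                              molar_absorptivity_scale = 0.0016,
                              path_length = 1, led_center = 535,
                              led_fwhm = 20, led_amplitude = 1,
                              unit = "mg/L"),
      kinetics = kinetic_model(rate_constant = 0.24, read_times = c(0, 5)),
      plan = sample_plan(c(500, 400, 300, 200, 150, 100, 50), unit = "mg/L",
                         include_blank = TRUE, seed = seed)),
    "albumin-bcg" = list(
      type = "colorimetric",
      model = chromogen_model(absorbance_peak = 620, absorbance_fwhm = 40,
                              molar_absorptivity_scale = 0.03,
                              path_length = 1, led_center = 625,
                              led_fwhm = 20, led_amplitude = 1,
                              unit = "mg/mL"),
      kinetics = NULL,
      plan = sample_plan(c(50, 40, 30, 20, 10, 5), unit = "mg/mL",
                         include_blank = TRUE, seed = seed)))
  out$name <- name
  out$unit <- out$model$unit
  structure(out, class = "ggp_assay")
}
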