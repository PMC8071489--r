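#' Spectrum and CCD-trace containers
#'
#' A spectrum sample is intensity versus wavelength on a strictly increasing
#' grid; a CCD trace is intensity versus pixel index. Both are plain
#' data.frames with a class tag so methods can dispatch, mirroring the two
#' domains the filter maps between.
#'
#' @param wavelength_nm Strictly increasing wavelength grid, nm.
#' @param intensity Non-negative intensities, same length.
#' @return A `ggp_spectrum` data.frame with columns `wavelength_nm`,
#'   `intensity`.
#' @export
spectrum_sample <- function(wavelength_nm, intensity) {
  if (length(wavelength_nm) != length(intensity))
    stop_ggp("wavelength grid and intensities differ in length",
             "ggpgmr_validation_error")
  if (any(diff(wavelength_nm) <= 0))
    stop_ggp("wavelength grid must be strictly increasing", "ggpgmr_validation_error")
  if (any(intensity < 0))
    stop_ggp("intensities must be non-negative", "ggpgmr_validation_error")
  structure(data.frame(wavelength_nm = wavelength_nm, intensity = intensity),
            class = c("ggp_spectrum", "data.frame"))
}

#' @param pixel Integer pixel indices.
#' @param intensity Non-negative intensities.
#' @param metadata Optional named list (exposure tag, seed, ...).
#' @rdname spectrum_sample
#' @return For `ccd_trace()`, a `ggp_ccd_trace` data.frame with columns
#'   `pixel`, `intensity`.
#' @export
ccd_trace <- function(pixel, intensity, metadata = list()) {
  if (length(pixel) != length(intensity))
    stop_ggp("pixel indices and intensities differ in length",
             "ggpgmr_validation_error")
  if (any(intensity < 0))
    stop_ggp("trace intensities must be non-negative", "ggpgmr_validation_error")
  structure(data.frame(pixel = as.integer(pixel), intensity = intensity),
            metadata = metadata,
            class = c("ggp_ccd_trace", "data.frame"))
}

#' Default instrument wavelength grid
#'
#' 200 bins at 1-nm spacing starting at 500 nm (500--699 nm): the
#' half-open convention that keeps both the wavelength index and the
#' selected readout pixels at 200 while covering the 500--700 nm band.
#'
#' @return Numeric vector of length 200.
#' @export
default_wavelength_grid <- function() seq(500, by = 1, length.out = 200)

#' Narrowband (monochromator-like) spectrum
#'
#' Gaussian line of given FWHM centred at `center`, peak `amplitude`,
#' evaluated on `grid`. Emulates a broadband-lamp-plus-monochromator source
#' with ~2.5-nm linewidth.
#'
#' @param center Centre wavelength, nm; must lie inside the grid span.
#' @param linewidth FWHM, nm.
#' @param amplitude Peak intensity (arbitrary linear units).
#' @param grid Wavelength grid, nm.
#' @return A [spectrum_sample()].
#' @export
monochromatic_spectrum <- function(center, linewidth = 2.5, amplitude = 1,
                                   grid = default_wavelength_grid()) {
  assert_scalar_num(linewidth, "linewidth", lower = 0, strict_lower = TRUE)
  if (center < min(grid) || center > max(grid))
    stop_ggp("`center` lies outside the wavelength grid", "ggpgmr_range_error")
  sigma <- linewidth / (2 * sqrt(2 * log(2)))
  spectrum_sample(grid, amplitude * exp(-0.5 * ((grid - center) / sigma)^2))
}
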