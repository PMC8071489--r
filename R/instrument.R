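#' Linear-CCD geometry
#'
#' Maps device coordinates to pixel indices: pixel `i` (1-based) spans
#' `[position_offset + (i-1)*pixel_pitch, position_offset + i*pixel_pitch)`
#' in the device frame, so `position_offset` is the device coordinate of
#' pixel 1's left edge. Use [anchor_ccd()] to place the CCD so the printed
#' pixel numbering (MICP 2073 at 500 nm through 2361 at 700 nm) is
#' reproduced for a given layout.
#'
#' @param pixel_pitch Pixel pitch, nm per pixel.
#' @param n_pixels Number of pixels on the sensor.
#' @param position_offset Device coordinate (nm) of pixel 1's left edge;
#'   may be negative (sensor extends beyond the filter).
#' @param anchor Optional record of the (pixel, wavelength) anchors used to
#'   derive the geometry; informational.
#' @return A `ggp_ccd_geometry` object.
#' @export
ccd_geometry <- function(pixel_pitch = 8000, n_pixels = 3000,
                         position_offset = 0, anchor = NULL) {
  assert_scalar_num(pixel_pitch, "pixel_pitch", lower = 0, strict_lower = TRUE)
  assert_scalar_num(n_pixels, "n_pixels", lower = 1)
  assert_scalar_num(position_offset, "position_offset")
  structure(list(pixel_pitch = pixel_pitch, n_pixels = as.integer(n_pixels),
                 position_offset = position_offset, anchor = anchor),
            class = "ggp_ccd_geometry")
}

# device position at which the layout resonates at `wavelength` (segment
# centres interpolated linearly over resonance; clamped at the end segments,
# where the dip of an out-of-band input saturates)
layout_position_of <- function(layout, wavelength) {
  x <- layout$resonant_wavelength_nm
  y <- layout$start_nm + layout$length_nm / 2
  approx(x, y, xout = wavelength, rule = 2)$y
}

#' Anchor a CCD to a layout via printed pixel numbers
#'
#' Chooses pitch and offset so that the device position resonating at
#' `wavelength1` falls on the centre of pixel `pixel1` and likewise for the
#' second anchor --- the configuration in which the MICP runs from pixel 2073
#' at 500 nm to pixel 2361 at 700 nm.
#'
#' @param layout A [build_layout()] result whose resonances cover both
#'   anchor wavelengths (up to mild extrapolation at the band edges).
#' @param pixel1,wavelength1,pixel2,wavelength2 The two anchors.
#' @param n_pixels Sensor length in pixels.
#' @return A [ccd_geometry()].
#' @export
anchor_ccd <- function(layout, pixel1 = 2073, wavelength1 = 500,
                       pixel2 = 2361, wavelength2 = 700, n_pixels = 3000) {
  stopifnot(inherits(layout, "ggp_device_layout"), pixel2 > pixel1,
            wavelength2 > wavelength1)
  p1 <- layout_position_of(layout, wavelength1)
  p2 <- layout_position_of(layout, wavelength2)
  pitch <- (p2 - p1) / (pixel2 - pixel1)
  offset <- p1 - (pixel1 - 0.5) * pitch
  ccd_geometry(pixel_pitch = pitch, n_pixels = n_pixels,
               position_offset = offset,
               anchor = list(pixel = c(pixel1, pixel2),
                             wavelength = c(wavelength1, wavelength2)))
}

#' Resonance lineshape of the bandstop dip
#'
#' The guided-mode resonance rejects a narrow band around the Bragg
#' wavelength; transmission is modelled as \eqn{1 - d\,L(\lambda-\lambda_R)}
#' with `L` a unit-peak Lorentzian (default) or Gaussian of FWHM `fwhm`.
#'
#' @param depth Dip depth `d` in (0, 1]; 1 means total rejection on
#'   resonance.
#' @param fwhm Full width at half maximum of the dip, nm.
#' @param shape `"lorentzian"` or `"gaussian"`.
#' @return A `ggp_lineshape` object.
#' @export
resonance_lineshape <- function(depth = 0.9, fwhm = 3,
                                shape = c("lorentzian", "gaussian")) {
  shape <- match.arg(shape)
  assert_scalar_num(depth, "depth", lower = 0, upper = 1, strict_lower = TRUE)
  assert_scalar_num(fwhm, "fwhm", lower = 0, strict_lower = TRUE)
  structure(list(depth = depth, fwhm = fwhm, shape = shape),
            class = "ggp_lineshape")
}

#' Transmission of one grating period at one wavelength
#'
#' @param lineshape A [resonance_lineshape()].
#' @param wavelength Wavelength(s), nm.
#' @param resonant_wavelength The period's Bragg resonance, nm.
#' @return Transmission in `[1 - depth, 1]`, vectorized over `wavelength`.
#' @export
transmission_profile <- function(lineshape, wavelength, resonant_wavelength) {
  stopifnot(inherits(lineshape, "ggp_lineshape"))
  d <- wavelength - resonant_wavelength
  L <- switch(lineshape$shape,
              lorentzian = 1 / (1 + (2 * d / lineshape$fwhm)^2),
              gaussian   = exp(-4 * log(2) * (d / lineshape$fwhm)^2))
  1 - lineshape$depth * L
}

# per-pixel resonance: overlap-weighted mean resonant wavelength of the
# segments under each pixel, plus the fraction of the pixel covered by the
# device at all
pixel_resonances <- function(layout, ccd, pixels) {
  starts <- layout$start_nm
  ends <- layout$start_nm + layout$length_nm
  total <- attr(layout, "total_length_nm")
  lamR <- layout$resonant_wavelength_nm
  p <- ccd$pixel_pitch
  res <- numeric(length(pixels))
  cov <- numeric(length(pixels))
  spans <- integer(length(pixels))
  for (k in seq_along(pixels)) {
    left <- ccd$position_offset + (pixels[k] - 1) * p
    right <- left + p
    a <- max(left, 0); b <- min(right, total)
    if (b <= a) { res[k] <- NA_real_; cov[k] <- 0; next }
    i1 <- findInterval(a, starts, rightmost.closed = TRUE)
    i2 <- findInterval(b - 1e-9, starts, rightmost.closed = TRUE)
    idx <- i1:i2
    w <- pmin(ends[idx], b) - pmax(starts[idx], a)
    res[k] <- sum(w * lamR[idx]) / sum(w)
    cov[k] <- (b - a) / p
    spans[k] <- length(idx)
  }
  if (any(spans > 2))
    warning("pixel pitch coarse: some pixels span more than two grating segments")
  data.frame(pixel = pixels, resonance_nm = res, coverage = cov)
}

#' Build the transmission-efficiency matrix T
#'
#' Entry `T[i, j]` is the filter transmission at readout pixel `i` for
#' incident wavelength `j`: each pixel inherits the resonance of the grating
#' segment over it (length-weighted when a pixel straddles two segments) and
#' applies the bandstop lineshape; pixels only partially covered by the
#' device blend with unit transmission, and `pad_pixels` uncovered pixels of
#' unit transmission are kept either side so dips near the band edges retain
#' a baseline. With `paper_mode = TRUE` the rows are restricted to the one
#' pixel whose resonance is nearest each grid wavelength, giving the square
#' (e.g. 200 x 200) matrix convention.
#'
#' @param layout A [build_layout()] result.
#' @param ccd A [ccd_geometry()].
#' @param lineshape A [resonance_lineshape()].
#' @param wavelength_grid Column wavelengths, nm (default
#'   [default_wavelength_grid()]).
#' @param paper_mode Square output with one row per wavelength bin.
#' @param pad_pixels Uncovered unit-transmission rows kept either side
#'   (ignored in paper mode).
#' @return A `ggp_transmission_matrix`: list with the matrix `T` (dimnames:
#'   pixels, wavelengths), `pixels`, `wavelengths`, `resonance_nm` per row,
#'   and the generating `ccd`.
#' @export
build_transmission_matrix <- function(layout, ccd, lineshape,
                                      wavelength_grid = default_wavelength_grid(),
                                      paper_mode = FALSE, pad_pixels = 15) {
  stopifnot(inherits(layout, "ggp_device_layout"),
            inherits(ccd, "ggp_ccd_geometry"),
            inherits(lineshape, "ggp_lineshape"))
  if (any(diff(wavelength_grid) <= 0))
    stop_ggp("wavelength grid must be strictly increasing", "ggpgmr_validation_error")
  total <- attr(layout, "total_length_nm")
  first <- floor((0 - ccd$position_offset) / ccd$pixel_pitch) + 1L
  last <- ceiling((total - ccd$position_offset) / ccd$pixel_pitch)
  first <- max(1L, first - as.integer(pad_pixels))
  last <- min(ccd$n_pixels, last + as.integer(pad_pixels))
  pixels <- first:last
  pr <- pixel_resonances(layout, ccd, pixels)

  if (paper_mode) {
    covered <- which(pr$coverage > 0)
    sel <- covered[vapply(wavelength_grid, function(w)
      which.min(abs(pr$resonance_nm[covered] - w)), 0L)]
    pr <- pr[sel, ]
    pixels <- pr$pixel
  }

  Tm <- matrix(1, nrow = length(pixels), ncol = length(wavelength_grid),
               dimnames = list(pixels, wavelength_grid))
  covered <- which(pr$coverage > 0)
  for (k in covered) {
    Tk <- transmission_profile(lineshape, wavelength_grid, pr$resonance_nm[k])
    Tm[k, ] <- pr$coverage[k] * Tk + (1 - pr$coverage[k])
  }
  structure(list(T = Tm, pixels = pixels, wavelengths = wavelength_grid,
                 resonance_nm = pr$resonance_nm, coverage = pr$coverage,
                 ccd = ccd, lineshape = lineshape),
            class = "ggp_transmission_matrix")
}

#' @export
print.ggp_transmission_matrix <- function(x, ...) {
  cat(sprintf("transmission matrix: %d pixels x %d wavelengths (%g-%g nm), pixels %d-%d\n",
              nrow(x$T), ncol(x$T), min(x$wavelengths), max(x$wavelengths),
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Instrument noise parameters
#'
#' Additive dark offset, Gaussian read noise, and signal-dependent shot
#' noise (standard deviation `shot_noise_scale * sqrt(C)`), all seeded for
#' reproducibility. Zeros disable each term.
#'
#' @param read_noise_sd Read-noise standard deviation, intensity units.
#' @param shot_noise_scale Shot-noise scale (0 disables).
#' @param dark_offset Constant dark level, intensity units.
#' @param seed Integer seed; `NULL` draws from the session RNG stream.
#' @return A `ggp_noise_params` object.
#' @export
noise_params <- function(read_noise_sd = 0, shot_noise_scale = 0,
                         dark_offset = 0, seed = NULL) {
  assert_scalar_num(read_noise_sd, "read_noise_sd", lower = 0)
  assert_scalar_num(shot_noise_scale, "shot_noise_scale", lower = 0)
  assert_scalar_num(dark_offset, "dark_offset", lower = 0)
  structure(list(read_noise_sd = read_noise_sd,
                 shot_noise_scale = shot_noise_scale,
                 dark_offset = dark_offset, seed = seed),
            class = "ggp_noise_params")
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

#' Simulate the CCD readout C = TI
#'
#' The noiseless core is the matrix-vector product of the transmission
#' matrix with the digitized incident spectrum; noise (if given) adds the
#' dark offset, Gaussian read noise and shot noise, after which intensities
#' are clipped at zero.
#'
#' @param tm A [build_transmission_matrix()] result.
#' @param spectrum A [spectrum_sample()] on exactly the matrix's column
#'   wavelengths.
#' @param noise Optional [noise_params()].
#' @param quantize Round intensities to integer counts.
#' @return A [ccd_trace()] over the matrix's row pixels.
#' @export
forward_readout <- function(tm, spectrum, noise = NULL, quantize = FALSE) {
  stopifnot(inherits(tm, "ggp_transmission_matrix"),
            inherits(spectrum, "ggp_spectrum"))
  if (length(spectrum$wavelength_nm) != length(tm$wavelengths) ||
      max(abs(spectrum$wavelength_nm - tm$wavelengths)) > 1e-9)
    stop_ggp("spectrum grid does not match the transmission matrix columns",
             "ggpgmr_dimension_error")
  C <- drop(tm$T %*% spectrum$intensity)
  meta <- list()
  if (!is.null(noise)) {
    stopifnot(inherits(noise, "ggp_noise_params"))
    C <- with_seed(noise$seed, {
      n <- length(C)
      C + noise$dark_offset +
        (if (noise$read_noise_sd > 0) rnorm(n, 0, noise$read_noise_sd) else 0) +
        (if (noise$shot_noise_scale > 0)
          rnorm(n, 0, noise$shot_noise_scale * sqrt(pmax(C, 0))) else 0)
    })
    meta$seed <- noise$seed
  }
  C <- pmax(C, 0)
  if (quantize) C <- round(C)
  ccd_trace(tm$pixels, C, metadata = meta)
}
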