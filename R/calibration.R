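#' Locate the minimum-intensity corresponding pixel (MICP)
#'
#' Smooths the trace with a moving average, takes the discrete argmin, and
#' refines it with a parabola through the three smoothed points around the
#' minimum. The dip depth is measured against the local baseline (median of
#' the smoothed trace); traces whose dip is shallower than `min_dip_depth`
#' (for example dark frames) raise a no-dip error. Multiple equal minima
#' after smoothing resolve to the lowest pixel index with `tie = TRUE`.
#'
#' @param trace A [ccd_trace()].
#' @param smoothing_window Moving-average window, pixels (odd recommended).
#' @param min_dip_depth Minimum fractional dip depth accepted.
#' @return List with `micp` (integer pixel), `subpixel` (refined position),
#'   `dip_depth`, `intensity` (raw trace intensity at the MICP pixel) and
#'   `tie`.
#' @export
find_micp <- function(trace, smoothing_window = 5, min_dip_depth = 0.05) {
  stopifnot(inherits(trace, "ggp_ccd_trace"))
  y <- trace$intensity
  if (length(y) < smoothing_window)
    stop_ggp("trace shorter than the smoothing window", "ggpgmr_validation_error")
  sm <- moving_average(y, smoothing_window)
  mins <- which(sm == min(sm))
  # contiguous runs of equal minima: a flat run centres the estimate; several
  # separate runs are a genuine tie, resolved to the lowest-pixel run
  breaks <- c(0L, which(diff(mins) > 1L), length(mins))
  run <- mins[(breaks[1] + 1L):breaks[2]]
  tie <- length(breaks) > 2L
  m <- run[ceiling(length(run) / 2)]
  baseline <- median(sm)
  if (baseline <= 0)
    stop_ggp("no dip found: zero baseline", "ggpgmr_no_dip_error")
  dip_depth <- (baseline - sm[m]) / baseline
  if (dip_depth < min_dip_depth)
    stop_ggp(sprintf("no dip found: depth %.4f below threshold %.4f",
                     dip_depth, min_dip_depth), "ggpgmr_no_dip_error")
  sub <- if (length(run) > 1L) mean(run) else m
  if (length(run) == 1L && m > 1L && m < length(sm)) {
    denom <- sm[m - 1] - 2 * sm[m] + sm[m + 1]
    if (denom > 0) sub <- m + 0.5 * (sm[m - 1] - sm[m + 1]) / denom
  }
  subpixel <- trace$pixel[1] + (sub - 1)  # trace indices -> pixel numbers
  micp <- as.integer(round(subpixel))
  list(micp = micp, subpixel = subpixel, dip_depth = dip_depth,
       intensity = trace$intensity[match(micp, trace$pixel)], tie = tie)
}

#' Build the wavelength/MICP calibration curve
#'
#' Reproduces the monochromator-scan calibration: one narrowband readout per
#' scan wavelength, MICP extraction, then an isotonic (pool-adjacent-
#' violators) projection to repair small inversions before the monotone
#' forward and inverse lookups are stored. Raw scans with inversions larger
#' than `max_inversion` pixels fail instead of being silently repaired.
#'
#' @param tm A [build_transmission_matrix()] for the system under
#'   calibration (noise-free scans by default, matching the amplitude
#'   independence of the MICP).
#' @param scan_range Length-2 numeric, scan limits in nm; defaults to the
#'   matrix's wavelength span.
#' @param scan_step Scan increment, nm.
#' @param linewidth Source FWHM, nm.
#' @param noise Optional [noise_params()] applied to every scan readout.
#' @param smoothing_window,min_dip_depth Passed to [find_micp()].
#' @param max_inversion Largest tolerated raw non-monotonicity, pixels.
#' @return A `ggp_calibration_curve`: data.frame of knots `wavelength_nm`,
#'   `micp_pixel` (post-isotonic sub-pixel positions) with attribute
#'   `valid_range`.
#' @export
build_calibration_curve <- function(tm, scan_range = NULL, scan_step = 1,
                                    linewidth = 2.5, noise = NULL,
                                    smoothing_window = 5, min_dip_depth = 0.05,
                                    max_inversion = 2) {
  stopifnot(inherits(tm, "ggp_transmission_matrix"))
  if (is.null(scan_range)) scan_range <- range(tm$wavelengths)
  if (scan_range[1] < min(tm$wavelengths) || scan_range[2] > max(tm$wavelengths))
    stop_ggp("scan range outside the instrument wavelength grid",
             "ggpgmr_range_error")
  wl <- seq(scan_range[1], scan_range[2], by = scan_step)
  raw <- vapply(seq_along(wl), function(i) {
    sp <- monochromatic_spectrum(wl[i], linewidth = linewidth, amplitude = 1,
                                 grid = tm$wavelengths)
    ns <- if (is.null(noise)) NULL else
      noise_params(noise$read_noise_sd, noise$shot_noise_scale,
                   noise$dark_offset,
                   seed = if (is.null(noise$seed)) NULL else
                     child_seed(noise$seed, i, stream = 7L))
    find_micp(forward_readout(tm, sp, ns), smoothing_window, min_dip_depth)$subpixel
  }, 0)
  inv <- cummax(raw) - raw
  if (max(inv) > max_inversion)
    stop_ggp(sprintf("calibration scan non-monotone by %.2f pixels (> %g allowed)",
                     max(inv), max_inversion), "ggpgmr_calibration_error")
  iso <- isoreg(wl, raw)$yf
  structure(data.frame(wavelength_nm = wl, micp_pixel = iso),
            valid_range = range(wl),
            class = c("ggp_calibration_curve", "data.frame"))
}

#' @export
print.ggp_calibration_curve <- function(x, ...) {
  cat(sprintf("calibration curve: %d knots, %g-%g nm -> pixels %.1f-%.1f\n",
              nrow(x), min(x$wavelength_nm), max(x$wavelength_nm),
              min(x$micp_pixel), max(x$micp_pixel)))
  invisible(x)
}

#' Forward and inverse calibration lookups
#'
#' Linear interpolation between the stored knots; out-of-range queries raise
#' an extrapolation error rather than extrapolating silently. The inverse
#' lookup resolves flat runs of the monotone fit to their mean wavelength.
#'
#' @param curve A [build_calibration_curve()] result (or one read back with
#'   [read_calibration_csv()]).
#' @param wavelength_nm Wavelength(s), nm.
#' @return Sub-pixel MICP position(s).
#' @export
wavelength_to_pixel <- function(curve, wavelength_nm) {
  stopifnot(inherits(curve, "ggp_calibration_curve"))
  vr <- attr(curve, "valid_range")
  if (any(wavelength_nm < vr[1] | wavelength_nm > vr[2]))
    stop_ggp("wavelength outside the calibration valid range",
             "ggpgmr_extrapolation_error")
  approx(curve$wavelength_nm, curve$micp_pixel, xout = wavelength_nm,
         ties = mean)$y
}

#' @param micp Sub-pixel MICP position(s).
#' @rdname wavelength_to_pixel
#' @return For `micp_to_wavelength()`, wavelength(s) in nm.
#' @export
micp_to_wavelength <- function(curve, micp) {
  stopifnot(inherits(curve, "ggp_calibration_curve"))
  pr <- range(curve$micp_pixel)
  if (any(micp < pr[1] | micp > pr[2]))
    stop_ggp("MICP outside the calibrated pixel range",
             "ggpgmr_extrapolation_error")
  approx(curve$micp_pixel, curve$wavelength_nm, xout = micp, ties = mean)$y
}

#' Calibration CSV round trip
#'
#' Header `wavelength_nm,micp_pixel`, one row per scan wavelength
#' (post-isotonic), full-precision decimal text.
#'
#' @param curve A calibration curve.
#' @param path File path.
#' @return `path` (write) or the curve (read).
#' @export
write_calibration_csv <- function(curve, path) {
  stopifnot(inherits(curve, "ggp_calibration_curve"))
  df <- data.frame(wavelength_nm = format(curve$wavelength_nm, digits = 15,
                                          trim = TRUE),
                   micp_pixel = format(curve$micp_pixel, digits = 15,
                                       trim = TRUE))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_calibration_csv
#' @export
read_calibration_csv <- function(path) {
  df <- read_checked_csv(path, c("wavelength_nm", "micp_pixel"))
  if (any(diff(df$wavelength_nm) <= 0))
    stop_ggp("calibration wavelengths must be strictly increasing",
             "ggpgmr_format_error")
  structure(df, valid_range = range(df$wavelength_nm),
            class = c("ggp_calibration_curve", "data.frame"))
}
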