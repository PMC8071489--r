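#' Extract a peak/MICP measurement from one readout
#'
#' GGP-GMR channel (a CCD trace): locate the MICP with [find_micp()], map
#' the sub-pixel position to wavelength through the calibration curve, and
#' report the raw trace intensity at the MICP pixel. Spectrometer channel
#' (a spectrum): 5-bin moving-average smoothing, argmax, parabolic sub-bin
#' refinement. A MICP outside the calibration range yields a flagged
#' measurement with `NA` wavelength rather than an error.
#'
#' @param x A [ccd_trace()] or a [spectrum_sample()].
#' @param curve Calibration curve; required for traces.
#' @param smoothing_window,min_dip_depth Passed to [find_micp()] (traces
#'   only).
#' @return A `ggp_measurement` list: `channel`, `intensity`, `flagged`, and
#'   either `micp_pixel`/`subpixel`/`estimated_wavelength_nm` or
#'   `peak_wavelength_nm`.
#' @export
extract_measurement <- function(x, curve = NULL, smoothing_window = 5,
                                min_dip_depth = 0.05) {
  if (inherits(x, "ggp_ccd_trace")) {
    if (is.null(curve))
      stop_ggp("a calibration curve is required for CCD traces",
               "ggpgmr_validation_error")
    fm <- find_micp(x, smoothing_window, min_dip_depth)
    wl <- tryCatch(micp_to_wavelength(curve, fm$subpixel),
                   ggpgmr_extrapolation_error = function(e) NA_real_)
    out <- list(channel = "ggp-gmr", micp_pixel = fm$micp,
                subpixel = fm$subpixel, estimated_wavelength_nm = wl,
                intensity = fm$intensity, flagged = is.na(wl))
  } else if (inherits(x, "ggp_spectrum")) {
    sm <- moving_average(x$intensity, smoothing_window)
    m <- which.max(sm)
    sub <- m
    if (m > 1L && m < length(sm)) {
      denom <- sm[m - 1] - 2 * sm[m] + sm[m + 1]
      if (denom < 0) sub <- m + 0.5 * (sm[m - 1] - sm[m + 1]) / denom
    }
    step <- x$wavelength_nm[2] - x$wavelength_nm[1]
    out <- list(channel = "spectrometer",
                peak_wavelength_nm = x$wavelength_nm[1] + (sub - 1) * step,
                intensity = x$intensity[m], flagged = FALSE)
  } else {
    stop_ggp("`x` must be a CCD trace or a spectrum sample",
             "ggpgmr_validation_error")
  }
  structure(out, class = "ggp_measurement")
}

#' Measure every record of a dataset through both channels
#'
#' Applies [extract_measurement()] to each trace/spectrum pair. For kinetic
#' (two-timepoint) assays the dose-response observable is instead the
#' intensity at a fixed readout location --- `readout_wavelength` on the
#' spectrometer and its calibrated pixel on the CCD --- as peak finding is
#' meaningless for a monotone LED band.
#'
#' Two reading conventions govern the dose-response intensity of the CCD
#' channel. `"sample"` reads each trace at its own detected MICP.
#' `"reference"` reads every trace of a run at the MICP pixel of that run's
#' highest-concentration measurement --- the bench convention for assays whose
#' emission peak does not move with concentration, where it avoids coupling
#' the read noise to the minimum search (reading at a noisy argmin
#' systematically picks noise troughs and distorts replicate statistics).
#' The default `"auto"` picks `"reference"` for fluorophore models with zero
#' peak shift per decade and `"sample"` otherwise. Either way, dim traces
#' (blanks, lowest dilutions) with no detectable dip fall back to the
#' reference pixel.
#'
#' @param dataset A [generate_dataset()] result.
#' @param curve Calibration curve for the GGP-GMR channel.
#' @param readout_wavelength Fixed readout wavelength (nm) for kinetic
#'   assays; defaults to the chromogen's LED centre.
#' @param intensity_at `"auto"`, `"sample"` or `"reference"` (see Details).
#' @return A data.frame: id, run, replicate, concentration, timepoint,
#'   channel, wavelength_nm, micp_pixel, intensity.
#' @export
measure_dataset <- function(dataset, curve, readout_wavelength = NULL,
                            intensity_at = c("auto", "sample", "reference")) {
  stopifnot(inherits(dataset, "ggp_assay_dataset"))
  intensity_at <- match.arg(intensity_at)
  if (intensity_at == "auto")
    intensity_at <- if (dataset$assay$type == "fluorescent" &&
                        dataset$assay$model$peak_shift_per_decade == 0)
      "reference" else "sample"
  kinetic <- !is.null(dataset$assay$kinetics)
  if (kinetic && is.null(readout_wavelength))
    readout_wavelength <- dataset$assay$model$led_center
  rows <- lapply(seq_len(nrow(dataset$index)), function(i) {
    ix <- dataset$index[i, ]
    tr <- dataset$traces[[ix$id]]
    sp <- dataset$spectra[[ix$id]]
    if (kinetic) {
      px <- as.integer(round(wavelength_to_pixel(curve, readout_wavelength)))
      g <- data.frame(channel = "ggp-gmr", wavelength_nm = readout_wavelength,
                      micp_pixel = px,
                      intensity = tr$intensity[match(px, tr$pixel)])
      sbin <- which.min(abs(sp$wavelength_nm - readout_wavelength))
      s <- data.frame(channel = "spectrometer",
                      wavelength_nm = sp$wavelength_nm[sbin],
                      micp_pixel = NA_integer_, intensity = sp$intensity[sbin])
    } else {
      mg <- tryCatch(extract_measurement(tr, curve),
                     ggpgmr_no_dip_error = function(e) NULL)
      ms <- extract_measurement(sp)
      g <- if (is.null(mg))
        data.frame(channel = "ggp-gmr", wavelength_nm = NA_real_,
                   micp_pixel = NA_integer_, intensity = NA_real_)
      else
        data.frame(channel = "ggp-gmr",
                   wavelength_nm = mg$estimated_wavelength_nm,
                   micp_pixel = mg$micp_pixel, intensity = mg$intensity)
      s <- data.frame(channel = "spectrometer",
                      wavelength_nm = ms$peak_wavelength_nm,
                      micp_pixel = NA_integer_, intensity = ms$intensity)
    }
    cbind(ix[rep(1, 2), c("id", "run", "replicate", "concentration",
                          "timepoint")], rbind(g, s), row.names = NULL)
  })
  out <- do.call(rbind, rows)
  if (!kinetic && (intensity_at == "reference" ||
                   anyNA(out$intensity[out$channel == "ggp-gmr"]))) {
    cmax <- max(out$concentration)
    for (r in unique(out$run)) {
      sel <- out$channel == "ggp-gmr" & out$run == r
      ref_px <- out$micp_pixel[sel & out$concentration == cmax][1]
      if (is.na(ref_px))
        stop_ggp(sprintf("run %s: no dip even at the highest concentration", r),
                 "ggpgmr_no_dip_error")
      redo <- if (intensity_at == "reference") which(sel)
              else which(sel & is.na(out$intensity))
      for (i in redo) {
        tr <- dataset$traces[[out$id[i]]]
        out$intensity[i] <- tr$intensity[match(ref_px, tr$pixel)]
        if (is.na(out$micp_pixel[i])) out$micp_pixel[i] <- ref_px
      }
    }
  }
  out
}

#' Build a normalized dose-response table
#'
#' Non-kinetic assays: one intensity per (run, replicate, concentration),
#' normalized per run to the mean intensity at the highest concentration.
#' Kinetic assays: the raw observable is the intensity drop between the
#' first and last read times at the fixed readout location, normalized the
#' same way.
#'
#' @param measurements Data.frame with columns `run`, `concentration`,
#'   `intensity` (plus `timepoint` and `replicate` for kinetic mode), as
#'   from [measure_dataset()] filtered to one channel.
#' @param normalization `"max"` (per-run highest-concentration reference) or
#'   `"none"`.
#' @param kinetic Interpret rows as two-timepoint kinetic readouts.
#' @return A `ggp_dose_response` data.frame: `run`, `concentration`,
#'   `raw_intensity`, `normalized_intensity`; attribute `unit` if supplied.
#' @export
build_dose_response <- function(measurements, normalization = c("max", "none"),
                                kinetic = FALSE) {
  normalization <- match.arg(normalization)
  m <- as.data.frame(measurements)
  stopifnot(all(c("run", "concentration", "intensity") %in% names(m)))
  if (!"replicate" %in% names(m)) m$replicate <- 1L
  if (kinetic) {
    stopifnot("timepoint" %in% names(m))
    tps <- sort(unique(m$timepoint))
    if (length(tps) < 2L)
      stop_ggp("kinetic mode needs two timepoints", "ggpgmr_validation_error")
    key <- interaction(m$run, m$replicate, m$concentration, drop = TRUE)
    first <- m[m$timepoint == tps[1L], ]
    last <- m[m$timepoint == tps[length(tps)], ]
    k1 <- interaction(first$run, first$replicate, first$concentration, drop = FALSE)
    k2 <- interaction(last$run, last$replicate, last$concentration, drop = FALSE)
    last <- last[match(k1, k2), ]
    m <- data.frame(run = first$run, replicate = first$replicate,
                    concentration = first$concentration,
                    intensity = first$intensity - last$intensity)
  }
  cmax <- max(m$concentration)
  out <- do.call(rbind, lapply(split(m, m$run), function(g) {
    raw <- g$intensity
    if (normalization == "max") {
      refv <- g$intensity[g$concentration == cmax]
      ref <- mean(refv)
      if (!length(refv) || !is.finite(ref))
        stop_ggp(sprintf("run %s lacks a reference at the highest concentration",
                         g$run[1]), "ggpgmr_normalization_error")
      if (ref == 0) {
        if (any(abs(raw) > 0))
          stop_ggp(sprintf("run %s: zero reference with nonzero responses",
                           g$run[1]), "ggpgmr_normalization_error")
        norm <- raw  # no-reaction limit: table of zeros
      } else norm <- raw / ref
    } else norm <- raw
    data.frame(run = g$run, concentration = g$concentration,
               raw_intensity = raw, normalized_intensity = norm)
  }))
  rownames(out) <- NULL
  structure(out, kinetic = kinetic, normalization = normalization,
            class = c("ggp_dose_response", "data.frame"))
}

#' Fit the dose-response line (sensitivity)
#'
#' Ordinary least squares of normalized intensity against concentration
#' expressed in units of `per` (default 10, i.e. the slope is normalized
#' intensity per 10 concentration units --- the convention under which the
#' printed noise/sensitivity pairs reproduce the printed LODs). For assays
#' that are linear only at the low end, `lowest` restricts the fit to the
#' `lowest` smallest distinct concentrations (local-linear convention).
#'
#' @param table A [build_dose_response()] result.
#' @param per Concentration block size of the slope convention.
#' @param lowest Optional: use only this many lowest distinct concentrations.
#' @return A `ggp_dose_fit` with `slope` (per `per` units), `intercept`,
#'   `r_squared`, `n`, `degenerate` flag; supports `coef()`, `predict()`,
#'   `print()`, `summary()`.
#' @export
fit_dose_response <- function(table, per = 10, lowest = NULL) {
  stopifnot(inherits(table, "ggp_dose_response"))
  df <- as.data.frame(table)
  if (!is.null(lowest)) {
    keep <- sort(unique(df$concentration))[seq_len(lowest)]
    df <- df[df$concentration %in% keep, ]
  }
  if (length(unique(df$concentration)) < 3L)
    stop_ggp("need at least 3 distinct concentrations to fit",
             "ggpgmr_insufficient_data_error")
  x <- df$concentration / per
  y <- df$normalized_intensity
  degenerate <- var(y) == 0
  if (degenerate) {
    fit <- list(slope = 0, intercept = y[1], r_squared = 0)
  } else {
    lmfit <- lm(y ~ x)
    fit <- list(slope = unname(coef(lmfit)[2]),
                intercept = unname(coef(lmfit)[1]),
                r_squared = suppressWarnings(summary(lmfit)$r.squared))
  }
  structure(c(fit, list(per = per, n = nrow(df), degenerate = degenerate,
                        lowest = lowest)),
            class = "ggp_dose_fit")
}

#' @export
print.ggp_dose_fit <- function(x, ...) {
  cat(sprintf("dose-response fit: slope %.4g per %g units, intercept %.4g, R^2 %.4f (n = %d%s)\n",
              x$slope, x$per, x$intercept, x$r_squared, x$n,
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' @export
coef.ggp_dose_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.ggp_dose_fit <- function(object, concentration, ...) {
  object$intercept + object$slope * concentration / object$per
}

#' @export
summary.ggp_dose_fit <- function(object, ...) {
  structure(unclass(object), class = "summary.ggp_dose_fit")
}

#' @export
print.summary.ggp_dose_fit <- function(x, ...) {
  print(structure(x, class = "ggp_dose_fit"))
  invisible(x)
}

pooled_sd <- function(values, groups) {
  sp <- split(values, groups)
  df <- vapply(sp, function(v) length(v) - 1L, 0L)
  if (sum(df) < 1L)
    stop_ggp("noise undefined: need >= 2 replicates at some concentration",
             "ggpgmr_insufficient_data_error")
  ss <- vapply(sp, function(v) if (length(v) > 1) (length(v) - 1) * var(v) else 0, 0)
  sqrt(sum(ss) / sum(df))
}

#' Limit of detection from noise and sensitivity
#'
#' LOD = noise / sensitivity, with noise defined as three times the standard
#' deviation of the (normalized) measurements and sensitivity the
#' dose-response slope per `per` concentration units, so the LOD comes out
#' in the table's concentration units. The default noise population is the
#' pooled within-concentration SD (`"pooled"`); `"global"` (SD ignoring
#' concentration structure) and `"blank"` (blank replicates only) are
#' selectable. `noise` and `sensitivity` can also be supplied directly,
#' bypassing the table --- useful for reproducing printed worked numbers.
#'
#' @param table A [build_dose_response()] result (optional if `noise` and
#'   `sensitivity` are both given).
#' @param fit A [fit_dose_response()] result (optional if `sensitivity`
#'   given).
#' @param noise Noise (3 x SD) in normalized intensity units, overriding the
#'   table-derived value.
#' @param sensitivity Slope per `per` concentration units, overriding `fit`.
#' @param per Slope convention block size (must match the fit's).
#' @param noise_definition `"pooled"`, `"global"` or `"blank"`.
#' @return A `ggp_lod_result` list: `noise`, `sensitivity`, `lod`, `per`,
#'   `noise_definition`.
#' @examples
#' estimate_lod(noise = 0.1517, sensitivity = 0.037)$lod  # 41.0 mg/L
#' @export
estimate_lod <- function(table = NULL, fit = NULL, noise = NULL,
                         sensitivity = NULL, per = 10,
                         noise_definition = c("pooled", "global", "blank")) {
  noise_definition <- match.arg(noise_definition)
  if (is.null(sensitivity)) {
    stopifnot(inherits(fit, "ggp_dose_fit"))
    sensitivity <- fit$slope
    per <- fit$per
  }
  if (is.null(noise)) {
    stopifnot(inherits(table, "ggp_dose_response"))
    y <- table$normalized_intensity
    noise <- 3 * switch(noise_definition,
      pooled = pooled_sd(y, table$concentration),
      global = sd(y),
      blank = {
        b <- y[table$concentration == 0]
        if (length(b) < 2L)
          stop_ggp("blank noise undefined: need >= 2 blank measurements",
                   "ggpgmr_insufficient_data_error")
        sd(b)
      })
  }
  if (sensitivity <= 0)
    stop_ggp("sensitivity must be positive to define an LOD",
             "ggpgmr_validation_error")
  structure(list(noise = noise, sensitivity = sensitivity,
                 lod = noise / sensitivity * per, per = per,
                 noise_definition = noise_definition),
            class = "ggp_lod_result")
}

#' @export
print.ggp_lod_result <- function(x, ...) {
  cat(sprintf("LOD = noise / sensitivity = %.4g / %.4g (per %g units) = %.4g concentration units [%s SD]\n",
              x$noise, x$sensitivity, x$per, x$lod, x$noise_definition))
  invisible(x)
}

#' Cross-instrument agreement
#'
#' Pairs the two channels' normalized intensities by (run, concentration)
#' and regresses channel A on channel B; for two instruments measuring the
#' same quantity both the slope and R^2 approach 1.
#'
#' @param table_a,table_b [build_dose_response()] results for the two
#'   channels, sharing (run, concentration) keys.
#' @return List with `slope`, `intercept`, `r_squared`, `n_pairs`.
#' @export
compare_instruments <- function(table_a, table_b) {
  stopifnot(inherits(table_a, "ggp_dose_response"),
            inherits(table_b, "ggp_dose_response"))
  a <- as.data.frame(table_a); b <- as.data.frame(table_b)
  a$key <- paste(a$run, a$concentration, ave(a$run, a$run, a$concentration,
                                             FUN = seq_along))
  b$key <- paste(b$run, b$concentration, ave(b$run, b$run, b$concentration,
                                             FUN = seq_along))
  mm <- merge(a, b, by = "key", suffixes = c("_a", "_b"))
  if (nrow(mm) != nrow(a) || nrow(mm) != nrow(b))
    stop_ggp("tables do not share identical (run, concentration) keys",
             "ggpgmr_pairing_error")
  if (nrow(mm) < 3L)
    stop_ggp("need >= 3 pairs to compare instruments",
             "ggpgmr_insufficient_data_error")
  lmfit <- lm(normalized_intensity_a ~ normalized_intensity_b, data = mm)
  list(slope = unname(coef(lmfit)[2]), intercept = unname(coef(lmfit)[1]),
       r_squared = suppressWarnings(summary(lmfit)$r.squared), n_pairs = nrow(mm))
}

#' Correlation of MICP location with spectrometer peak wavelength
#'
#' OLS of MICP pixel against the spectrometer-measured peak wavelength over
#' a concentration series; a near-unity R^2 with slope equal to the local
#' calibration-curve slope (pixels per nm) confirms the spatial encoding.
#'
#' @param micp_pixel MICP positions (pixels).
#' @param peak_wavelength_nm Matched spectrometer peak wavelengths (nm).
#' @return List with `slope` (pixels/nm) and `r_squared`.
#' @export
correlate_micp_wavelength <- function(micp_pixel, peak_wavelength_nm) {
  if (length(micp_pixel) != length(peak_wavelength_nm) ||
      length(micp_pixel) < 3L)
    stop_ggp("need >= 3 matched (MICP, wavelength) points",
             "ggpgmr_insufficient_data_error")
  if (var(peak_wavelength_nm) == 0)
    stop_ggp("degenerate regression: all peak wavelengths identical",
             "ggpgmr_degenerate_error")
  lmfit <- lm(micp_pixel ~ peak_wavelength_nm)
  list(slope = unname(coef(lmfit)[2]),
       r_squared = suppressWarnings(summary(lmfit)$r.squared))
}
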