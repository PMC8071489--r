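#' Gradient-grating design parameters
#'
#' Geometry of the gradient-grating-period filter: the period ramps from
#' `period_start` to `period_end` in steps of `period_step`, each period
#' repeated `cycles_per_period` times, with ridge `duty_cycle`, ridge height
#' `grating_depth` and a conformal waveguiding coat of `coating_thickness`.
#' Defaults reproduce the stock device: 250--550 nm in 2-nm steps, 100
#' cycles, duty 0.5, 85-nm depth, 130-nm TiO2.
#'
#' @param period_start,period_end,period_step Grating periods, nm.
#' @param cycles_per_period Repeats of each period (integer >= 1).
#' @param duty_cycle Ridge fraction of a period, in (0, 1).
#' @param grating_depth Ridge height, nm.
#' @param coating_thickness Waveguiding coat thickness, nm.
#' @return An object of class `ggp_grating_design`.
#' @export
grating_design <- function(period_start = 250, period_end = 550,
                           period_step = 2, cycles_per_period = 100,
                           duty_cycle = 0.5, grating_depth = 85,
                           coating_thickness = 130) {
  assert_scalar_num(period_start, "period_start", lower = 0, strict_lower = TRUE)
  assert_scalar_num(period_end, "period_end", lower = period_start)
  assert_scalar_num(period_step, "period_step", lower = 0, strict_lower = TRUE)
  assert_scalar_num(cycles_per_period, "cycles_per_period", lower = 1)
  assert_scalar_num(duty_cycle, "duty_cycle", lower = 0, upper = 1,
                    strict_lower = TRUE)
  if (duty_cycle >= 1)
    stop_ggp("`duty_cycle` must lie strictly inside (0, 1)",
             "ggpgmr_validation_error")
  assert_scalar_num(grating_depth, "grating_depth", lower = 0, strict_lower = TRUE)
  assert_scalar_num(coating_thickness, "coating_thickness", lower = 0,
                    strict_lower = TRUE)
  structure(list(period_start = period_start, period_end = period_end,
                 period_step = period_step,
                 cycles_per_period = as.integer(cycles_per_period),
                 duty_cycle = duty_cycle, grating_depth = grating_depth,
                 coating_thickness = coating_thickness),
            class = "ggp_grating_design")
}

#' Effective refractive index of the guided mode
#'
#' Two models of the effective index entering the second-order Bragg
#' condition \eqn{\lambda_R = n_{eff}\Lambda}:
#'
#' * `"slab"` (default): the corrugated region is homogenized by zeroth-order
#'   effective-medium theory for TE polarization
#'   (\eqn{n_g^2 = f\,n_{ridge}^2 + (1-f)\,n_{groove}^2}, ridge = adhesive,
#'   groove = superstrate), collapsed with the flat coating into a single
#'   film by thickness-weighted squared index, and the fundamental TE mode
#'   of the resulting asymmetric slab (adhesive substrate, superstrate
#'   cover) is solved by root bracketing.
#' * `"weighted"`: a simple thickness-weighted mean of layer indices --- the
#'   coating, the duty-weighted corrugated layer, and fixed 50-nm evanescent
#'   tails into the adhesive and the superstrate.
#'
#' @param design A [grating_design()].
#' @param materials A [material_set()].
#' @param wavelength Wavelength in nm (scalar).
#' @param period Grating period in nm; enters only through the design's duty
#'   cycle under zeroth-order homogenization, kept for interface symmetry.
#' @param model `"slab"` or `"weighted"`.
#' @return Dimensionless effective index, between the larger of the
#'   substrate/superstrate indices and the coating index.
#' @export
effective_index <- function(design, materials, wavelength,
                            period = design$period_start,
                            model = c("slab", "weighted")) {
  model <- match.arg(model)
  stopifnot(inherits(design, "ggp_grating_design"),
            inherits(materials, "ggp_material_set"))
  n_coat <- material_index(materials$coating, wavelength)
  n_adh  <- material_index(materials$adhesive, wavelength)
  n_sup  <- material_index(materials$superstrate, wavelength)
  f <- design$duty_cycle
  tc <- design$coating_thickness
  dg <- design$grating_depth

  if (model == "weighted") {
    tail <- 50  # nm, nominal evanescent penetration either side
    return((tc * n_coat + dg * (f * n_adh + (1 - f) * n_sup) +
              tail * n_adh + tail * n_sup) / (tc + dg + 2 * tail))
  }

  # slab: EMT-homogenized corrugation + coating collapsed into one film
  ng2 <- f * n_adh^2 + (1 - f) * n_sup^2
  tfilm <- tc + dg
  nf2 <- (tc * n_coat^2 + dg * ng2) / tfilm
  nf <- sqrt(nf2)
  ns <- n_adh
  nc <- n_sup
  if (nf <= max(ns, nc))
    stop_ggp("no guided mode: homogenized film index does not exceed the claddings",
             "ggpgmr_no_mode_error")
  k0 <- 2 * pi / wavelength
  disp <- function(N) {
    kap <- sqrt(nf2 - N^2)
    k0 * tfilm * kap - atan(sqrt(N^2 - ns^2) / kap) -
      atan(sqrt(N^2 - nc^2) / kap)
  }
  lo <- max(ns, nc) + 1e-9
  hi <- nf - 1e-9
  if (disp(lo) < 0)
    stop_ggp(sprintf("no guided TE0 mode at %g nm (film too thin)", wavelength),
             "ggpgmr_no_mode_error")
  uniroot(disp, c(lo, hi), tol = 1e-12)$root
}

#' Resonant wavelength of one grating period
#'
#' Solves the second-order Bragg condition \eqn{\lambda_R = n_{eff}(\lambda_R)\Lambda}
#' as a fixed point by damped iteration started from the weighted-average
#' estimate; with a dispersive stack the contraction is mild and convergence
#' to a residual below `tol` takes a handful of iterations.
#'
#' @inheritParams effective_index
#' @param period Grating period \eqn{\Lambda}, nm.
#' @param tol Residual tolerance on \eqn{|\lambda - n_{eff}(\lambda)\Lambda|}, nm.
#' @return Resonant wavelength in nm.
#' @export
resonant_wavelength <- function(design, materials, period,
                                model = c("slab", "weighted"), tol = 1e-7) {
  model <- match.arg(model)
  rng <- range_intersection(materials)
  lam <- effective_index(design, materials,
                         wavelength = min(max(1.7 * period, rng[1]), rng[2]),
                         period = period, model = "weighted") * period
  for (i in seq_len(100)) {
    if (lam < rng[1] || lam > rng[2])
      stop_ggp(sprintf("Bragg fixed point escaped the supported range at period %g nm",
                       period), "ggpgmr_convergence_error")
    nxt <- effective_index(design, materials, wavelength = lam,
                           period = period, model = model) * period
    if (abs(nxt - lam) <= tol) return(nxt)
    lam <- 0.5 * lam + 0.5 * nxt
  }
  stop_ggp(sprintf("Bragg fixed point did not converge for period %g nm", period),
           "ggpgmr_convergence_error")
}

#' Build the gradient-grating device layout
#'
#' Enumerates the periods of the design, computes each period's Bragg
#' resonant wavelength, and lays the segments end to end starting from the
#' smallest period at position 0 (so position, period and resonant
#' wavelength all increase together). With `band` given, only segments whose
#' resonance falls inside `[band[1], band[2]]` are kept (positions are then
#' re-accumulated from 0 for the kept segments, which form a contiguous run
#' by monotonicity).
#'
#' @inheritParams effective_index
#' @param band Optional length-2 numeric: keep only resonances in this
#'   wavelength band (nm).
#' @return A `ggp_device_layout`: a data.frame with columns
#'   `segment_index`, `period_nm`, `start_nm`, `length_nm`,
#'   `resonant_wavelength_nm`, plus attributes `total_length_nm`, `design`,
#'   `materials`, `model`.
#' @examples
#' \donttest{
#' lay <- build_layout(grating_design(), default_materials(), band = c(500, 700))
#' attr(lay, "total_length_nm") / 1e6  # device length in mm
#' }
#' @export
build_layout <- function(design, materials, band = NULL,
                         model = c("slab", "weighted")) {
  model <- match.arg(model)
  if (!is.null(band)) {
    stopifnot(length(band) == 2L)
    if (band[1] >= band[2])
      stop_ggp("`band` must satisfy band[1] < band[2]", "ggpgmr_validation_error")
  }
  periods <- seq(design$period_start, design$period_end, by = design$period_step)
  lamR <- vapply(periods, function(p)
    resonant_wavelength(design, materials, p, model = model), 0)
  keep <- if (is.null(band)) rep(TRUE, length(periods))
          else lamR >= band[1] & lamR <= band[2]
  if (!any(keep))
    stop_ggp("empty layout: no period resonates inside the requested band",
             "ggpgmr_empty_layout_error")
  periods <- periods[keep]
  lamR <- lamR[keep]
  len <- design$cycles_per_period * periods
  start <- c(0, cumsum(len)[-length(len)])
  out <- data.frame(segment_index = seq_along(periods),
                    period_nm = periods,
                    start_nm = start,
                    length_nm = len,
                    resonant_wavelength_nm = lamR)
  structure(out,
            total_length_nm = sum(len),
            design = design, materials = materials, model = model,
            class = c("ggp_device_layout", "data.frame"))
}

#' @export
print.ggp_device_layout <- function(x, ...) {
  cat(sprintf("GGP-GMR layout: %d segments, periods %g-%g nm, resonances %.1f-%.1f nm, length %.3f mm\n",
              nrow(x), min(x$period_nm), max(x$period_nm),
              min(x$resonant_wavelength_nm), max(x$resonant_wavelength_nm),
              attr(x, "total_length_nm") / 1e6))
  invisible(x)
}

#' Write / read a device layout as CSV
#'
#' Plain CSV with header
#' `segment_index,period_nm,start_nm,length_nm,resonant_wavelength_nm`.
#'
#' @param layout A [build_layout()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_layout_csv <- function(layout, path) {
  stopifnot(inherits(layout, "ggp_device_layout"))
  write.csv(as.data.frame(layout), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
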