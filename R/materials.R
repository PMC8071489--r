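#' Refractive-index models
#'
#' A material is a dispersion model mapping vacuum wavelength (nm) to a
#' dimensionless refractive index. Two models are supported: a constant
#' index and a two-term Cauchy law \eqn{n(\lambda) = A + B/\lambda^2} with
#' \eqn{\lambda} in nm. Each material carries the wavelength range over
#' which its dispersion coefficients are trusted; evaluation outside that
#' range is an error rather than a silent extrapolation.
#'
#' @param model `"constant"` or `"cauchy"`.
#' @param n Constant index (for `model = "constant"`).
#' @param A,B Cauchy coefficients; `A` dimensionless, `B` in nm^2.
#' @param range Length-2 numeric, supported wavelength range in nm.
#' @return An object of class `ggp_material`.
#' @examples
#' material_index(material("constant", n = 1.54), 600)
#' material_index(material("cauchy", A = 2.24, B = 3e4), 550)
#' @export
material <- function(model = c("constant", "cauchy"), n = NULL,
                     A = NULL, B = NULL, range = c(350, 1100)) {
  model <- match.arg(model)
  stopifnot(length(range) == 2L, range[1] < range[2])
  if (model == "constant") {
    assert_scalar_num(n, "n", lower = 1)
    coefs <- list(n = n)
  } else {
    assert_scalar_num(A, "A", lower = 0)
    assert_scalar_num(B, "B")
    coefs <- list(A = A, B = B)
    if (A + B / max(range)^2 < 1 || A + B / min(range)^2 < 1)
      stop_ggp("Cauchy model drops below index 1 inside its supported range",
               "ggpgmr_validation_error")
  }
  structure(list(model = model, coefs = coefs, range = range),
            class = "ggp_material")
}

#' Evaluate a material's refractive index
#'
#' @param mat A [material()].
#' @param wavelength Wavelength(s) in nm, inside the material's supported
#'   range.
#' @return Numeric vector of indices (>= 1), same length as `wavelength`.
#' @export
material_index <- function(mat, wavelength) {
  stopifnot(inherits(mat, "ggp_material"))
  if (any(wavelength < mat$range[1] | wavelength > mat$range[2]))
    stop_ggp(sprintf("wavelength outside supported dispersion range [%g, %g] nm",
                     mat$range[1], mat$range[2]), "ggpgmr_range_error")
  switch(mat$model,
         constant = rep_len(mat$coefs$n, length(wavelength)),
         cauchy   = mat$coefs$A + mat$coefs$B / wavelength^2)
}

#' Material stack of the GGP-GMR device
#'
#' Bundles the four index models entering the effective-index calculation:
#' the PET substrate, the NOA 68 optical adhesive forming the replicated
#' grating ridges, the sputtered TiO2 waveguiding coat, and the superstrate
#' (air unless the sample wets the grating). The guiding condition requires
#' the coating index to exceed the adhesive index, which must exceed the
#' superstrate index.
#'
#' @param coating,adhesive,substrate,superstrate [material()] objects.
#' @return An object of class `ggp_material_set`.
#' @seealso [default_materials()] for the stock stack.
#' @export
material_set <- function(coating, adhesive, substrate, superstrate) {
  for (m in list(coating, adhesive, substrate, superstrate))
    stopifnot(inherits(m, "ggp_material"))
  ms <- structure(list(coating = coating, adhesive = adhesive,
                       substrate = substrate, superstrate = superstrate),
                  class = "ggp_material_set")
  # guiding condition probed mid-range
  probe <- mean(range_intersection(ms))
  nc <- material_index(coating, probe)
  na <- material_index(adhesive, probe)
  if (!(nc > na && na > 1))
    stop_ggp("guiding condition violated: need coating index > adhesive index > 1",
             "ggpgmr_validation_error")
  ms
}

range_intersection <- function(ms) {
  lo <- max(vapply(ms, function(m) m$range[1], 0))
  hi <- min(vapply(ms, function(m) m$range[2], 0))
  c(lo, hi)
}

#' Default material stack
#'
#' TiO2 as a two-term Cauchy fit typical of sputtered films
#' (n = 2.24 + 3.0e4/lambda^2, lambda in nm; n ~= 2.34 at 550 nm),
#' NOA 68 at 1.54, PET at 1.57 and air at 1.0.
#'
#' @return A [material_set()].
#' @export
default_materials <- function() {
  material_set(
    coating     = material("cauchy", A = 2.24, B = 3.0e4),
    adhesive    = material("constant", n = 1.54),
    substrate   = material("constant", n = 1.57),
    superstrate = material("constant", n = 1.00)
  )
}
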