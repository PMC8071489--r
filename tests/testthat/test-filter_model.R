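test_that("material dispersion models evaluate correctly and guard their range", {
  expect_equal(material_index(material("constant", n = 1.54), 600), 1.54)
  expect_equal(material_index(material("constant", n = 2.35), 500), 2.35)
  # Cauchy closed form as oracle
  A <- 2.24; B <- 3.0e4
  expect_equal(material_index(material("cauchy", A = A, B = B), 550),
               A + B / 550^2)
  expect_error(material_index(material("constant", n = 1.5), 2000),
               class = "ggpgmr_range_error")
})

test_that("grating design invariants are enforced", {
  expect_error(grating_design(duty_cycle = 1.5), class = "ggpgmr_validation_error")
  expect_error(grating_design(period_step = 0), class = "ggpgmr_validation_error")
  expect_error(grating_design(period_start = 500, period_end = 300),
               class = "ggpgmr_validation_error")
})

test_that("weighted-average neff degenerates to the common index for a uniform stack", {
  m <- material("constant", n = 1.8)
  ms <- structure(list(coating = m, adhesive = m, substrate = m,
                       superstrate = m), class = "ggp_material_set")
  expect_equal(effective_index(grating_design(), ms, 600, model = "weighted"),
               1.8)
})

test_that("slab-mode neff matches an independent dense-grid root bracket", {
  d <- grating_design(); m <- default_materials()
  for (lam in c(500, 600, 700)) {
    expect_equal(effective_index(d, m, lam, model = "slab"),
                 neff_slab_oracle(lam), tolerance = 1e-8)
  }
})

test_that("slab-mode neff stays inside the guided-mode bounds over 500-700 nm", {
  d <- grating_design(); m <- default_materials()
  for (lam in seq(500, 700, by = 20)) {
    neff <- effective_index(d, m, lam, model = "slab")
    expect_gt(neff, max(material_index(m$substrate, lam),
                        material_index(m$superstrate, lam)))
    expect_lt(neff, material_index(m$coating, lam))
  }
})

test_that("weighted-average and slab-mode neff agree within the 15% sanity envelope", {
  d <- grating_design(); m <- default_materials()
  for (lam in c(500, 600, 700)) {
    ns <- effective_index(d, m, lam, model = "slab")
    nw <- effective_index(d, m, lam, model = "weighted")
    expect_lt(abs(ns - nw) / ns, 0.15)
  }
})

test_that("Bragg resonance is exact for a dispersionless stack", {
  m2 <- material("constant", n = 2.0)
  ms <- structure(list(coating = m2, adhesive = m2, substrate = m2,
                       superstrate = m2), class = "ggp_material_set")
  d <- grating_design()
  expect_equal(resonant_wavelength(d, ms, 300, model = "weighted"), 600)
  expect_equal(resonant_wavelength(d, ms, 250, model = "weighted"), 500)
})

test_that("dispersive Bragg fixed point matches a dense wavelength scan", {
  d <- grating_design(); m <- default_materials()
  lamR <- resonant_wavelength(d, m, 300)
  # oracle: coarse sign-change bracket then 0.001-nm scan of lambda - neff*P
  g <- function(l) l - neff_slab_oracle(l) * 300
  coarse <- seq(450, 700, by = 0.5)
  v <- vapply(coarse, g, 0)
  i <- which(v[-1] * v[-length(v)] <= 0)[1]
  fine <- seq(coarse[i], coarse[i + 1], by = 0.001)
  vf <- vapply(fine, g, 0)
  j <- which(vf[-1] * vf[-length(vf)] <= 0)[1]
  expect_lt(abs(lamR - fine[j]), 0.002)
})

test_that("full layout reproduces the printed period count and arithmetic-series length", {
  lay <- full_layout()
  expect_equal(nrow(lay), 151)
  periods <- seq(250, 550, by = 2)
  expect_equal(attr(lay, "total_length_nm"), 100 * sum(periods))  # 6.04 mm
  expect_equal(attr(lay, "total_length_nm"), 6.04e6)
  # contiguous, ordered segments
  expect_equal(lay$start_nm, c(0, cumsum(lay$length_nm)[-nrow(lay)]))
  expect_equal(lay$length_nm, 100 * lay$period_nm)
})

test_that("resonant wavelength increases strictly with period across the full layout", {
  lay <- full_layout()
  expect_true(all(diff(lay$resonant_wavelength_nm) > 0))
  expect_gt(lay$resonant_wavelength_nm[151] - lay$resonant_wavelength_nm[1], 400)
})

test_that("every layout segment satisfies the Bragg residual bound", {
  lay <- default_system()$layout
  d <- attr(lay, "design"); m <- attr(lay, "materials")
  res <- vapply(seq_len(nrow(lay)), function(i) {
    neff <- effective_index(d, m, lay$resonant_wavelength_nm[i],
                            period = lay$period_nm[i], model = "slab")
    abs(lay$resonant_wavelength_nm[i] - neff * lay$period_nm[i])
  }, 0)
  expect_lt(max(res), 1e-6)
})

test_that("single-period and empty-band layouts behave as specified", {
  d1 <- grating_design(period_start = 400, period_end = 400)
  lay <- build_layout(d1, default_materials())
  expect_equal(nrow(lay), 1)
  expect_equal(lay$length_nm, 40000)
  expect_error(build_layout(grating_design(), default_materials(),
                            band = c(100, 200)),
               class = "ggpgmr_empty_layout_error")
})

test_that("layout CSV export round trips", {
  lay <- default_system()$layout
  f <- tempfile(fileext = ".csv")
  write_layout_csv(lay, f)
  back <- read.csv(f)
  expect_equal(names(back), c("segment_index", "period_nm", "start_nm",
                              "length_nm", "resonant_wavelength_nm"))
  expect_equal(back$period_nm, lay$period_nm)
})
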