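test_that("rhodamine-like preset reproduces the printed concentration peak shift", {
  pre <- assay_preset("tamra")
  grid <- default_wavelength_grid()
  sp_hi <- fluorescence_spectrum(pre$model, 1e-3, grid)
  expect_equal(grid[which.max(sp_hi$intensity)], 600)
  sp_lo <- fluorescence_spectrum(pre$model, 1e-6, grid)
  expect_equal(grid[which.max(sp_lo$intensity)], 566)
})

test_that("zero concentration yields a background-only emission spectrum", {
  pre <- assay_preset("hsa-fluorescent")
  sp <- fluorescence_spectrum(pre$model, 0)
  expect_true(all(sp$intensity == pre$model$background))
  expect_error(fluorescence_spectrum(pre$model, -1),
               class = "ggpgmr_validation_error")
})

test_that("Beer-Lambert transmission obeys the zero-absorber and doubling laws", {
  pre <- assay_preset("albumin-bcg")
  grid <- default_wavelength_grid()
  led <- transmitted_spectrum(pre$model, 0, grid)
  sigma <- pre$model$led_fwhm / (2 * sqrt(2 * log(2)))
  expect_equal(led$intensity,
               exp(-0.5 * ((grid - pre$model$led_center) / sigma)^2))
  t1 <- transmitted_spectrum(pre$model, 10, grid)$intensity / led$intensity
  t2 <- transmitted_spectrum(pre$model, 20, grid)$intensity / led$intensity
  expect_equal(t2, t1^2, tolerance = 1e-12)
  # transmittance ratio minimized at the absorbance peak (620 nm)
  expect_equal(grid[which.min(t1)], 620)
})

test_that("kinetic development is absent at k = 0 or t = 0 and monotone in concentration", {
  pre <- assay_preset("creatinine-jaffe")
  grid <- default_wavelength_grid()
  frozen <- kinetic_pair(pre$model, kinetic_model(rate_constant = 0), 300, grid)
  expect_equal(frozen$t0$intensity, frozen$t5$intensity)
  pair <- kinetic_pair(pre$model, pre$kinetics, 300, grid)
  expect_equal(pair$t0$intensity, transmitted_spectrum(pre$model, 0, grid)$intensity)
  # intensity drop at the LED-center bin strictly increasing over the
  # printed concentration series
  bin <- which(grid == pre$model$led_center)
  concs <- sort(c(500, 400, 300, 200, 150, 100, 50))
  drops <- vapply(concs, function(cc) {
    p <- kinetic_pair(pre$model, pre$kinetics, cc, grid)
    p$t0$intensity[bin] - p$t5$intensity[bin]
  }, 0)
  expect_true(all(diff(drops) > 0))
})

test_that("replicated dataset has the planned size and is seed-deterministic", {
  sys <- default_system()
  pre <- assay_preset("hsa-fluorescent", seed = 5)
  ns <- noise_params(read_noise_sd = 0.02, shot_noise_scale = 0.01)
  d1 <- generate_dataset(pre$plan, pre, sys$tm, noise = ns,
                         spectrometer_noise_sd = 0.003,
                         spectrometer_gain_jitter_sd = 0.01)
  expect_equal(nrow(d1$index), 24)  # (7 concentrations + blank) x 3 runs
  d2 <- generate_dataset(pre$plan, pre, sys$tm, noise = ns,
                         spectrometer_noise_sd = 0.003,
                         spectrometer_gain_jitter_sd = 0.01)
  expect_identical(serialize(d1, NULL), serialize(d2, NULL))
})

test_that("noiseless spectrometer channel equals the true spectrum and the seed ledger regenerates traces", {
  sys <- default_system()
  pre <- assay_preset("tamra", seed = 3)
  d0 <- generate_dataset(pre$plan, pre, sys$tm)
  truth <- fluorescence_spectrum(pre$model, d0$index$concentration[4],
                                 sys$tm$wavelengths)
  expect_equal(d0$spectra[[4]]$intensity, truth$intensity)
  # ledger completeness with instrument noise on
  dn <- generate_dataset(pre$plan, pre, sys$tm,
                         noise = noise_params(read_noise_sd = 0.02))
  for (id in c(1L, 8L, 15L))
    expect_identical(regenerate_trace(dn, id, sys$tm)$intensity,
                     dn$traces[[id]]$intensity)
})

test_that("ground truth is recoverable from a noiseless dataset", {
  sys <- default_system()
  # clean fluorophore: fixed peak on the grid, no background
  model <- fluorophore_model(base_peak = 610, reference_concentration = 200,
                             emission_fwhm = 35, amplitude_law = "linear",
                             background = 0, unit = "mg/L")
  assay <- structure(list(name = "clean", type = "fluorescent", model = model,
                          kinetics = NULL, unit = "mg/L"),
                     class = "ggp_assay")
  plan <- sample_plan(c(200, 100, 50, 25), include_blank = FALSE, n_runs = 1)
  ds <- generate_dataset(plan, assay, sys$tm)
  mm <- measure_dataset(ds, sys$curve)
  g <- mm[mm$channel == "ggp-gmr", ]
  s <- mm[mm$channel == "spectrometer", ]
  expect_lt(max(abs(g$wavelength_nm - 610)), 1)
  expect_equal(s$wavelength_nm, rep(610, 4))
  # amplitude ratios recovered exactly through both channels
  expect_equal(g$intensity / g$intensity[1], plan$concentrations / 200,
               tolerance = 1e-12)
  expect_equal(s$intensity / s$intensity[1], plan$concentrations / 200,
               tolerance = 1e-12)
})

test_that("sampling plan validates its arguments", {
  expect_error(sample_plan(c(10, 10)), class = "ggpgmr_validation_error")
  expect_error(sample_plan(c(-1, 5)), class = "ggpgmr_validation_error")
  p <- sample_plan(c(5, 50, 10), include_blank = TRUE)
  expect_equal(p$concentrations, c(50, 10, 5, 0))
})
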