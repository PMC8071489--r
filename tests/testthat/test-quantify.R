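test_that("peak measurements agree across channels on a noiseless dye series", {
  sys <- default_system()
  pre <- assay_preset("tamra")
  sp <- fluorescence_spectrum(pre$model, 1e-3, sys$tm$wavelengths)
  tr <- forward_readout(sys$tm, sp)
  mg <- extract_measurement(tr, sys$curve)
  expect_lt(abs(mg$estimated_wavelength_nm - 600), 1)
  ms <- extract_measurement(sp)
  expect_equal(ms$peak_wavelength_nm, 600)
  # global intensity scaling moves intensity, not the MICP
  tr2 <- ccd_trace(tr$pixel, 5 * tr$intensity)
  mg2 <- extract_measurement(tr2, sys$curve)
  expect_equal(mg2$micp_pixel, mg$micp_pixel)
  expect_equal(mg2$subpixel, mg$subpixel, tolerance = 1e-9)
  expect_equal(mg2$intensity, 5 * mg$intensity, tolerance = 1e-12)
})

test_that("dose-response normalization divides by the per-run reference", {
  m <- data.frame(run = 1, concentration = c(10, 50, 100),
                  intensity = c(2, 4, 8))
  tab <- build_dose_response(m)
  expect_equal(tab$normalized_intensity, c(0.25, 0.5, 1.0))

  m3 <- expand.grid(run = 1:3, concentration = c(200, 150, 100, 50, 25, 12.5,
                                                 6.25, 0))
  m3$intensity <- m3$concentration + 10 * m3$run
  tab3 <- build_dose_response(m3)
  expect_equal(nrow(tab3), 24)
  expect_true(all(tab3$normalized_intensity[tab3$concentration == 200] == 1))
})

test_that("kinetic dose response with no reaction is a table of zeros", {
  m <- expand.grid(run = 1:2, concentration = c(50, 100, 500),
                   timepoint = c("t0", "t5"))
  m$intensity <- 3  # k = 0: identical at both read times
  tab <- build_dose_response(m, kinetic = TRUE)
  expect_true(all(tab$raw_intensity == 0))
  expect_true(all(tab$normalized_intensity == 0))
})

test_that("missing reference concentration is a normalization error", {
  m <- data.frame(run = c(1, 1, 2, 2), concentration = c(100, 50, 100, 50),
                  intensity = c(NA, 1, 2, 1))
  expect_error(build_dose_response(m), class = "ggpgmr_normalization_error")
})

test_that("dose-response regression recovers exact lines and flags degeneracy", {
  concs <- c(200, 150, 100, 50, 25, 12.5, 6.25)
  y <- 0.037 * concs / 10 + 0.05
  tab <- build_dose_response(data.frame(run = 1, concentration = concs,
                                        intensity = y),
                             normalization = "none")
  fit <- fit_dose_response(tab)
  expect_equal(fit$slope, 0.037, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(unname(coef(fit)["slope"]), fit$slope)
  expect_equal(predict(fit, 100), 0.037 * 10 + 0.05, tolerance = 1e-12)

  flat <- build_dose_response(data.frame(run = 1, concentration = concs,
                                         intensity = rep(2, 7)),
                              normalization = "none")
  ffit <- fit_dose_response(flat)
  expect_true(ffit$degenerate)
  expect_equal(ffit$slope, 0)
  expect_equal(ffit$r_squared, 0)

  expect_error(fit_dose_response(build_dose_response(
    data.frame(run = 1, concentration = c(1, 2), intensity = c(1, 2)),
    normalization = "none")), class = "ggpgmr_insufficient_data_error")
})

test_that("all regressions match the closed-form two-pass OLS oracle", {
  set.seed(31)
  for (k in 1:5) {
    x <- runif(8, 0, 50)
    y <- 0.3 * x + rnorm(8)
    tab <- build_dose_response(data.frame(run = 1, concentration = x,
                                          intensity = y),
                               normalization = "none")
    fit <- fit_dose_response(tab, per = 1)
    orc <- ols_oracle(x, y)
    expect_equal(fit$slope, orc$slope, tolerance = 1e-10)
    expect_equal(fit$intercept, orc$intercept, tolerance = 1e-10)
    expect_equal(fit$r_squared, orc$r_squared, tolerance = 1e-10)
  }
})

test_that("LOD arithmetic follows noise / sensitivity with the per-10 convention", {
  expect_equal(estimate_lod(noise = 0, sensitivity = 0.04)$lod, 0)
  r <- estimate_lod(noise = 0.3, sensitivity = 0.05)
  expect_equal(r$lod, 0.3 / 0.05 * 10)
  expect_error(estimate_lod(noise = 0.1, sensitivity = 0),
               class = "ggpgmr_validation_error")
})

test_that("pooled noise requires replication and respects the selected population", {
  concs <- c(100, 50, 25)
  single <- build_dose_response(data.frame(run = 1, concentration = concs,
                                           intensity = concs),
                                normalization = "none")
  sfit <- fit_dose_response(single, per = 1)
  expect_error(estimate_lod(single, sfit),
               class = "ggpgmr_insufficient_data_error")

  set.seed(4)
  m <- expand.grid(run = 1:3, concentration = concs)
  m$intensity <- m$concentration + rnorm(9, sd = 2)
  tab <- build_dose_response(m, normalization = "none")
  fit <- fit_dose_response(tab, per = 1)
  lod <- estimate_lod(tab, fit)
  # oracle: pooled within-concentration SD
  sds <- tapply(tab$normalized_intensity, tab$concentration, var)
  pooled <- sqrt(sum(2 * sds) / 6)
  expect_equal(lod$noise, 3 * pooled, tolerance = 1e-12)
  expect_equal(lod$lod, lod$noise / fit$slope, tolerance = 1e-12)
  g <- estimate_lod(tab, fit, noise_definition = "global")
  expect_equal(g$noise, 3 * sd(tab$normalized_intensity), tolerance = 1e-12)
})

test_that("instrument comparison detects identity and scale", {
  m <- expand.grid(run = 1:3, concentration = c(100, 50, 25, 10))
  m$intensity <- m$concentration * 0.01
  ta <- build_dose_response(m)
  expect_equal(compare_instruments(ta, ta)$slope, 1, tolerance = 1e-12)
  expect_equal(compare_instruments(ta, ta)$r_squared, 1, tolerance = 1e-12)
  tb <- ta
  tb$normalized_intensity <- tb$normalized_intensity / 2
  cmp <- compare_instruments(ta, tb)
  expect_equal(cmp$slope, 2, tolerance = 1e-12)
  # key mismatch
  tc <- build_dose_response(data.frame(run = 1, concentration = c(9, 5, 2),
                                       intensity = 1:3))
  expect_error(compare_instruments(ta, tc), class = "ggpgmr_pairing_error")
})

test_that("MICP/peak-wavelength correlation matches the local calibration slope", {
  sys <- default_system()
  pre <- assay_preset("tamra")
  ds <- generate_dataset(pre$plan, pre, sys$tm)
  mm <- measure_dataset(ds, sys$curve)
  g <- mm[mm$channel == "ggp-gmr" & mm$run == 1, ]
  s <- mm[mm$channel == "spectrometer" & mm$run == 1, ]
  cc <- correlate_micp_wavelength(g$micp_pixel, s$wavelength_nm)
  expect_gte(cc$r_squared, 0.99)
  local_slope <- (wavelength_to_pixel(sys$curve, 600) -
                    wavelength_to_pixel(sys$curve, 566)) / (600 - 566)
  expect_lt(abs(cc$slope - local_slope) / local_slope, 0.1)
  expect_error(correlate_micp_wavelength(c(1, 2, 3), c(5, 5, 5)),
               class = "ggpgmr_degenerate_error")
})
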