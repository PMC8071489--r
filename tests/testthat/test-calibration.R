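test_that("monochromatic spectrum has the stated peak, FWHM and integral", {
  grid <- default_wavelength_grid()
  sp <- monochromatic_spectrum(600, linewidth = 2.5, amplitude = 1, grid = grid)
  expect_equal(grid[which.max(sp$intensity)], 600)
  # FWHM definition: exactly half maximum at center +/- linewidth/2
  fine <- seq(590, 610, by = 0.25)
  spf <- monochromatic_spectrum(600, linewidth = 2.5, amplitude = 1, grid = fine)
  half <- spf$intensity[fine %in% c(598.75, 601.25)]
  expect_equal(half, c(0.5, 0.5))
  # quadrature oracle for the Gaussian integral (1-nm Riemann sum)
  sigma <- 2.5 / (2 * sqrt(2 * log(2)))
  anal <- integrate(function(l) exp(-0.5 * ((l - 600) / sigma)^2),
                    500, 699)$value
  expect_equal(sum(sp$intensity) * 1, anal, tolerance = 1e-9)
  expect_error(monochromatic_spectrum(400, grid = grid),
               class = "ggpgmr_range_error")
})

test_that("find_micp locates single minima and rejects flat traces", {
  y <- rep(1, 201); y[101] <- 0.1
  tr <- ccd_trace(2000:2200, y)
  fm <- find_micp(tr)
  expect_equal(fm$micp, 2100L)
  expect_false(fm$tie)
  expect_error(find_micp(ccd_trace(2000:2200, rep(1, 201))),
               class = "ggpgmr_no_dip_error")
  expect_error(find_micp(ccd_trace(2000:2200, rep(0, 201))),
               class = "ggpgmr_no_dip_error")
})

test_that("MICP is robust to seeded read noise at the 1% level", {
  sys <- default_system()
  sp <- monochromatic_spectrum(600, grid = sys$tm$wavelengths)
  clean <- forward_readout(sys$tm, sp)
  m0 <- find_micp(clean)$micp
  baseline <- median(clean$intensity)
  hits <- sum(vapply(1:20, function(s) {
    ns <- noise_params(read_noise_sd = 0.01 * baseline, seed = s)
    abs(find_micp(forward_readout(sys$tm, sp, ns))$micp - m0) <= 1
  }, TRUE))
  expect_gte(hits, 19)
})

test_that("calibration curve spans the printed pixel range and is monotone", {
  cur <- default_system()$curve
  expect_lte(abs(cur$micp_pixel[1] - 2073), 3)
  expect_lte(abs(cur$micp_pixel[nrow(cur)] - 2360.5), 3)
  expect_true(all(diff(cur$micp_pixel) >= 0))
})

test_that("forward/inverse lookups are self-consistent and guard their range", {
  cur <- default_system()$curve
  # knot identity
  k <- 50
  expect_equal(micp_to_wavelength(cur, cur$micp_pixel[k]), cur$wavelength_nm[k])
  # midpoint between adjacent knots maps to the mean wavelength
  mid <- (cur$micp_pixel[100] + cur$micp_pixel[101]) / 2
  expect_equal(micp_to_wavelength(cur, mid),
               (cur$wavelength_nm[100] + cur$wavelength_nm[101]) / 2)
  # round trip over 50 random interior wavelengths
  set.seed(7)
  w <- runif(50, 510, 690)
  back <- micp_to_wavelength(cur, wavelength_to_pixel(cur, w))
  expect_lt(max(abs(back - w)), 0.5)
  expect_error(micp_to_wavelength(cur, 1000), class = "ggpgmr_extrapolation_error")
  expect_error(wavelength_to_pixel(cur, 499), class = "ggpgmr_extrapolation_error")
})

test_that("MICP location is invariant to uniform source intensity scaling", {
  sys <- default_system()
  for (w in c(520, 610, 690)) {
    f1 <- find_micp(forward_readout(sys$tm, monochromatic_spectrum(w, amplitude = 1, grid = sys$tm$wavelengths)))
    f2 <- find_micp(forward_readout(sys$tm, monochromatic_spectrum(w, amplitude = 250, grid = sys$tm$wavelengths)))
    expect_equal(f1$subpixel, f2$subpixel, tolerance = 1e-9)
  }
})

test_that("noiseless end-to-end wavelength recovery is within 1 nm", {
  sys <- default_system()
  errs <- vapply(seq(505, 695, by = 2), function(w) {
    tr <- forward_readout(sys$tm, monochromatic_spectrum(w, grid = sys$tm$wavelengths))
    abs(micp_to_wavelength(sys$curve, find_micp(tr)$subpixel) - w)
  }, 0)
  expect_lt(max(errs), 1)
})

test_that("calibration CSV round trips and validates its schema", {
  cur <- default_system()$curve
  f <- tempfile(fileext = ".csv")
  write_calibration_csv(cur, f)
  back <- read_calibration_csv(f)
  expect_equal(back$wavelength_nm, cur$wavelength_nm)
  expect_equal(back$micp_pixel, cur$micp_pixel, tolerance = 1e-12)
  bad <- tempfile(fileext = ".csv")
  writeLines(c("wl,micp_pixel", "500,2073"), bad)
  expect_error(read_calibration_csv(bad), class = "ggpgmr_format_error")
})
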