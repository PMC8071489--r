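# shared fixtures, built once per test run

.fixture_cache <- new.env(parent = emptyenv())

default_system <- function() {
  if (is.null(.fixture_cache$sys)) {
    layout <- build_layout(grating_design(), default_materials(),
                           band = c(500, 700))
    ccd <- anchor_ccd(layout)
    lineshape <- resonance_lineshape()
    tm <- build_transmission_matrix(layout, ccd, lineshape)
    curve <- build_calibration_curve(tm)
    .fixture_cache$sys <- list(layout = layout, ccd = ccd,
                               lineshape = lineshape, tm = tm, curve = curve)
  }
  .fixture_cache$sys
}

full_layout <- function() {
  if (is.null(.fixture_cache$full))
    .fixture_cache$full <- build_layout(grating_design(), default_materials())
  .fixture_cache$full
}

# closed-form two-pass OLS, independent of lm()
ols_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  sxy <- sum((x - mx) * (y - my))
  syy <- sum((y - my)^2)
  slope <- sxy / sxx
  list(slope = slope, intercept = my - slope * mx,
       r_squared = sxy^2 / (sxx * syy))
}

# independent slab-mode oracle: homogenize the stack the same way but find
# the TE0 root by dense-grid sign change + bisection instead of uniroot
neff_slab_oracle <- function(lambda, duty = 0.5, depth = 85, tcoat = 130,
                             n_coat = NULL, n_adh = 1.54, n_sup = 1.0) {
  if (is.null(n_coat)) n_coat <- 2.24 + 3.0e4 / lambda^2
  ng2 <- duty * n_adh^2 + (1 - duty) * n_sup^2
  tf <- tcoat + depth
  nf2 <- (tcoat * n_coat^2 + depth * ng2) / tf
  k0 <- 2 * pi / lambda
  f <- function(N) {
    kap <- sqrt(nf2 - N^2)
    k0 * tf * kap - atan(sqrt(N^2 - n_adh^2) / kap) -
      atan(sqrt(N^2 - n_sup^2) / kap)
  }
  grid <- seq(n_adh + 1e-6, sqrt(nf2) - 1e-6, length.out = 4000)
  v <- vapply(grid, f, 0)
  i <- which(v[-1] * v[-length(v)] <= 0)[1]
  lo <- grid[i]; hi <- grid[i + 1]
  for (k in 1:60) {
    mid <- (lo + hi) / 2
    if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
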