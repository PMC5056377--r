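test_that("the subtraction factor is the least-squares projection", {
  grid <- seq(2100, 1500, by = -2)
  ref <- ir_spectrum(grid, band_profile(grid, 1800, 20, "lorentzian", 0))
  window <- c(1900, 1700)
  idx_out <- grid < 1700 # base lives outside the fit window, flat (zero) on it
  base <- ifelse(idx_out, 0.05, 0)
  s <- ir_spectrum(grid, base + 0.3 * ref$absorbance)

  fr <- fractional_subtract(s, ref, window)
  expect_equal(fr$factor, 0.3, tolerance = 1e-9)
  expect_equal(fr$corrected$absorbance, base, tolerance = 1e-9)
  expect_lt(fr$residual_rms, 1e-12)

  # orthogonal sample: factor 0, nothing subtracted
  orth <- ir_spectrum(grid, ifelse(idx_out, 0.2, 0))
  fr0 <- fractional_subtract(orth, ref, window)
  expect_equal(fr0$factor, 0)
  expect_equal(fr0$corrected$absorbance, orth$absorbance)

  # brute-force 1-D grid-search oracle for the same objective
  with_seed_test(3, {
    y <- 0.42 * ref$absorbance + rnorm(length(grid), 0, 0.01)
    s2 <- ir_spectrum(grid, y)
  })
  fr2 <- fractional_subtract(s2, ref, window)
  idx <- which(grid <= 1900 & grid >= 1700)
  fgrid <- seq(0, 1, by = 1e-5)
  sse <- vapply(fgrid, function(f)
    sum((s2$absorbance[idx] - f * ref$absorbance[idx])^2), numeric(1))
  expect_equal(fr2$factor, fgrid[which.min(sse)], tolerance = 1e-5)

  # with a flat pedestal on the window, the detrended fit still returns the
  # construction factor exactly
  s3 <- ir_spectrum(grid, 0.07 + 0.3 * ref$absorbance)
  fr3 <- fractional_subtract(s3, ref, window, detrend_order = 0)
  expect_equal(fr3$factor, 0.3, tolerance = 1e-9)

  expect_error(fractional_subtract(orth, ir_spectrum(grid, rep(0, length(grid))),
                                   window), "zero norm")
  expect_error(fractional_subtract(s, ref, c(990, 900)), "coverage")
})

test_that("Savitzky-Golay second derivative annihilates affine signals and reproduces quadratics", {
  grid <- seq(2000, 1000, by = -2)
  n <- length(grid)

  const <- second_derivative(ir_spectrum(grid, rep(0.7, n)))
  expect_true(all(abs(const$d2) < 1e-12))

  affine <- second_derivative(ir_spectrum(grid, 0.3 + 0.001 * seq_len(n)))
  expect_true(all(abs(affine$d2) < 1e-10))

  quad <- second_derivative(ir_spectrum(grid, as.numeric(seq_len(n))^2))
  expect_equal(quad$d2, rep(2, n), tolerance = 1e-6)

  # linearity to near machine precision
  with_seed_test(5, {
    y1 <- rnorm(n); y2 <- rnorm(n)
  })
  d_sum <- second_derivative(ir_spectrum(grid, 2 * y1 - 3 * y2))$d2
  d_parts <- 2 * second_derivative(ir_spectrum(grid, y1))$d2 -
    3 * second_derivative(ir_spectrum(grid, y2))$d2
  expect_equal(d_sum, d_parts, tolerance = 1e-10)

  expect_error(second_derivative(ir_spectrum(grid, y1), window_points = 8),
               "odd")
  expect_error(second_derivative(ir_spectrum(grid, y1), polyorder = 1),
               "polyorder")
  expect_error(second_derivative(ir_spectrum(grid[1:5], y1[1:5]),
                                 window_points = 9), "shorter")
})

test_that("the second-derivative minimum sits at the band centre", {
  # oracle: analytic second derivative of a Gaussian band has its minimum
  # exactly at the centre; the filtered derivative must agree to +/-1 point
  grid <- fixture_grid
  s <- ir_spectrum(grid, band_profile(grid, 1296, 14, "gaussian", 0))
  d <- second_derivative(s)
  expect_lte(abs(grid[which.min(d$d2)] - 1296), 2) # one 2 cm-1 grid step
  # analytic check on a fine grid: d2/dx2 exp(-a x^2) minimal at x = 0
  a <- 4 * log(2) / 14^2
  x <- seq(-30, 30, by = 0.01)
  expect_equal(x[which.min((4 * a^2 * x^2 - 2 * a) * exp(-a * x^2))], 0,
               tolerance = 0.02)
})

test_that("band response follows its sign conventions and linearity", {
  grid <- fixture_grid
  zero <- second_derivative(ir_spectrum(grid, rep(0, length(grid))))
  expect_equal(band_response(zero), 0)

  one <- generate_sample(sample_spec(c(cystine = 1), noise_sd = 0),
                         fixture_lib, grid)
  two <- generate_sample(sample_spec(c(cystine = 2), noise_sd = 0),
                         fixture_lib, grid)
  r1 <- cystine_response(one); r2 <- cystine_response(two)
  expect_equal(r2, 2 * r1, tolerance = 1e-9)
  expect_gt(r1, 0) # inverted response grows with concentration
  expect_equal(band_response(second_derivative(one)), -r1)

  # invariant to any affine baseline across the filter window
  tilted <- ir_spectrum(grid, one$absorbance + 0.5 - 1e-4 * grid)
  expect_equal(cystine_response(tilted), r1, tolerance = 1e-9)

  short <- ir_spectrum(seq(1200, 1100, by = -2), rep(0, 51))
  expect_error(band_response(second_derivative(short)), "not on the grid")
})

test_that("joint water/vapour removal recovers both generator factors", {
  refs <- fixture_refs()
  s <- generate_sample(sample_spec(c(urea = 150, creatinine = 8),
                                   baseline_coeffs = c(0.01, -0.015),
                                   water_factor = 0.9, vapour_factor = 0.25,
                                   noise_sd = 0), fixture_lib, fixture_grid)
  sw <- subtract_water(s, refs)
  expect_equal(sw$water_factor, 0.9, tolerance = 1e-3)
  # the urea/creatinine band tails reach into the vapour window, so the
  # comb factor carries a few percent of interference at high urea
  expect_equal(sw$vapour_factor, 0.25, tolerance = 0.05)
})
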