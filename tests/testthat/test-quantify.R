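test_that("through-origin calibration reproduces exact lines", {
  m <- fit_calibration(c(1, 2, 3), c(2, 4, 6))
  expect_equal(m$slope, 2)
  expect_equal(m$r_squared, 1)
  expect_equal(m$residual_sd, 0)
  expect_equal(m$concentration_range, c(1, 3))

  m2 <- fit_calibration(0:3, 0:3)
  expect_equal(m2$slope, 1)

  expect_error(fit_calibration(c(0, 0, 0), c(1, 2, 3)), "degenerate")
  expect_error(fit_calibration(1, 2), "at least 2")
  expect_warning(fit_calibration(c(1, 2, 3), c(-1, -2, -3)), "not positive")
})

test_that("through-origin slope matches lm and a 1-D minimisation oracle", {
  with_seed_test(13, {
    conc <- rep(seq(0, 3, by = 0.5), each = 2)
    resp <- 0.0037 * conc + rnorm(length(conc), 0, 2e-4)
  })
  m <- fit_calibration(conc, resp)
  # independent route 1: R's no-intercept least squares
  expect_equal(m$slope, unname(coef(lm(resp ~ 0 + conc))), tolerance = 1e-12)
  # independent route 2: dense slope-grid minimisation of the objective
  ks <- seq(0.003, 0.0045, by = 1e-8)
  sse <- vapply(ks, function(k) sum((resp - k * conc)^2), numeric(1))
  expect_equal(m$slope, ks[which.min(sse)], tolerance = 1e-6)
})

test_that("prediction inverts the calibration, clips at zero and flags extrapolation", {
  m <- fit_calibration(c(0, 1, 2, 3), c(0, 0.004, 0.008, 0.012))
  expect_equal(as.numeric(predict_concentration(m, m$slope * 1.5)), 1.5)
  p <- predict_concentration(m, c(-0.001, 0.004, 0.020))
  expect_equal(as.numeric(p), c(0, 1, 5))
  expect_equal(attr(p, "extrapolated"), c(FALSE, FALSE, TRUE))

  bad <- suppressWarnings(fit_calibration(c(1, 2), c(-1, -2)))
  expect_error(predict_concentration(bad, 0.1), "slope must be positive")
})

test_that("predict after fit is the identity on noiseless linear data", {
  for (slope in c(1e-4, 0.37, 12)) {
    conc <- seq(0, 3, by = 0.5)
    m <- fit_calibration(conc, slope * conc)
    expect_equal(as.numeric(predict_concentration(m, slope * conc)), conc,
                 tolerance = 1e-12)
  }
})

test_that("closed-loop calibration recovers the simulator slope", {
  conc <- seq(0, 3, by = 0.5)
  truth_slope <- cystine_response(
    render_component(fixture_lib$cystine, fixture_grid, 1))

  # zero noise: exact
  s0 <- generate_calibration_series(conc, noise_sd = 0)
  m0 <- fit_calibration(conc, vapply(s0, function(m)
    cystine_response(m$spectrum), numeric(1)))
  expect_equal(m0$slope, truth_slope, tolerance = 1e-6)

  # default noise: within 2%
  s1 <- generate_calibration_series(conc, noise_sd = 2e-4, seed = 17)
  m1 <- fit_calibration(conc, vapply(s1, function(m)
    cystine_response(m$spectrum), numeric(1)))
  expect_equal(m1$slope, truth_slope, tolerance = 0.02)
  expect_gt(m1$r_squared, 0.99)
})

test_that("volume bookkeeping rescales concentrations correctly", {
  expect_equal(apply_dilution(2.0, 1, 1), 2.0)
  expect_equal(apply_dilution(2.0, 1, 0.5), 1.0)
  expect_equal(apply_dilution(0, 3, 0.2), 0)
  expect_error(apply_dilution(1, 0, 1), "positive")
  expect_error(apply_dilution(1, 1, -1), "positive")
})

test_that("sample reports apply the SEM, offset, censoring and ratio conventions", {
  q <- report_sample("P01", c(2.0, 2.1, 2.2), creatinine_mM = 10,
                     detection_threshold = 0.05)
  expect_equal(q$insoluble_cystine_mM, 2.1)
  expect_equal(q$sem_mM, sd(c(2.0, 2.1, 2.2)) / sqrt(3))
  expect_equal(q$sem_mM, 0.0577, tolerance = 1e-3)
  expect_true(q$detected)
  expect_equal(q$total_cystine_mM, 3.1)
  expect_equal(q$ratio_uM_per_mM, 210)

  # undetected: censored interval, insoluble reported as zero
  q0 <- report_sample("C01", c(0, 0, 0), creatinine_mM = 5,
                      detection_threshold = 0.05)
  expect_false(q0$detected)
  expect_equal(q0$insoluble_cystine_mM, 0)
  expect_equal(q0$total_cystine_mM, c(centre = 0.5, halfwidth = 0.5))

  # creatinine <= 0: ratio undefined, not an error
  qna <- report_sample("P02", c(1, 1.1), creatinine_mM = 0,
                       detection_threshold = 0.05)
  expect_true(is.na(qna$ratio_uM_per_mM))

  expect_error(report_sample("x", numeric(0)), "replicate")

  tab <- quant_table(list(q, q0))
  expect_equal(nrow(tab), 2)
  expect_equal(tab$total_mM, c(3.1, 0.5))
  expect_equal(tab$total_halfwidth_mM, c(0, 0.5))
})

test_that("parameter recovery across the working range with a 3-sigma LOD", {
  # 200 simulated insoluble fractions spanning 0-3.1 mM at default noise,
  # quantitated against a default-noise calibration
  conc_series <- seq(0, 3, by = 0.5)
  series <- generate_calibration_series(conc_series, noise_sd = 2e-4,
                                        seed = 41)
  cal <- fit_calibration(conc_series, vapply(series, function(m)
    cystine_response(m$spectrum), numeric(1)))
  lod <- detection_limit(cal)
  expect_gt(lod, 0)
  expect_lt(lod, 0.5)

  n <- 200
  truth <- seq(0, 3.1, length.out = n)
  est <- vapply(seq_len(n), function(i) {
    s <- generate_sample(sample_spec(c(cystine = truth[i]), noise_sd = 2e-4,
                                     seed = 1000 + i),
                         fixture_lib, fixture_grid)
    as.numeric(predict_concentration(cal, cystine_response(s)))
  }, numeric(1))
  expect_lte(median(abs(est - truth)), 0.1)

  # zero-cystine samples never cross the 3-sigma threshold
  blanks <- vapply(1:25, function(i) {
    s <- generate_sample(sample_spec(c(cystine = 0), noise_sd = 2e-4,
                                     seed = 5000 + i),
                         fixture_lib, fixture_grid)
    as.numeric(predict_concentration(cal, cystine_response(s)))
  }, numeric(1))
  expect_equal(sum(blanks > lod), 0)
})

test_that("spot capacity reproduces the worked example and scales physically", {
  cap <- spot_capacity(193e-30, 1e-6, 3e-3)
  expect_equal(cap, 60.8, tolerance = 0.002)
  # independent hand computation of the cylinder volume route
  vol <- pi * (1.5e-3)^2 * 1e-6
  expect_equal(cap, vol / 193e-30 / 6.02214076e23 * 1e9, tolerance = 1e-12)
  # ...and the aliquot equivalence: 5 uL of 12 mM is 60 nmol
  expect_equal(5e-6 * 12e-3 * 1e9, 60)
  expect_equal(cap, 60, tolerance = 0.015)

  expect_equal(spot_capacity(film_height = 2e-6), 2 * cap)
  # invariant under a consistent change of length unit (metres -> microns)
  expect_equal(spot_capacity(193e-12, 1, 3e3), cap, tolerance = 1e-12)
  expect_error(spot_capacity(-1, 1, 1), "positive")
})
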