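test_that("spectra are validated and stored on a descending grid", {
  s <- ir_spectrum(c(1300, 1298, 1296), c(0.1, 0.2, 0.3))
  expect_s3_class(s, "ir_spectrum")
  expect_equal(s$wavenumbers, c(1300, 1298, 1296))

  # ascending input is reversed to the same object, with a metadata note
  s2 <- ir_spectrum(c(1296, 1298, 1300), c(0.3, 0.2, 0.1))
  expect_equal(s2$wavenumbers, s$wavenumbers)
  expect_equal(s2$absorbance, s$absorbance)
  expect_true(isTRUE(s2$meta$reversed_on_input))

  expect_error(ir_spectrum(c(1300, 1300, 1296), c(1, 2, 3)), "monotonic")
  expect_error(ir_spectrum(c(1300, 1296, 1298), c(1, 2, 3)), "monotonic")
  expect_error(ir_spectrum(1300, 0.1), "at least 2")
  expect_error(ir_spectrum(c(1300, 1298), c(NA, 1)), "absorbance")
  expect_error(ir_spectrum(c(1300, 1298), c(Inf, 1)), "absorbance")
})

test_that("csv round trip preserves data and metadata", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1300,0.1", "1298,0.2", "1296,0.3"), path)
  s <- read_spectrum(path)
  expect_equal(s$wavenumbers, c(1300, 1298, 1296))
  expect_equal(s$absorbance, c(0.1, 0.2, 0.3))

  # ascending file gives the identical spectrum
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavenumber_cm-1,absorbance",
               "1296,0.3", "1298,0.2", "1300,0.1"), path2)
  s2 <- read_spectrum(path2)
  expect_equal(s2$wavenumbers, s$wavenumbers)
  expect_equal(s2$absorbance, s$absorbance)

  # duplicated wavenumber row fails validation
  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1300,0.1", "1300,0.2", "1296,0.3"), path3)
  expect_error(read_spectrum(path3), "monotonic")

  # full-precision round trip with metadata comments
  orig <- fixture_small_spectrum()
  out <- withr::local_tempfile(fileext = ".csv")
  write_spectrum(orig, out, "csv")
  expect_true(any(grepl("^# sample_id: fix", readLines(out))))
  back <- read_spectrum(out)
  expect_equal(back$wavenumbers, orig$wavenumbers, tolerance = 1e-12)
  expect_equal(back$absorbance, orig$absorbance, tolerance = 1e-12)
  expect_equal(back$meta$sample_id, "fix")
})

test_that("unparseable csv content is reported with its line", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1300,0.1", "oops,zap", "1296,0.3"), path)
  expect_error(read_spectrum(path), "line 2")
  expect_error(read_spectrum(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("jcamp AFFN round trip is the identity to tolerance", {
  orig <- fixture_small_spectrum(n = 37)
  path <- withr::local_tempfile(fileext = ".jdx")
  write_spectrum(orig, path, "jcamp")
  back <- read_spectrum(path) # format dispatch from extension
  expect_equal(back$wavenumbers, orig$wavenumbers, tolerance = 1e-9)
  expect_equal(back$absorbance, orig$absorbance, tolerance = 1e-9)
})

test_that("jcamp compressed (SQZ/DIF/DUP) ordinates decode correctly", {
  # hand-decoded expectation: A0 = SQZ 10; K = DIF +2 -> 12; each T = DUP 2
  # (the pending +2 difference applied once more) -> 14 then 16; % = DIF 0
  # -> 16; j2 = DIF -12 -> 4. YFACTOR 0.5 halves everything.
  path <- withr::local_tempfile(fileext = ".jdx")
  writeLines(c(
    "##TITLE=sqz dif dup fixture",
    "##JCAMP-DX=4.24",
    "##XUNITS=1/CM", "##YUNITS=ABSORBANCE",
    "##FIRSTX=1000", "##LASTX=990", "##NPOINTS=6",
    "##XFACTOR=1", "##YFACTOR=0.5",
    "##XYDATA=(X++(Y..Y))",
    "1000 A0 K T T % j2",
    "##END="), path)
  s <- read_spectrum(path)
  expect_equal(s$absorbance, 0.5 * c(10, 12, 14, 16, 16, 4))
  expect_equal(s$wavenumbers, seq(1000, 990, length.out = 6))

  # NPOINTS mismatch is an error, not a silent truncation
  bad <- sub("##NPOINTS=6", "##NPOINTS=7", readLines(path))
  path2 <- withr::local_tempfile(fileext = ".jdx")
  writeLines(bad, path2)
  expect_error(read_spectrum(path2), "NPOINTS")
})

test_that("multi-block jcamp files are rejected with a clear message", {
  path <- withr::local_tempfile(fileext = ".jdx")
  writeLines(c("##TITLE=a", "##BLOCKS=2", "##TITLE=b", "##END="), path)
  expect_error(read_spectrum(path), "multi-block")
})

test_that("degenerate spectra are never written", {
  s <- fixture_small_spectrum()
  s$wavenumbers <- s$wavenumbers[1]
  s$absorbance <- s$absorbance[1]
  expect_error(write_spectrum(s, withr::local_tempfile()), "degenerate")
})

test_that("resampling is exact on lines, the identity on its own grid, and never extrapolates", {
  grid <- seq(2000, 1000, by = -2)
  a <- 3e-4; b <- -0.05
  s <- ir_spectrum(grid, a * grid + b)

  expect_equal(resample_to_grid(s, grid)$absorbance, s$absorbance)

  target <- seq(1999, 1001, by = -7.3) # off-grid points inside coverage
  r <- resample_to_grid(s, target)
  expect_equal(r$absorbance, a * target + b, tolerance = 1e-12)

  expect_error(resample_to_grid(s, c(1500, 990)), "coverage")
  expect_error(resample_to_grid(s, c(2010, 1500)), "coverage")
})

test_that("band lookup honours the +/-1 cm-1 tolerance and breaks ties upward", {
  grid <- seq(1310, 1270, by = -2)
  expect_equal(grid[wn_index(grid, 1296)], 1296)
  expect_equal(grid[wn_index(grid, 1296.8)], 1296)
  # 1295 is equidistant from 1294 and 1296: tie goes to the higher wavenumber
  expect_equal(grid[wn_index(grid, 1295)], 1296)
  expect_error(wn_index(grid, 1293.5 + 5), NA) # inside coverage, within tol
  expect_error(wn_index(grid, 1260), "not on the grid")
})

test_that("reference sets enforce a shared grid and survive a directory round trip", {
  grid <- seq(1600, 1200, by = -2)
  lib <- fixture_lib
  refs <- reference_set(list(
    urea = render_component(lib$urea, grid, 100),
    creatinine = render_component(lib$creatinine, grid, 10)))
  expect_s3_class(refs, "reference_set")
  expect_equal(refs$grid, grid)

  # a component on a different grid is resampled onto the shared one
  fine <- render_component(lib$urea, seq(1600, 1200, by = -1), 100)
  refs2 <- reference_set(list(urea = fine, creatinine =
                                refs$components$creatinine), grid = grid)
  expect_equal(length(refs2$components$urea$wavenumbers), length(grid))

  expect_error(reference_set(list(refs$components$urea)), "named")
  expect_error(reference_set(list(a = refs$components$urea,
                                  a = refs$components$creatinine)),
               "duplicate")

  dir <- withr::local_tempdir()
  write_reference_set(refs, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_reference_set(dir)
  expect_equal(names(back$components), names(refs$components))
  expect_equal(back$components$urea$absorbance,
               refs$components$urea$absorbance, tolerance = 1e-9)
})
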