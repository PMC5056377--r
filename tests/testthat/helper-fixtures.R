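# Shared fixtures: the default analysis grid is large, so most unit tests
# use the band library on the full grid but only a handful of spectra.

fixture_grid <- default_grid()
fixture_lib <- default_component_library()

fixture_refs <- function(grid = fixture_grid, lib = fixture_lib,
                         ref_urea = 100, ref_creatinine = 10) {
  reference_set(list(
    urea = render_component(lib$urea, grid, ref_urea),
    creatinine = render_component(lib$creatinine, grid, ref_creatinine),
    cystine = render_component(lib$cystine, grid, 1),
    liquid_water = render_component(lib$liquid_water, grid, 1),
    water_vapour = render_component(lib$water_vapour, grid, 1)), grid)
}

# small synthetic spectrum for I/O tests
fixture_small_spectrum <- function(n = 25, seed = 7) {
  wn <- seq(1500, by = -2, length.out = n)
  ab <- with_seed_test(seed, stats::runif(n, 0, 0.5))
  ir_spectrum(wn, ab, meta = list(sample_id = "fix", scans = 500))
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}
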