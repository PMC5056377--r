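#' Band and component models for the forward simulator
#'
#' A component model is a named set of absorbance bands. Each band has a
#' centre (cm-1), a height expressed as absorbance per mM at the band peak,
#' a full width at half maximum (cm-1) and a line shape: `gaussian`,
#' `lorentzian` or `pseudo_voigt` (the mixing fraction `eta` weights the
#' Lorentzian part; `eta = 0` and `eta = 1` recover the pure shapes).
#'
#' @param center band centre, cm-1.
#' @param height peak absorbance per mM (>= 0).
#' @param fwhm full width at half maximum, cm-1 (> 0).
#' @param shape one of `"gaussian"`, `"lorentzian"`, `"pseudo_voigt"`.
#' @param eta Lorentzian fraction in \[0, 1\] for `pseudo_voigt`.
#' @return `band_model()`: a one-row data.frame; `component_model()`: an
#'   object of class `component_model` with `name` and a data.frame `bands`.
#' @export
band_model <- function(center, height, fwhm, shape = "pseudo_voigt",
                       eta = 0.5) {
  shape <- match.arg(shape, c("gaussian", "lorentzian", "pseudo_voigt"))
  if (fwhm <= 0) stop("band fwhm must be positive")
  if (height < 0) stop("band height must be non-negative")
  if (eta < 0 || eta > 1) stop("eta must lie in [0, 1]")
  data.frame(center = center, height = height, fwhm = fwhm,
             shape = shape, eta = eta, stringsAsFactors = FALSE)
}

#' @rdname band_model
#' @param name component identifier.
#' @param bands data.frame of bands, e.g. `rbind()` of [band_model()] rows.
#' @export
component_model <- function(name, bands) {
  if (!nrow(bands)) stop("a component needs at least one band")
  structure(list(name = name, bands = bands), class = "component_model")
}

# Peak-normalised band profile on a wavenumber grid
band_profile <- function(grid, center, fwhm, shape, eta) {
  u <- (grid - center) / fwhm
  g <- exp(-4 * log(2) * u^2)
  l <- 1 / (1 + 4 * u^2)
  switch(shape,
         gaussian = g,
         lorentzian = l,
         pseudo_voigt = eta * l + (1 - eta) * g)
}

#' Default component band library
#'
#' Synthetic stand-ins for the five components the analysis needs. Band
#' positions follow the assignments the method relies on: cystine at 1296
#' cm-1 (plus the weaker 845 and 775 cm-1 bands), urea and creatinine as
#' distinct overlapping bands inside the 1510-1445 cm-1 quantitation window,
#' liquid water as broad bands near 1640 (bend) and 3350 cm-1 (OH stretch),
#' and water vapour as a comb of 40 narrow Lorentzian lines across 2000-1300
#' cm-1 with a fixed height pattern. Peak heights (absorbance per mM) are
#' synthetic: true molar absorptivities at these wavenumbers are not
#' tabulated here, so the library is calibrated only in the sense that a
#' 3 mM cystine film gives a second-derivative band response roughly 50
#' times the default spectral noise. `liquid_water` and `water_vapour` are
#' unit components: their "concentration" is the dimensionless scale factor
#' applied during simulation and removed by fractional subtraction.
#'
#' @return Named list of [component_model()] objects.
#' @export
default_component_library <- function() {
  vap_centres <- seq(2000, 1300, length.out = 40)
  # fixed quasi-irregular height pattern; deterministic so the reference
  # spectrum used for subtraction is exactly the contaminating comb
  vap_heights <- 0.01 * (0.3 + 0.7 * abs(sin(seq_along(vap_centres) * 2.4)))
  list(
    cystine = component_model("cystine", rbind(
      band_model(1296, 0.033, 10),
      band_model(845, 0.008, 12),
      band_model(775, 0.006, 12))),
    urea = component_model("urea", rbind(
      band_model(1462, 0.0020, 28),
      band_model(1160, 0.0008, 30))),
    creatinine = component_model("creatinine", rbind(
      band_model(1490, 0.0030, 20),
      band_model(1240, 0.0012, 24))),
    liquid_water = component_model("liquid_water", rbind(
      band_model(1640, 0.50, 120),
      band_model(3350, 1.20, 420))),
    water_vapour = component_model("water_vapour", do.call(rbind, Map(
      function(c0, h) band_model(c0, h, 4, shape = "lorentzian"),
      vap_centres, vap_heights)))
  )
}

#' Render a component spectrum at a given concentration
#'
#' Absorbance is `concentration` times the sum of the component's band
#' profiles (Beer-Lambert linearity: exactly linear in concentration, no
#' saturation).
#'
#' @param component a [component_model()].
#' @param grid wavenumber grid (descending).
#' @param concentration mM (>= 0). For the unit components `liquid_water`
#'   and `water_vapour` this is a dimensionless scale.
#' @return An [ir_spectrum()].
#' @export
render_component <- function(component, grid, concentration = 1) {
  stopifnot(inherits(component, "component_model"))
  if (concentration < 0)
    stop("concentration must be non-negative, got ", concentration)
  b <- component$bands
  y <- numeric(length(grid))
  for (i in seq_len(nrow(b)))
    y <- y + b$height[i] * band_profile(grid, b$center[i], b$fwhm[i],
                                        b$shape[i], b$eta[i])
  ir_spectrum(grid, concentration * y,
              meta = list(component = component$name,
                          concentration_mM = concentration))
}

# Seed derivation: stable polynomial rolling hash of (master, id, replicate)
# so every sample/replicate gets an independent, reproducible RNG stream.
# Multiplier kept small so intermediate products stay exact in doubles.
derive_seed <- function(master, ...) {
  key <- paste(c(master, ...), collapse = "\x1f")
  bytes <- utf8ToInt(key)
  h <- 17
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}

# Run code with a local RNG state; the caller's stream is untouched.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specify one simulated measurement
#'
#' Bundles everything [generate_sample()] needs: component concentrations,
#' baseline drift (polynomial in the scaled wavenumber coordinate
#' `u = (wn - 750) / (4000 - 750)`), the i.i.d. Gaussian spectral noise sd,
#' the water-vapour and liquid-water contamination scales, and the RNG seed.
#'
#' @param concentrations named numeric vector/list, component -> mM (>= 0).
#' @param baseline_coeffs polynomial coefficients, constant term first.
#' @param noise_sd absorbance noise sd (>= 0).
#' @param vapour_factor,water_factor contamination scales (>= 0).
#' @param seed integer RNG seed.
#' @return A `sample_spec` list.
#' @export
sample_spec <- function(concentrations = c(), baseline_coeffs = 0,
                        noise_sd = 2e-4, vapour_factor = 0, water_factor = 0,
                        seed = 1L) {
  concentrations <- unlist(concentrations)
  if (length(concentrations) && any(concentrations < 0))
    stop("concentrations must be non-negative")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(concentrations = concentrations,
                 baseline_coeffs = as.numeric(baseline_coeffs),
                 noise_sd = noise_sd, vapour_factor = vapour_factor,
                 water_factor = water_factor, seed = as.integer(seed)),
            class = "sample_spec")
}

baseline_eval <- function(grid, coeffs) {
  u <- (grid - 750) / (4000 - 750)
  y <- numeric(length(grid))
  for (k in seq_along(coeffs)) y <- y + coeffs[k] * u^(k - 1)
  y
}

#' Simulate one absorbance spectrum
#'
#' The measurement model is additive: rendered components at their stated
#' concentrations, plus `water_factor` times the unit liquid-water spectrum,
#' plus `vapour_factor` times the unit water-vapour comb, plus a polynomial
#' baseline, plus i.i.d. Gaussian noise. Deterministic given the seed.
#'
#' @param spec a [sample_spec()].
#' @param library component library, as [default_component_library()].
#' @param grid wavenumber grid.
#' @return An [ir_spectrum()].
#' @export
generate_sample <- function(spec, library = default_component_library(),
                            grid = default_grid()) {
  stopifnot(inherits(spec, "sample_spec"))
  y <- numeric(length(grid))
  for (nm in names(spec$concentrations)) {
    if (is.null(library[[nm]]))
      stop("unknown component '", nm, "' (library has: ",
           paste(names(library), collapse = ", "), ")")
    y <- y + render_component(library[[nm]], grid,
                              spec$concentrations[[nm]])$absorbance
  }
  if (spec$water_factor != 0)
    y <- y + spec$water_factor *
      render_component(library$liquid_water, grid, 1)$absorbance
  if (spec$vapour_factor != 0)
    y <- y + spec$vapour_factor *
      render_component(library$water_vapour, grid, 1)$absorbance
  y <- y + baseline_eval(grid, spec$baseline_coeffs)
  if (spec$noise_sd > 0)
    y <- y + with_seed(spec$seed, stats::rnorm(length(grid), 0, spec$noise_sd))
  ir_spectrum(grid, y, meta = list(seed = spec$seed,
                                   noise_sd = spec$noise_sd))
}

#' Simulate a dried-film cystine calibration series
#'
#' One dried-film spectrum per concentration, emulating 5 uL aliquots of 0
#' to 3 mM cystine suspensions dried on the prism. Standards are clean by
#' default (no baseline or water contamination); pass `vapour_factor` etc.
#' to dirty them up.
#'
#' @param concentrations mM series, default `seq(0, 3, by = 0.5)`.
#' @param noise_sd absorbance noise sd.
#' @param seed master seed; per-member streams are derived from it.
#' @param library,grid as in [generate_sample()].
#' @param vapour_factor,water_factor,baseline_coeffs contamination passed to
#'   each member.
#' @return List with one element per concentration: `list(concentration_mM,
#'   spectrum)`.
#' @export
generate_calibration_series <- function(concentrations = seq(0, 3, by = 0.5),
                                        noise_sd = 2e-4, seed = 1L,
                                        library = default_component_library(),
                                        grid = default_grid(),
                                        vapour_factor = 0, water_factor = 0,
                                        baseline_coeffs = 0) {
  if (!length(concentrations)) stop("empty calibration series")
  if (any(concentrations < 0)) stop("concentrations must be non-negative")
  lapply(seq_along(concentrations), function(i) {
    sp <- sample_spec(
      concentrations = c(cystine = concentrations[i]),
      baseline_coeffs = baseline_coeffs, noise_sd = noise_sd,
      vapour_factor = vapour_factor, water_factor = water_factor,
      seed = derive_seed(seed, "calibration", i))
    list(concentration_mM = concentrations[i],
         spectrum = generate_sample(sp, library, grid))
  })
}

#' Saturation of the spectroscopically active film volume
#'
#' The evanescent wave probes only ~1 um above the prism, so a dried film
#' holding more analyte than the active volume can accommodate stops gaining
#' absorbance. Modelled as a hard plateau: the response is scaled by
#' `min(1, capacity / amount)` - linear below capacity, flat above.
#'
#' @param spectrum the unsaturated rendered [ir_spectrum()].
#' @param amount_nmol nanomoles deposited in the film.
#' @param capacity_nmol capacity of the active volume (> 0), cf.
#'   [spot_capacity()].
#' @return The scaled `ir_spectrum`.
#' @export
saturate_film <- function(spectrum, amount_nmol, capacity_nmol) {
  stopifnot(is_ir_spectrum(spectrum))
  if (capacity_nmol <= 0) stop("capacity must be positive")
  if (amount_nmol < 0) stop("amount must be non-negative")
  f <- if (amount_nmol <= capacity_nmol) 1 else capacity_nmol / amount_nmol
  ir_spectrum(spectrum$wavenumbers, f * spectrum$absorbance,
              meta = c(spectrum$meta, list(saturation_factor = f)))
}

#' Default cohort distribution block
#'
#' Study-shaped defaults: urea log-uniform on 28-443 mM, creatinine uniform
#' on 0.5-20 mM, insoluble cystine uniform on 0-3.1 mM for patients and 0
#' for controls; triplicate dried-film aliquots with 2% aliquot-to-aliquot
#' concentration CV; Jaffe creatinine = truth + 1.4 mM bias + N(0, 1 mM);
#' IEC total cystine = insoluble + soluble + N(0, 0.1 mM). The soluble
#' fraction of any urine carrying insoluble cystine sits at the 1 mM
#' solubility limit (a suspension is saturated by definition - the same
#' argument that justifies the reporting offset); unsaturated urines draw a
#' sub-limit value, U\[0.5, 1\] mM for patients and U\[0, 1\] mM for
#' controls.
#'
#' @param ... overrides for any element.
#' @return Named list of distribution parameters.
#' @export
cohort_distributions <- function(...) {
  defaults <- list(
    urea_range = c(28, 443), creatinine_range = c(0.5, 20),
    cystine_range = c(0, 3.1), solubility_limit = 1.0,
    soluble_range = c(0.5, 1), control_soluble_range = c(0, 1),
    noise_sd = 2e-4, n_replicates = 3L, aliquot_cv = 0.02,
    jaffe_bias = 1.4, jaffe_sd = 1.0, iec_sd = 0.1,
    vapour_factor_range = c(0.05, 0.3), urine_water_factor = 0.95,
    urine_baseline_range = c(-0.02, 0.02),
    film_baseline_range = c(-0.005, 0.005))
  utils::modifyList(defaults, list(...))
}

#' Simulate a urine cohort with paired clinical comparator values
#'
#' Per subject: one undried-urine spectrum (urea + creatinine on a dominant
#' liquid-water background with vapour lines, linear baseline and noise),
#' `n_replicates` dried insoluble-fraction spectra (independent aliquots:
#' the true film concentration is jittered by the aliquot CV), and noisy
#' comparator measurements (Jaffe creatinine; IEC total cystine = soluble +
#' insoluble). Controls carry no insoluble cystine. Fully deterministic
#' given the master seed.
#'
#' @param n_patients,n_controls subject counts (>= 0).
#' @param distributions a [cohort_distributions()] block.
#' @param seed master seed.
#' @param library,grid as in [generate_sample()].
#' @return List with `samples` (per subject: `id`, `treatment`, `urine`
#'   spectrum, `insoluble` list of replicate spectra) and `truth`, a
#'   data.frame of the generating values and comparator measurements.
#' @export
generate_cohort <- function(n_patients = 22, n_controls = 5,
                            distributions = cohort_distributions(),
                            seed = 1L,
                            library = default_component_library(),
                            grid = default_grid()) {
  d <- distributions
  if (n_patients < 0 || n_controls < 0) stop("cohort counts must be >= 0")
  rng_ok <- function(r) length(r) == 2 && all(is.finite(r)) && r[2] >= r[1]
  for (nm in c("urea_range", "creatinine_range", "cystine_range",
               "soluble_range", "control_soluble_range"))
    if (!rng_ok(d[[nm]]) || any(d[[nm]] < 0))
      stop("invalid distribution parameter '", nm, "'")
  if (d$noise_sd < 0 || d$aliquot_cv < 0 || d$n_replicates < 1)
    stop("invalid distribution parameters (noise_sd/aliquot_cv/n_replicates)")

  n <- n_patients + n_controls
  ids <- c(sprintf("P%02d", seq_len(n_patients)),
           sprintf("C%02d", seq_len(n_controls)))
  is_patient <- c(rep(TRUE, n_patients), rep(FALSE, n_controls))

  truth <- with_seed(derive_seed(seed, "truth"), {
    urea <- exp(stats::runif(n, log(d$urea_range[1]), log(d$urea_range[2])))
    crea <- stats::runif(n, d$creatinine_range[1], d$creatinine_range[2])
    cys <- ifelse(is_patient,
                  stats::runif(n, d$cystine_range[1], d$cystine_range[2]), 0)
    # a urine carrying insoluble cystine is saturated, so its soluble
    # fraction sits at the ~1 mM solubility limit; unsaturated urines draw
    # a sub-limit value
    sub_lim <- ifelse(is_patient,
                      stats::runif(n, d$soluble_range[1], d$soluble_range[2]),
                      stats::runif(n, d$control_soluble_range[1],
                                   d$control_soluble_range[2]))
    sol <- ifelse(cys > 0, d$solubility_limit, sub_lim)
    jaffe <- crea + d$jaffe_bias + stats::rnorm(n, 0, d$jaffe_sd)
    iec <- pmax(0, cys + sol + stats::rnorm(n, 0, d$iec_sd))
    data.frame(sample_id = ids, treatment = is_patient,
               urea_mM = urea, creatinine_mM = crea,
               insoluble_cystine_mM = cys, soluble_cystine_mM = sol,
               jaffe_creatinine_mM = jaffe, iec_total_cystine_mM = iec,
               stringsAsFactors = FALSE)
  })

  samples <- lapply(seq_len(n), function(i) {
    id <- ids[i]
    aux <- with_seed(derive_seed(seed, id, "aux"), list(
      vap = stats::runif(1, d$vapour_factor_range[1], d$vapour_factor_range[2]),
      ub = stats::runif(2, d$urine_baseline_range[1], d$urine_baseline_range[2]),
      fb = stats::runif(d$n_replicates * 3, d$film_baseline_range[1],
                        d$film_baseline_range[2]),
      jit = stats::rnorm(d$n_replicates, 0, d$aliquot_cv)))
    urine <- generate_sample(sample_spec(
      concentrations = c(urea = truth$urea_mM[i],
                         creatinine = truth$creatinine_mM[i]),
      baseline_coeffs = aux$ub, noise_sd = d$noise_sd,
      vapour_factor = aux$vap, water_factor = d$urine_water_factor,
      seed = derive_seed(seed, id, "urine")), library, grid)
    insol <- lapply(seq_len(d$n_replicates), function(r) {
      conc <- max(0, truth$insoluble_cystine_mM[i] * (1 + aux$jit[r]))
      generate_sample(sample_spec(
        concentrations = c(cystine = conc),
        baseline_coeffs = aux$fb[(r - 1) * 3 + 1:3] * c(1, 1, 0.5),
        noise_sd = d$noise_sd, vapour_factor = aux$vap,
        seed = derive_seed(seed, id, "film", r)), library, grid)
    })
    list(id = id, treatment = is_patient[i], urine = urine, insoluble = insol)
  })
  list(samples = samples, truth = truth)
}
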