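#' Assemble the analysis configuration
#'
#' One serialisable block holding every tunable of the end-to-end analysis:
#' grid, Savitzky-Golay parameters, subtraction and deconvolution windows,
#' the calibration series, detection-threshold rule, solubility offset and
#' seeds. Every pipeline output embeds the FNV-1a digest of the canonical
#' JSON form of this block, so a run is reproducible from its report alone.
#'
#' @param seed master seed for all simulated randomness.
#' @param n_patients,n_controls simulated cohort sizes.
#' @param grid_from,grid_to,grid_by wavenumber grid, cm-1.
#' @param sg_window,sg_polyorder Savitzky-Golay second-derivative settings.
#' @param vapour_window,water_window fractional-subtraction fit windows.
#' @param deconv_window,baseline_order urea/creatinine deconvolution
#'   settings.
#' @param calibration_concentrations cystine standard series, mM.
#' @param offset_mM solubility offset for total-cystine reporting.
#' @param ref_urea_mM,ref_creatinine_mM concentrations at which the pure
#'   reference spectra are rendered (the deconvolution coefficient
#'   calibration).
#' @param distributions cohort distribution block,
#'   [cohort_distributions()].
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, n_patients = 22L, n_controls = 5L,
                       grid_from = 4000, grid_to = 750, grid_by = 2,
                       sg_window = 9L, sg_polyorder = 3L,
                       vapour_window = c(1900, 1700),
                       water_window = c(3900, 3100),
                       deconv_window = c(1510, 1445), baseline_order = 1L,
                       calibration_concentrations = seq(0, 3, by = 0.5),
                       offset_mM = 1.0,
                       ref_urea_mM = 100, ref_creatinine_mM = 10,
                       distributions = cohort_distributions()) {
  structure(list(seed = as.integer(seed), n_patients = as.integer(n_patients),
                 n_controls = as.integer(n_controls),
                 grid_from = grid_from, grid_to = grid_to, grid_by = grid_by,
                 sg_window = as.integer(sg_window),
                 sg_polyorder = as.integer(sg_polyorder),
                 vapour_window = vapour_window, water_window = water_window,
                 deconv_window = deconv_window,
                 baseline_order = as.integer(baseline_order),
                 calibration_concentrations = calibration_concentrations,
                 offset_mM = offset_mM, ref_urea_mM = ref_urea_mM,
                 ref_creatinine_mM = ref_creatinine_mM,
                 distributions = distributions),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Fields mirror the [run_config()] arguments; missing fields take their
#' defaults, `distributions` entries override [cohort_distributions()].
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  dist <- do.call(cohort_distributions, as.list(y$distributions))
  y$distributions <- NULL
  do.call(run_config, c(y, list(distributions = dist)))
}

# FNV-1a digest over the canonical JSON serialisation (multiplication split
# so intermediates stay exact in doubles)
config_digest <- function(config) {
  txt <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = 12)
  bytes <- utf8ToInt(as.character(txt))
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 65536; hi <- (h - lo) / 65536 # 16-bit halves keep xor exact
    h <- hi * 65536 + bitwXor(lo, b)
    lo <- h %% 65536; hi <- (h - lo) / 65536
    h <- (((hi * 403) %% 65536) * 65536 + lo * 16777619) %% 4294967296
  }
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

#' Run the complete quantitation pipeline on a simulated cohort
#'
#' End-to-end demonstration and validation harness: simulate a cohort,
#' build the reference set, calibrate the second-derivative cystine
#' response on the standard series, then for every subject subtract water
#' vapour (and, for undried urine, liquid water), deconvolve urea and
#' creatinine from 1510-1445 cm-1, quantitate insoluble cystine from the
#' replicate dried films, apply the reporting conventions, and compare
#' against the simulated clinical comparators (Jaffe creatinine;
#' ion-exchange total cystine with the 1 mM offset). Deterministic given
#' the config seed.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, writes `results.csv`,
#'   `truth.csv`, `calibration.json`, `comparisons.json` and `config.json`
#'   (all plain text, byte-reproducible for a fixed config).
#' @return List: `results` (per-sample [quant_table()] plus truth columns),
#'   `calibration` model, `lod_mM`, `creatinine_comparison` (Jaffe vs FTIR),
#'   `cystine_comparison` (IEC vs FTIR + offset), `truth`, `config`,
#'   `config_digest`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  grid <- seq(config$grid_from, config$grid_to, by = -config$grid_by)
  comp_lib <- default_component_library()
  refs <- reference_set(list(
    urea = render_component(comp_lib$urea, grid, config$ref_urea_mM),
    creatinine = render_component(comp_lib$creatinine, grid,
                                  config$ref_creatinine_mM),
    cystine = render_component(comp_lib$cystine, grid, 1),
    liquid_water = render_component(comp_lib$liquid_water, grid, 1),
    water_vapour = render_component(comp_lib$water_vapour, grid, 1)),
    grid = grid)
  deconv_cal <- list(urea = config$ref_urea_mM,
                     creatinine = config$ref_creatinine_mM)

  # calibration: clean dried standards, vapour-corrected like the samples
  series <- generate_calibration_series(
    config$calibration_concentrations,
    noise_sd = config$distributions$noise_sd,
    seed = derive_seed(config$seed, "calibration"),
    library = comp_lib, grid = grid,
    vapour_factor = 0.1)
  responses <- vapply(series, function(m) {
    corr <- subtract_water(m$spectrum, refs, config$vapour_window,
                           water = FALSE)$corrected
    cystine_response(corr, config$sg_window, config$sg_polyorder)
  }, numeric(1))
  calibration <- fit_calibration(config$calibration_concentrations, responses)
  lod <- detection_limit(calibration)

  cohort <- generate_cohort(config$n_patients, config$n_controls,
                            config$distributions, seed = config$seed,
                            library = comp_lib, grid = grid)

  results <- lapply(cohort$samples, function(smp) {
    urine <- subtract_water(smp$urine, refs, config$vapour_window,
                            config$water_window)$corrected
    fit <- fit_components(urine, refs, config$deconv_window,
                          config$baseline_order,
                          calibrations = deconv_cal)
    reps <- vapply(smp$insoluble, function(sp) {
      corr <- subtract_water(sp, refs, config$vapour_window,
                             water = FALSE)$corrected
      film <- predict_concentration(calibration,
                                    cystine_response(corr, config$sg_window,
                                                     config$sg_polyorder))
      apply_dilution(as.numeric(film), 1, 1)
    }, numeric(1))
    report_sample(smp$id, reps,
                  creatinine_mM = fit$concentrations[["creatinine"]],
                  urea_mM = fit$concentrations[["urea"]],
                  detection_threshold = lod,
                  offset_mM = config$offset_mM)
  })
  tab <- quant_table(results)
  tab <- merge(tab, cohort$truth, by = "sample_id", sort = TRUE,
               suffixes = c("", "_true"))

  crea_cmp <- bland_altman(tab$jaffe_creatinine_mM, tab$creatinine_mM,
                           ids = tab$sample_id)
  cys_cmp <- comparison_with_offset(
    tab[, c("sample_id", "insoluble_mM", "detected")],
    data.frame(sample_id = tab$sample_id,
               total_mM = tab$iec_total_cystine_mM),
    offset = config$offset_mM)

  out <- list(results = tab, calibration = calibration, lod_mM = lod,
              creatinine_comparison = crea_cmp,
              cystine_comparison = cys_cmp,
              truth = cohort$truth, config = config,
              config_digest = config_digest(config))
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

fmt_df <- function(df) {
  for (nm in names(df))
    if (is.numeric(df[[nm]])) df[[nm]] <- sprintf("%.10g", df[[nm]])
  df
}

write_pipeline_outputs <- function(out, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  digest_line <- sprintf("# config_digest: %s", out$config_digest)
  wr <- function(df, file) {
    con <- file.path(out_dir, file)
    writeLines(digest_line, con)
    suppressWarnings(utils::write.table(
      fmt_df(df), con, sep = ",", row.names = FALSE, quote = FALSE,
      append = TRUE))
  }
  wr(out$results, "results.csv")
  wr(out$truth, "truth.csv")
  cmp_json <- function(cmp) list(
    pearson_r = cmp$pearson_r, mean_bias = cmp$mean_bias,
    sd_diff = cmp$sd_diff, loa_low = cmp$loa_low, loa_high = cmp$loa_high,
    outliers = cmp$outliers, orientation = cmp$orientation,
    n = nrow(cmp$pairs))
  jsonlite::write_json(
    list(config_digest = out$config_digest,
         creatinine = cmp_json(out$creatinine_comparison),
         cystine = cmp_json(out$cystine_comparison)),
    file.path(out_dir, "comparisons.json"), auto_unbox = TRUE, digits = 12,
    pretty = TRUE)
  jsonlite::write_json(
    list(config_digest = out$config_digest,
         slope = out$calibration$slope, n_points = out$calibration$n_points,
         r_squared = out$calibration$r_squared,
         residual_sd = out$calibration$residual_sd,
         concentration_range = out$calibration$concentration_range,
         lod_mM = out$lod_mM,
         sg_window = out$config$sg_window,
         sg_polyorder = out$config$sg_polyorder),
    file.path(out_dir, "calibration.json"), auto_unbox = TRUE, digits = 12,
    pretty = TRUE)
  jsonlite::write_json(
    c(list(config_digest = out$config_digest), unclass(out$config)),
    file.path(out_dir, "config.json"), auto_unbox = TRUE, digits = 12,
    pretty = TRUE)
  invisible(out_dir)
}
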