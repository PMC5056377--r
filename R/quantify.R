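#' Through-origin calibration of band response against concentration
#'
#' Fits the Beer-Lambert calibration line used for cystine quantitation: a
#' linear line of best fit through the origin with no error weighting,
#' `slope = sum(c * r) / sum(c^2)`. Diagnostics: uncentred r-squared (the
#' standard no-intercept definition), residual sd on n - 1 degrees of
#' freedom, and the calibrated concentration range.
#'
#' @param concentration mM values of the standards (default series 0-3 mM).
#' @param response band responses, same length (conventionally the inverted
#'   second-derivative 1296 minus 1280 cm-1 difference, see
#'   [cystine_response()]).
#' @return A `calibration_model` list: `slope` (response per mM),
#'   `n_points`, `r_squared`, `residual_sd`, `concentration_range`,
#'   `slope_warning` (TRUE when the fitted slope is not positive).
#' @export
fit_calibration <- function(concentration, response) {
  concentration <- as.numeric(concentration)
  response <- as.numeric(response)
  if (length(concentration) != length(response))
    stop("concentration and response differ in length")
  if (length(concentration) < 2L)
    stop("need at least 2 calibration points")
  if (all(concentration == 0))
    stop("degenerate calibration: all concentrations are zero")
  if (any(concentration < 0)) stop("concentrations must be non-negative")
  slope <- sum(concentration * response) / sum(concentration^2)
  resid <- response - slope * concentration
  n <- length(response)
  residual_sd <- sqrt(sum(resid^2) / (n - 1))
  ss_tot <- sum(response^2) # uncentred: the through-origin convention
  r_squared <- if (ss_tot > 0) max(0, 1 - sum(resid^2) / ss_tot) else 1
  slope_warning <- slope <= 0
  if (slope_warning)
    warning("fitted calibration slope is not positive (", format(slope),
            "); check the response sign convention")
  structure(list(slope = slope, n_points = n, r_squared = r_squared,
                 residual_sd = residual_sd,
                 concentration_range = range(concentration),
                 slope_warning = slope_warning),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "<calibration_model> slope %.6g per mM (n = %d, R^2 = %.4f, residual sd %.3g)\n",
    x$slope, x$n_points, x$r_squared, x$residual_sd))
  cat(sprintf("  calibrated range %.3g to %.3g mM; LOD %.3g mM\n",
              x$concentration_range[1], x$concentration_range[2],
              detection_limit(x)))
  invisible(x)
}

#' 3-sigma limit of detection of a calibration
#'
#' The smallest concentration distinguishable from blank under the standard
#' 3-sigma convention: three times the calibration residual sd divided by
#' the slope.
#'
#' @param model a `calibration_model`.
#' @return LOD in mM.
#' @export
detection_limit <- function(model) {
  stopifnot(inherits(model, "calibration_model"))
  if (model$slope <= 0) return(NA_real_)
  3 * model$residual_sd / model$slope
}

#' Predict concentration from a band response
#'
#' `concentration = response / slope`, clipped at zero. Responses mapping
#' above the calibrated range are allowed but flagged (linearity beyond the
#' calibrated standards is unverified).
#'
#' @param model a `calibration_model` with positive slope.
#' @param response numeric vector of band responses.
#' @return Numeric mM vector with attribute `extrapolated` (logical vector).
#' @export
predict_concentration <- function(model, response) {
  stopifnot(inherits(model, "calibration_model"))
  if (model$slope <= 0)
    stop("invalid calibration model: slope must be positive (got ",
         format(model$slope), ")")
  conc <- pmax(0, as.numeric(response) / model$slope)
  structure(conc, extrapolated = conc > model$concentration_range[2])
}

#' Correct a film concentration for the centrifugation bookkeeping
#'
#' The insoluble fraction of `original_volume` mL urine is pelleted and
#' re-suspended in `resuspension_volume` mL water before drying, so the
#' concentration in the original urine is the measured film value times
#' `resuspension_volume / original_volume`. The reference protocol uses
#' 1 mL into 1 mL, the identity.
#'
#' @param concentration_in_film mM measured in the dried/resuspended film.
#' @param original_volume,resuspension_volume mL (> 0).
#' @return mM in the original urine.
#' @export
apply_dilution <- function(concentration_in_film, original_volume = 1,
                           resuspension_volume = 1) {
  if (original_volume <= 0 || resuspension_volume <= 0)
    stop("volumes must be positive")
  concentration_in_film * (resuspension_volume / original_volume)
}

#' Summarise replicate measurements of one sample
#'
#' Applies the reporting conventions: mean and standard error over
#' replicates (n - 1 sd); a sample is `detected` when the mean exceeds the
#' detection threshold; detected samples get a total-cystine estimate of
#' insoluble + 1 mM (the solubility limit accounts for the soluble fraction
#' that must have been present), undetected samples are censored to the
#' interval 0.5 +/- 0.5 mM and their insoluble value reported as 0; the
#' cystine:creatinine ratio is in uM per mM (insoluble mM x 1000 /
#' creatinine mM), undefined when creatinine <= 0.
#'
#' @param sample_id identifier.
#' @param insoluble_mM per-replicate insoluble cystine, mM (>= 1 value).
#' @param creatinine_mM urinary creatinine, mM (for normalisation).
#' @param urea_mM urinary urea, mM (context only).
#' @param detection_threshold mM; typically [detection_limit()] of the
#'   calibration.
#' @param offset_mM solubility offset added to detected samples (default 1).
#' @return A `quant_result` list; see Details. `total_cystine_mM` is a point
#'   value when detected, otherwise `c(centre = 0.5, halfwidth = 0.5)`.
#' @export
report_sample <- function(sample_id, insoluble_mM, creatinine_mM = NA_real_,
                          urea_mM = NA_real_, detection_threshold = 0,
                          offset_mM = 1.0) {
  insoluble_mM <- as.numeric(insoluble_mM)
  if (!length(insoluble_mM)) stop("need at least one replicate")
  n <- length(insoluble_mM)
  m <- mean(insoluble_mM)
  sem <- if (n > 1) stats::sd(insoluble_mM) / sqrt(n) else NA_real_
  detected <- m > detection_threshold
  reported <- if (detected) m else 0
  total <- if (detected) m + offset_mM else c(centre = 0.5, halfwidth = 0.5)
  ratio <- if (!is.na(creatinine_mM) && creatinine_mM > 0)
    reported * 1000 / creatinine_mM else NA_real_
  structure(list(sample_id = sample_id, replicates_mM = insoluble_mM,
                 insoluble_cystine_mM = reported, sem_mM = sem,
                 detected = detected, total_cystine_mM = total,
                 censored = !detected,
                 creatinine_mM = creatinine_mM, urea_mM = urea_mM,
                 ratio_uM_per_mM = ratio,
                 detection_threshold_mM = detection_threshold),
            class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  tot <- if (x$censored) "0.5 +/- 0.5 (censored)" else
    sprintf("%.3g", x$total_cystine_mM)
  cat(sprintf(
    "<quant_result> %s: insoluble %.3g mM (SEM %.3g, n = %d), %s; total %s mM\n",
    x$sample_id, x$insoluble_cystine_mM, x$sem_mM, length(x$replicates_mM),
    if (x$detected) "detected" else "not detected", tot))
  if (!is.na(x$ratio_uM_per_mM))
    cat(sprintf("  cystine:creatinine %.4g uM/mM (creatinine %.3g mM)\n",
                x$ratio_uM_per_mM, x$creatinine_mM))
  invisible(x)
}

#' Tabulate quantitation results
#'
#' @param x list of `quant_result` objects (or a single one).
#' @return data.frame with one row per sample, mirroring the per-sample
#'   report columns (censored totals appear as the 0.5 mM centre with
#'   `total_halfwidth_mM` 0.5).
#' @export
quant_table <- function(x) {
  if (inherits(x, "quant_result")) x <- list(x)
  do.call(rbind, lapply(x, function(q) {
    tot <- if (q$censored) q$total_cystine_mM[["centre"]] else q$total_cystine_mM
    hw <- if (q$censored) q$total_cystine_mM[["halfwidth"]] else 0
    data.frame(sample_id = q$sample_id,
               insoluble_mM = q$insoluble_cystine_mM, sem_mM = q$sem_mM,
               detected = q$detected, total_mM = tot,
               total_halfwidth_mM = hw,
               creatinine_mM = q$creatinine_mM, urea_mM = q$urea_mM,
               ratio_uM_per_mM = q$ratio_uM_per_mM,
               stringsAsFactors = FALSE)
  }))
}

#' Capacity of the spectroscopically active film volume
#'
#' How much analyte fits inside the volume probed by the evanescent wave: a
#' cylinder of the deposited spot's diameter and the penetration depth's
#' height, divided by the molecular volume, converted to moles. All three
#' lengths must be expressed in one common unit (the volume in that unit
#' cubed); the result only depends on the dimensionless count, so it is
#' invariant under any consistent rescaling of the inputs. The defaults are
#' the cystine worked example: 193 Angstrom^3 molecular volume, ~1 um active
#' height, 3 mm spot diameter (in metres), giving ~60 nmol - equivalent to a
#' 5 uL drop of a 12 mM suspension.
#'
#' @param molecular_volume molecular volume, length-unit^3
#'   (default 193 Angstrom^3 = 193e-30 m^3).
#' @param film_height active film height (default 1 um = 1e-6 m).
#' @param spot_diameter spot diameter (default 3 mm = 3e-3 m).
#' @return Capacity in nanomoles.
#' @examples
#' spot_capacity() # ~60.8 nmol
#' @export
spot_capacity <- function(molecular_volume = 193e-30, film_height = 1e-6,
                          spot_diameter = 3e-3) {
  if (molecular_volume <= 0 || film_height <= 0 || spot_diameter <= 0)
    stop("all spot_capacity arguments must be positive")
  avogadro <- 6.02214076e23
  film_volume <- pi * (spot_diameter / 2)^2 * film_height
  (film_volume / molecular_volume) / avogadro * 1e9
}
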