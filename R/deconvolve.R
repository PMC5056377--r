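#' Constrained least-squares deconvolution of overlapping bands
#'
#' Estimates component scales in a spectral window by minimising
#' `sum((sample - sum_c coef_c * ref_c - baseline)^2)` subject to
#' `coef_c >= 0`, with a free polynomial baseline of order `baseline_order`.
#' The default window, 1510-1445 cm-1, is the region of undried urine
#' spectra dominated by urea and creatinine. The non-negativity constraint
#' is handled by active-set non-negative least squares; the unconstrained
#' baseline coefficients enter as the usual difference of two non-negative
#' columns.
#'
#' @param sample an [ir_spectrum()] (typically water- and vapour-corrected).
#' @param references a [reference_set()] holding the components to fit.
#' @param window cm-1 interval, endpoints inclusive on the nearest-grid
#'   convention; default `c(1510, 1445)`.
#' @param baseline_order polynomial baseline order (default 1, i.e. affine);
#'   negative for no baseline.
#' @param components names of the components to fit, default
#'   `c("urea", "creatinine")`.
#' @param calibrations optional named list of mM-per-unit-coefficient
#'   slopes; when present, concentrations are filled in via
#'   [concentration_from_coefficients()].
#' @return A `deconvolution_fit` list: `coefficients` (named, >= 0),
#'   `baseline_coeffs`, `concentrations` (or NULL), `window`,
#'   `residual_rms`, `condition_number`.
#' @export
fit_components <- function(sample, references, window = c(1510, 1445),
                           baseline_order = 1,
                           components = c("urea", "creatinine"),
                           calibrations = NULL) {
  stopifnot(is_ir_spectrum(sample), inherits(references, "reference_set"))
  missing <- setdiff(components, names(references$components))
  if (length(missing))
    stop("reference set lacks component(s): ", paste(missing, collapse = ", "))
  if (!same_grid(sample, list(wavenumbers = references$grid)))
    sample <- resample_to_grid(sample, references$grid)
  idx <- window_indices(references$grid, window)
  n_base <- max(0L, baseline_order + 1L)
  n_par <- length(components) + n_base
  if (length(idx) < 2L * n_par)
    stop("window holds ", length(idx), " grid points for ", n_par,
         " free parameters; need at least ", 2L * n_par)
  R <- vapply(components,
              function(nm) references$components[[nm]]$absorbance[idx],
              numeric(length(idx)))
  # scale columns to unit norm so the condition number reflects shape overlap
  nrm <- sqrt(colSums(R^2))
  if (any(nrm == 0))
    stop("component(s) ", paste(components[nrm == 0], collapse = ", "),
         " are zero on the fit window")
  Rs <- sweep(R, 2, nrm, "/")
  sv <- svd(Rs)$d
  kappa <- sv[1] / sv[length(sv)]
  if (!is.finite(kappa) || kappa > 1e8)
    stop(sprintf(
      "reference spectra are collinear on the window (condition number %.3g); cannot separate components",
      kappa))
  u <- seq(-1, 1, length.out = length(idx))
  B <- if (n_base > 0) outer(u, 0:(n_base - 1L), `^`) else NULL
  A <- if (is.null(B)) Rs else cbind(Rs, B, -B) # +/- split frees the baseline
  fit <- pracma::lsqnonneg(A, sample$absorbance[idx])
  x <- fit$x
  k <- length(components)
  coefficients <- stats::setNames(x[seq_len(k)] / nrm, components)
  baseline_coeffs <- if (n_base > 0)
    x[k + seq_len(n_base)] - x[k + n_base + seq_len(n_base)] else numeric(0)
  resid <- sample$absorbance[idx] - as.vector(A %*% x)
  concentrations <- if (!is.null(calibrations))
    concentration_from_coefficients(coefficients, calibrations) else NULL
  structure(list(coefficients = coefficients,
                 baseline_coeffs = baseline_coeffs,
                 concentrations = concentrations,
                 window = sort(window, decreasing = TRUE),
                 residual_rms = sqrt(mean(resid^2)),
                 condition_number = kappa),
            class = "deconvolution_fit")
}

#' @export
print.deconvolution_fit <- function(x, ...) {
  cat(sprintf("<deconvolution_fit> window [%.6g, %.6g] cm-1, residual rms %.3g\n",
              x$window[1], x$window[2], x$residual_rms))
  cat("  coefficients:",
      paste(sprintf("%s = %.4g", names(x$coefficients), x$coefficients),
            collapse = ", "), "\n")
  if (!is.null(x$concentrations))
    cat("  concentrations (mM):",
        paste(sprintf("%s = %.4g", names(x$concentrations),
                      x$concentrations), collapse = ", "), "\n")
  invisible(x)
}

#' Convert fitted component scales to concentrations
#'
#' Each reference spectrum is the measured (or rendered) spectrum of the
#' pure component at a known concentration, so a fitted coefficient maps to
#' mM through a per-component slope: `concentration = coefficient * slope`,
#' where the slope is the concentration the reference corresponds to at unit
#' coefficient.
#'
#' @param coefficients named non-negative scales from [fit_components()].
#' @param calibrations named list/vector, component -> mM per unit
#'   coefficient.
#' @return Named numeric vector of concentrations (mM, >= 0).
#' @export
concentration_from_coefficients <- function(coefficients, calibrations) {
  calibrations <- unlist(calibrations)
  missing <- setdiff(names(coefficients), names(calibrations))
  if (length(missing))
    stop("no calibration for component(s): ", paste(missing, collapse = ", "))
  stats::setNames(
    as.numeric(coefficients) * as.numeric(calibrations[names(coefficients)]),
    names(coefficients))
}
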