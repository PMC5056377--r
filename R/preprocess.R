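#' Fractional subtraction of a reference spectrum
#'
#' Removes a pure-component contribution (water vapour in the optical path,
#' liquid water for samples in aqueous media) by scaling the reference with
#' a fitted factor and subtracting it. The factor minimises the squared
#' residual over `fit_window` and has the closed form
#' `sum(sample * ref) / sum(ref^2)` on the window; the corrected spectrum is
#' returned on the full common grid.
#'
#' @param sample an [ir_spectrum()].
#' @param reference the pure-component [ir_spectrum()]; resampled onto the
#'   sample grid if the grids differ (its coverage must allow it).
#' @param fit_window cm-1 interval `c(hi, lo)` over which the factor is
#'   estimated. Defaults: water vapour is usually fitted on 1900-1700 cm-1,
#'   liquid water on 3900-3100 cm-1 (see [subtract_water()]).
#' @param detrend_order `NULL` (default) for the pure projection above; an
#'   integer >= 0 to co-fit a free polynomial of that order on the window,
#'   so that smooth interferents (baseline drift, tails of broad
#'   neighbouring bands) do not leak into the factor. Only the scaled
#'   reference is subtracted either way.
#' @return A `subtraction_result` list: `corrected` spectrum, `factor`,
#'   `fit_window`, `residual_rms` (over the window).
#' @export
fractional_subtract <- function(sample, reference,
                                fit_window = c(1900, 1700),
                                detrend_order = NULL) {
  stopifnot(is_ir_spectrum(sample), is_ir_spectrum(reference))
  if (!same_grid(sample, reference)) {
    cover <- range(reference$wavenumbers)
    srange <- range(sample$wavenumbers)
    if (srange[1] < cover[1] - 1e-9 || srange[2] > cover[2] + 1e-9)
      stop(sprintf(
        "reference coverage [%.6g, %.6g] cm-1 does not span the sample grid [%.6g, %.6g] cm-1",
        cover[1], cover[2], srange[1], srange[2]))
    reference <- resample_to_grid(reference, sample$wavenumbers)
  }
  idx <- window_indices(sample$wavenumbers, fit_window)
  r <- reference$absorbance[idx]
  s <- sample$absorbance[idx]
  denom <- sum(r * r)
  if (denom <= 0)
    stop(sprintf(
      "reference has zero norm on the fit window [%.6g, %.6g] cm-1; cannot estimate a subtraction factor",
      max(fit_window), min(fit_window)))
  if (is.null(detrend_order)) {
    factor <- sum(s * r) / denom
    resid <- s - factor * r
  } else {
    u <- seq(-1, 1, length.out = length(idx))
    X <- cbind(r, outer(u, 0:detrend_order, `^`))
    beta <- stats::lm.fit(X, s)$coefficients
    factor <- unname(beta[1L])
    resid <- s - as.vector(X %*% beta)
  }
  corrected <- ir_spectrum(
    sample$wavenumbers,
    sample$absorbance - factor * reference$absorbance,
    meta = sample$meta)
  structure(list(corrected = corrected, factor = factor,
                 fit_window = sort(fit_window, decreasing = TRUE),
                 residual_rms = sqrt(mean(resid^2))),
            class = "subtraction_result")
}

#' @export
print.subtraction_result <- function(x, ...) {
  cat(sprintf(
    "<subtraction_result> factor %.6g on [%.6g, %.6g] cm-1, residual rms %.3g\n",
    x$factor, x$fit_window[1], x$fit_window[2], x$residual_rms))
  invisible(x)
}

#' Remove water vapour and liquid water from a spectrum
#'
#' Remove water vapour and liquid water in one step
#'
#' Estimates the water-vapour and liquid-water subtraction factors jointly
#' by least squares on the union of the two fit windows, co-fitting a free
#' polynomial (order `detrend_order`) so baseline drift does not leak into
#' either factor. The joint fit matters because the broad liquid-water band
#' tails across the vapour window: fitting the vapour comb alone there
#' would see that tail as signal, while in the joint design the water
#' reference explains its own tail. With a single reference requested the
#' fit reduces to [fractional_subtract()] with the same `detrend_order`.
#'
#' @param sample an [ir_spectrum()].
#' @param references a [reference_set()] holding `water_vapour` and/or
#'   `liquid_water` on the sample grid.
#' @param vapour_window,water_window fit windows, cm-1 (vapour lines strong
#'   and urine-film features weak on 1900-1700; the water OH stretch
#'   dominates 3900-3100).
#' @param vapour,water logical switches for each reference.
#' @param detrend_order polynomial order co-fitted with the factors.
#' @return List: `corrected` spectrum, `vapour_factor`, `water_factor`
#'   (NA for a reference not requested).
#' @export
subtract_water <- function(sample, references,
                           vapour_window = c(1900, 1700),
                           water_window = c(3900, 3100),
                           vapour = TRUE, water = TRUE,
                           detrend_order = 2) {
  stopifnot(is_ir_spectrum(sample), inherits(references, "reference_set"))
  if (!vapour && !water)
    return(list(corrected = sample, vapour_factor = NA_real_,
                water_factor = NA_real_))
  if (!same_grid(sample, list(wavenumbers = references$grid)))
    stop("sample and reference set must share one grid; resample first")
  idx <- integer(0); cols <- list()
  if (vapour) idx <- c(idx, window_indices(sample$wavenumbers, vapour_window))
  if (water) idx <- c(idx, window_indices(sample$wavenumbers, water_window))
  idx <- sort(unique(idx))
  if (vapour) cols$water_vapour <-
      references$components$water_vapour$absorbance[idx]
  if (water) cols$liquid_water <-
      references$components$liquid_water$absorbance[idx]
  for (nm in names(cols)) if (sum(cols[[nm]]^2) <= 0)
    stop("reference '", nm, "' has zero norm on its fit window")
  u <- (sample$wavenumbers[idx] - 750) / 3250 # global baseline coordinate
  X <- cbind(do.call(cbind, cols), outer(u, 0:detrend_order, `^`))
  beta <- unname(stats::lm.fit(X, sample$absorbance[idx])$coefficients)
  vf <- if (vapour) beta[1L] else NA_real_
  wf <- if (water) beta[1L + as.integer(vapour)] else NA_real_
  y <- sample$absorbance
  if (vapour) y <- y - vf * references$components$water_vapour$absorbance
  if (water) y <- y - wf * references$components$liquid_water$absorbance
  list(corrected = ir_spectrum(sample$wavenumbers, y, meta = sample$meta),
       vapour_factor = vf, water_factor = wf)
}

#' Savitzky-Golay second derivative of a spectrum
#'
#' Smoothed second derivative with respect to the grid index (the customary
#' band-sharpening transform; smooth baselines up to the polynomial order
#' are annihilated, affine trends exactly). The filter fits a polynomial of
#' `polyorder` in a moving window of `window_points` points and evaluates
#' its second derivative; endpoints are handled by the standard asymmetric
#' Savitzky-Golay startup filters.
#'
#' @param spectrum an [ir_spectrum()].
#' @param window_points odd window length in points (> `polyorder`),
#'   default 9.
#' @param polyorder polynomial order >= 2, default 3.
#' @return A `derivative_spectrum` list: `wavenumbers`, `d2`, `params`,
#'   `meta`.
#' @export
second_derivative <- function(spectrum, window_points = 9, polyorder = 3) {
  stopifnot(is_ir_spectrum(spectrum))
  if (window_points %% 2 != 1)
    stop("Savitzky-Golay window length must be odd, got ", window_points)
  if (polyorder < 2)
    stop("polyorder must be >= 2 to carry a second derivative")
  if (window_points <= polyorder)
    stop("window length (", window_points,
         ") must exceed the polynomial order (", polyorder, ")")
  n <- length(spectrum$wavenumbers)
  if (n < window_points)
    stop("spectrum length ", n, " shorter than the filter window ",
         window_points)
  d2 <- signal::sgolayfilt(spectrum$absorbance, p = polyorder,
                           n = window_points, m = 2, ts = 1)
  structure(list(wavenumbers = spectrum$wavenumbers, d2 = d2,
                 params = list(window_points = window_points,
                               polyorder = polyorder,
                               convention = "d2 w.r.t. grid index"),
                 meta = spectrum$meta),
            class = "derivative_spectrum")
}

#' @export
print.derivative_spectrum <- function(x, ...) {
  cat(sprintf(
    "<derivative_spectrum> %d points, SG window %d / order %d, d2 range [%.3g, %.3g]\n",
    length(x$wavenumbers), x$params$window_points, x$params$polyorder,
    min(x$d2), max(x$d2)))
  invisible(x)
}

#' Two-point second-derivative band response
#'
#' The cystine quantitation signal: the difference in second-derivative
#' intensities between two wavenumbers, by default 1296 minus 1280 cm-1.
#' Wavenumbers are looked up on the nearest grid point within +/-1 cm-1
#' (ties toward the higher wavenumber). The raw convention is
#' `d2(wn_a) - d2(wn_b)`; for an absorbance band peaked at `wn_a` this
#' difference is negative, so the calibration/quantitation pipeline uses
#' `invert = TRUE`, the band-sharpened (negated) second derivative, which
#' grows positively with concentration. Either way the response is linear in
#' concentration and immune to baselines that are affine across the filter
#' window.
#'
#' @param d2 a `derivative_spectrum` from [second_derivative()].
#' @param wn_a,wn_b wavenumbers, cm-1 (defaults 1296 and 1280).
#' @param invert if `TRUE`, return `d2(wn_b) - d2(wn_a)` (positive for a
#'   band at `wn_a`).
#' @param tol lookup tolerance, cm-1.
#' @return Scalar response (second-derivative intensity units).
#' @export
band_response <- function(d2, wn_a = 1296, wn_b = 1280, invert = FALSE,
                          tol = 1) {
  stopifnot(inherits(d2, "derivative_spectrum"))
  ia <- wn_index(d2$wavenumbers, wn_a, tol = tol)
  ib <- wn_index(d2$wavenumbers, wn_b, tol = tol)
  r <- d2$d2[ia] - d2$d2[ib]
  if (invert) -r else r
}

#' Second-derivative cystine response of an absorbance spectrum
#'
#' Pipeline shorthand: Savitzky-Golay second derivative followed by the
#' inverted 1296 minus 1280 cm-1 band response, which is positive and
#' proportional to the cystine film concentration.
#'
#' @param spectrum an [ir_spectrum()] of a dried film.
#' @param window_points,polyorder Savitzky-Golay parameters.
#' @return Scalar response.
#' @export
cystine_response <- function(spectrum, window_points = 9, polyorder = 3) {
  band_response(second_derivative(spectrum, window_points, polyorder),
                wn_a = 1296, wn_b = 1280, invert = TRUE)
}
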