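#' Construct a mid-infrared absorbance spectrum
#'
#' `ir_spectrum` is the basic currency of the package: a strictly monotonic
#' wavenumber grid (stored descending, high to low cm-1, the usual FTIR
#' display convention) with one absorbance value per grid point and a
#' free-form metadata list (resolution, scans, sample id, ...).
#'
#' Ascending input is accepted and silently reversed; a note is recorded in
#' `meta$reversed_on_input` so provenance is not lost.
#'
#' @param wavenumbers numeric vector of wavenumbers in cm-1, strictly
#'   monotonic, length >= 2.
#' @param absorbance numeric vector of absorbance values (dimensionless),
#'   same length, all finite.
#' @param meta named list of free-form metadata.
#' @return An object of class `ir_spectrum` with elements `wavenumbers`
#'   (descending), `absorbance` and `meta`.
#' @examples
#' s <- ir_spectrum(c(1300, 1298, 1296), c(0.1, 0.2, 0.3))
#' s$wavenumbers
#' @export
ir_spectrum <- function(wavenumbers, absorbance, meta = list()) {
  wavenumbers <- as.numeric(wavenumbers)
  absorbance <- as.numeric(absorbance)
  if (length(wavenumbers) < 2L)
    stop("a spectrum needs at least 2 points, got ", length(wavenumbers))
  if (length(wavenumbers) != length(absorbance))
    stop("wavenumbers (", length(wavenumbers), ") and absorbance (",
         length(absorbance), ") differ in length")
  if (anyNA(wavenumbers) || any(!is.finite(wavenumbers)))
    stop("wavenumbers contain NA or non-finite values")
  d <- diff(wavenumbers)
  if (any(d == 0))
    stop("wavenumber grid is not strictly monotonic (duplicated wavenumber near ",
         format(wavenumbers[which(d == 0)[1L]]), " cm-1)")
  if (!(all(d > 0) || all(d < 0)))
    stop("wavenumber grid is not strictly monotonic")
  if (all(d > 0)) { # ascending input: flip to the descending house convention
    wavenumbers <- rev(wavenumbers)
    absorbance <- rev(absorbance)
    meta$reversed_on_input <- TRUE
  }
  if (anyNA(absorbance) || any(!is.finite(absorbance)))
    stop("absorbance contains NA or non-finite values")
  structure(list(wavenumbers = wavenumbers, absorbance = absorbance,
                 meta = meta),
            class = "ir_spectrum")
}

#' @export
print.ir_spectrum <- function(x, ...) {
  cat(sprintf("<ir_spectrum> %d points, %.6g to %.6g cm-1\n",
              length(x$wavenumbers), x$wavenumbers[1L],
              x$wavenumbers[length(x$wavenumbers)]))
  cat(sprintf("  absorbance range [%.4g, %.4g]\n",
              min(x$absorbance), max(x$absorbance)))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.ir_spectrum <- function(x) length(x$wavenumbers)

is_ir_spectrum <- function(x) inherits(x, "ir_spectrum")

#' Default working wavenumber grid
#'
#' The default analysis grid spans 4000 to 750 cm-1 with 2 cm-1 point
#' spacing, descending. Spectra acquired at 4 cm-1 optical resolution are
#' typically digitised at about half that interval, and 2 cm-1 spacing
#' places the analysis wavenumbers 1296 and 1280 cm-1 exactly on grid
#' points.
#'
#' @param from,to grid limits in cm-1 (from > to).
#' @param by point spacing in cm-1 (positive).
#' @return Descending numeric wavenumber vector.
#' @export
default_grid <- function(from = 4000, to = 750, by = 2) {
  if (by <= 0) stop("grid spacing must be positive")
  if (from <= to) stop("'from' must exceed 'to' for a descending grid")
  seq(from, to, by = -by)
}

#' Locate the grid point nearest a target wavenumber
#'
#' Band positions are quoted with an accuracy of about +/-1 cm-1, so lookups
#' accept the nearest grid point within `tol` cm-1; ties are broken toward
#' the higher wavenumber. Used by [band_response()] and window cropping.
#'
#' @param grid descending wavenumber vector (or an `ir_spectrum`).
#' @param wn target wavenumber, cm-1.
#' @param tol maximum |grid - wn| accepted, cm-1 (default 1).
#' @return Integer index into `grid`.
#' @export
wn_index <- function(grid, wn, tol = 1) {
  if (is_ir_spectrum(grid)) grid <- grid$wavenumbers
  dist <- abs(grid - wn)
  i <- which(dist == min(dist))[1L] # descending grid: first hit = higher wn
  if (dist[i] > tol + 1e-9)
    stop(sprintf(
      "wavenumber %.6g cm-1 not on the grid within %.3g cm-1 (nearest point %.6g)",
      wn, tol, grid[i]))
  i
}

# Indices covering an inclusive window [hi, lo] cm-1, endpoints mapped to the
# nearest grid points (ties toward higher wavenumber). Errors if the window
# is not inside the grid's coverage.
window_indices <- function(grid, window) {
  if (is_ir_spectrum(grid)) grid <- grid$wavenumbers
  hi <- max(window); lo <- min(window)
  spacing <- if (length(grid) > 1) max(abs(diff(grid))) else Inf
  if (hi > grid[1L] + spacing / 2 || lo < grid[length(grid)] - spacing / 2)
    stop(sprintf(
      "window [%.6g, %.6g] cm-1 exceeds spectrum coverage [%.6g, %.6g] cm-1",
      hi, lo, grid[length(grid)], grid[1L]))
  i_hi <- wn_index(grid, hi, tol = spacing)
  i_lo <- wn_index(grid, lo, tol = spacing)
  seq(i_hi, i_lo)
}

#' Resample a spectrum onto a new wavenumber grid
#'
#' Linear interpolation; never extrapolates. The target grid must lie within
#' the spectrum's coverage. Exact on piecewise-linear signals and the
#' identity on the spectrum's own grid.
#'
#' @param spectrum an [ir_spectrum()].
#' @param grid target wavenumber vector (any monotonic order; output follows
#'   the descending house convention).
#' @return An `ir_spectrum` on `grid`.
#' @export
resample_to_grid <- function(spectrum, grid) {
  stopifnot(is_ir_spectrum(spectrum))
  grid <- as.numeric(grid)
  lo <- min(spectrum$wavenumbers); hi <- max(spectrum$wavenumbers)
  bad <- grid < lo - 1e-12 | grid > hi + 1e-12
  if (any(bad))
    stop(sprintf(
      "requested grid points [%.6g, %.6g] cm-1 outside spectrum coverage [%.6g, %.6g] cm-1 (no extrapolation)",
      min(grid[bad]), max(grid[bad]), lo, hi))
  # approx needs ascending x
  y <- stats::approx(rev(spectrum$wavenumbers), rev(spectrum$absorbance),
                     xout = grid, rule = 1)$y
  ir_spectrum(grid, y, meta = spectrum$meta)
}

# Arithmetic helpers on a shared grid -----------------------------------

same_grid <- function(a, b, tol = 1e-9) {
  length(a$wavenumbers) == length(b$wavenumbers) &&
    all(abs(a$wavenumbers - b$wavenumbers) <= tol)
}

# b brought onto a's grid (resampling if needed), then a + w*b
spectrum_axpy <- function(a, b, w = 1) {
  if (!same_grid(a, b)) b <- resample_to_grid(b, a$wavenumbers)
  ir_spectrum(a$wavenumbers, a$absorbance + w * b$absorbance, meta = a$meta)
}
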