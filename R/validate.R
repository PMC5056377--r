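#' Pearson product-moment correlation between two methods
#'
#' Thin, checked wrapper for paired method values: requires at least three
#' pairs and non-zero variance in both methods, then returns the standard
#' product-moment coefficient.
#'
#' @param a,b paired numeric vectors.
#' @return r in \[-1, 1\].
#' @export
pearson_r <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("methods have different numbers of values")
  if (length(a) < 3L) stop("need at least 3 pairs for a correlation")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("correlation undefined: one method has zero variance")
  stats::cor(a, b)
}

#' Bland-Altman agreement analysis
#'
#' Mean bias of the paired differences and 95% limits of agreement at
#' bias +/- 1.96 sd (n - 1 sd). The difference orientation is
#' `method_a - method_b` and is recorded; by the package convention the
#' clinical comparator is passed as `method_a` so that a comparator reading
#' high yields a positive bias. Pairs falling outside the limits are listed
#' as outliers. The per-pair mean `(a + b) / 2` is carried as the x
#' coordinate for plotting.
#'
#' @param method_a,method_b paired numeric vectors (>= 2 pairs).
#' @param ids optional sample identifiers.
#' @param halfwidth optional per-pair half-widths (censoring intervals)
#'   carried into the plot export.
#' @return A `method_comparison` list: `pairs` data.frame (id, a, b, mean,
#'   difference, halfwidth), `pearson_r` (NA with < 3 pairs or zero
#'   variance), `mean_bias`, `sd_diff`, `loa_low`, `loa_high`, `outliers`,
#'   `orientation`.
#' @export
bland_altman <- function(method_a, method_b, ids = NULL, halfwidth = NULL) {
  a <- as.numeric(method_a); b <- as.numeric(method_b)
  if (length(a) != length(b)) stop("methods have different numbers of values")
  if (length(a) < 2L) stop("need at least 2 pairs for a Bland-Altman analysis")
  if (is.null(ids)) ids <- as.character(seq_along(a))
  if (is.null(halfwidth)) halfwidth <- rep(0, length(a))
  d <- a - b
  bias <- mean(d)
  sd_d <- stats::sd(d) # n - 1 denominator
  loa_low <- bias - 1.96 * sd_d
  loa_high <- bias + 1.96 * sd_d
  out <- ids[d < loa_low | d > loa_high]
  r <- if (length(a) >= 3L && stats::sd(a) > 0 && stats::sd(b) > 0)
    stats::cor(a, b) else NA_real_
  structure(list(
    pairs = data.frame(sample_id = ids, method_a = a, method_b = b,
                       mean = (a + b) / 2, difference = d,
                       halfwidth = halfwidth, stringsAsFactors = FALSE),
    pearson_r = r, mean_bias = bias, sd_diff = sd_d,
    loa_low = loa_low, loa_high = loa_high, outliers = out,
    orientation = "method_a - method_b"),
    class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf(
    "<method_comparison> n = %d, bias %.4g, 95%% limits [%.4g, %.4g], r = %.3f\n",
    nrow(x$pairs), x$mean_bias, x$loa_low, x$loa_high, x$pearson_r))
  if (length(x$outliers))
    cat("  outliers:", paste(x$outliers, collapse = ", "), "\n")
  invisible(x)
}

#' Compare FTIR insoluble cystine with a total-cystine comparator
#'
#' The spectroscopic method measures only the insoluble fraction while the
#' clinical comparator (ion-exchange chromatography) reports total cystine.
#' For comparison, detected samples have the solubility-limit offset
#' (default 1 mM) added to their insoluble value; samples with no detectable
#' insoluble cystine must have had < 1 mM total and are entered as censored
#' 0.5 +/- 0.5 mM points (optionally excluded). The comparison is oriented
#' comparator - FTIR.
#'
#' @param ftir data.frame with columns `sample_id`, `insoluble_mM`,
#'   `detected` (as produced by [quant_table()]).
#' @param comparator data.frame with columns `sample_id` and `total_mM`.
#' @param offset solubility offset, mM.
#' @param include_censored include undetected samples as 0.5 mM points
#'   (default TRUE); `FALSE` drops them from the statistics.
#' @return A `method_comparison` (see [bland_altman()]); censored pairs
#'   carry `halfwidth` 0.5.
#' @export
comparison_with_offset <- function(ftir, comparator, offset = 1.0,
                                   include_censored = TRUE) {
  need <- setdiff(c("sample_id", "insoluble_mM", "detected"), names(ftir))
  if (length(need)) stop("ftir table lacks column(s): ",
                         paste(need, collapse = ", "))
  if (!all(c("sample_id", "total_mM") %in% names(comparator)))
    stop("comparator table needs columns sample_id and total_mM")
  unmatched <- c(setdiff(ftir$sample_id, comparator$sample_id),
                 setdiff(comparator$sample_id, ftir$sample_id))
  if (length(unmatched))
    stop("unpaired sample id(s): ", paste(unique(unmatched), collapse = ", "))
  m <- merge(ftir, comparator, by = "sample_id", sort = TRUE)
  ftir_total <- ifelse(m$detected, m$insoluble_mM + offset, 0.5)
  hw <- ifelse(m$detected, 0, 0.5)
  if (!include_censored) {
    keep <- m$detected
    m <- m[keep, , drop = FALSE]
    ftir_total <- ftir_total[keep]; hw <- hw[keep]
  }
  if (nrow(m) < 2L)
    stop("fewer than 2 comparable pairs after filtering")
  bland_altman(m$total_mM, ftir_total, ids = m$sample_id, halfwidth = hw)
}

#' Bland-Altman and scatter plots for a method comparison
#'
#' Base-graphics rendering of the agreement analysis: differences against
#' per-pair means with the bias (dashed) and 95% limits (dotted), or the
#' paired scatter with the identity line. Censored points draw their
#' half-width as error bars.
#'
#' @param x a `method_comparison`.
#' @param which `"bland_altman"` or `"scatter"`.
#' @param xlab,ylab,main usual graphics labels.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.method_comparison <- function(x, which = c("bland_altman", "scatter"),
                                   xlab = NULL, ylab = NULL, main = NULL,
                                   ...) {
  which <- match.arg(which)
  p <- x$pairs
  if (which == "bland_altman") {
    graphics::plot(p$mean, p$difference,
                   xlab = xlab %||% "mean of methods",
                   ylab = ylab %||% paste0("difference (", x$orientation, ")"),
                   main = main %||% "Bland-Altman", pch = 19, ...)
    graphics::abline(h = x$mean_bias, lty = 2)
    graphics::abline(h = c(x$loa_low, x$loa_high), lty = 3)
  } else {
    graphics::plot(p$method_b, p$method_a,
                   xlab = xlab %||% "method B", ylab = ylab %||% "method A",
                   main = main %||% "method comparison", pch = 19, ...)
    graphics::abline(0, 1, lty = 2)
    cen <- p$halfwidth > 0
    if (any(cen))
      graphics::arrows(p$method_b[cen] - p$halfwidth[cen], p$method_a[cen],
                       p$method_b[cen] + p$halfwidth[cen], p$method_a[cen],
                       angle = 90, code = 3, length = 0.03)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
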