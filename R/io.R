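#' Read a spectrum from CSV or JCAMP-DX
#'
#' CSV files are two numeric columns (wavenumber in cm-1, absorbance) with an
#' optional header row and optional `#`-prefixed metadata comments of the
#' form `# key: value`. JCAMP-DX files must be single-block
#' `##XYDATA=(X++(Y..Y))` tables in AFFN or SQZ/DIF/DUP compressed form.
#'
#' @param path file path.
#' @param format `"auto"` (by extension: `.jdx`/`.dx`/`.jcamp` are JCAMP,
#'   anything else CSV), `"csv"` or `"jcamp"`.
#' @return A validated [ir_spectrum()] (descending grid; ascending files are
#'   reversed with `meta$reversed_on_input = TRUE`).
#' @seealso [write_spectrum()]
#' @export
read_spectrum <- function(path, format = c("auto", "csv", "jcamp")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("jdx", "dx", "jcamp")) "jcamp" else "csv"
  }
  switch(format, csv = read_spectrum_csv(path), jcamp = read_spectrum_jcamp(path))
}

#' Write a spectrum to CSV or JCAMP-DX
#'
#' Values are written with full double precision so that
#' `read_spectrum(write_spectrum(s))` round-trips to better than 1e-9
#' relative error. CSV metadata is carried in `# key: value` comment lines;
#' JCAMP output is an AFFN `##XYDATA=(X++(Y..Y))` table.
#'
#' @param spectrum an [ir_spectrum()].
#' @param path destination path.
#' @param format `"csv"` or `"jcamp"`.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path, format = c("csv", "jcamp")) {
  format <- match.arg(format)
  stopifnot(is_ir_spectrum(spectrum))
  if (length(spectrum$wavenumbers) < 2L)
    stop("refusing to write a degenerate spectrum")
  lines <- switch(format,
    csv = format_spectrum_csv(spectrum),
    jcamp = format_spectrum_jcamp(spectrum))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) e)
  if (!isTRUE(ok)) stop("could not write spectrum to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

# CSV dialect -----------------------------------------------------------

num17 <- function(x) sprintf("%.17g", x)

format_spectrum_csv <- function(s) {
  meta <- s$meta
  hdr <- character(0)
  if (length(meta)) {
    vals <- vapply(meta, function(v) paste(format(v), collapse = " "), "")
    hdr <- sprintf("# %s: %s", names(meta), vals)
  }
  c(hdr, "wavenumber_cm-1,absorbance",
    paste(num17(s$wavenumbers), num17(s$absorbance), sep = ","))
}

read_spectrum_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  is_comment <- grepl("^\\s*#", lines)
  meta <- list()
  for (cm in lines[is_comment]) {
    m <- regmatches(cm, regexec("^\\s*#\\s*([^:]+?)\\s*:\\s*(.*)$", cm))[[1L]]
    if (length(m) == 3L) meta[[m[2L]]] <- m[3L]
  }
  body <- lines[!is_comment & nzchar(trimws(lines))]
  if (!length(body)) stop("no data rows in ", path)
  # optional single header row
  first_fields <- strsplit(body[1L], ",")[[1L]]
  if (suppressWarnings(anyNA(as.numeric(first_fields[1:2])))) body <- body[-1L]
  if (!length(body)) stop("no numeric data rows in ", path)
  parts <- strsplit(body, ",")
  bad <- which(lengths(parts) < 2L)
  if (length(bad))
    stop("unparseable CSV row (need two columns) at data line ", bad[1L],
         " of ", path)
  wn <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1L)))
  ab <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  if (anyNA(wn) || anyNA(ab)) {
    bad <- which(is.na(wn) | is.na(ab))[1L]
    stop("non-numeric value at data line ", bad, " of ", path)
  }
  meta$reversed_on_input <- NULL
  ir_spectrum(wn, ab, meta = meta)
}

# JCAMP-DX --------------------------------------------------------------

format_spectrum_jcamp <- function(s) {
  n <- length(s$wavenumbers)
  title <- if (!is.null(s$meta$title)) s$meta$title else "ir spectrum"
  head <- c(
    sprintf("##TITLE=%s", title),
    "##JCAMP-DX=4.24",
    "##DATA TYPE=INFRARED SPECTRUM",
    "##XUNITS=1/CM",
    "##YUNITS=ABSORBANCE",
    sprintf("##FIRSTX=%s", num17(s$wavenumbers[1L])),
    sprintf("##LASTX=%s", num17(s$wavenumbers[n])),
    "##XFACTOR=1",
    "##YFACTOR=1",
    sprintf("##NPOINTS=%d", n),
    "##XYDATA=(X++(Y..Y))")
  per_line <- 4L
  starts <- seq(1L, n, by = per_line)
  body <- vapply(starts, function(i) {
    j <- min(i + per_line - 1L, n)
    paste(c(num17(s$wavenumbers[i]), num17(s$absorbance[i:j])), collapse = " ")
  }, "")
  c(head, body, "##END=")
}

# ASDF (SQZ/DIF/DUP) digit tables
.sqz_chars <- c("@", LETTERS[1:9], letters[1:9])
.sqz_vals  <- c(0, 1:9, -(1:9))
.dif_chars <- c("%", LETTERS[10:18], letters[10:18])
.dif_vals  <- c(0, 1:9, -(1:9))
.dup_chars <- c(LETTERS[19:26], "s")
.dup_vals  <- 1:9

# Decode one XYDATA line body (after the leading X value) into y values.
# state: list(prev = last y of previous line or NA). Returns list(y, in_dif).
decode_asdf_line <- function(txt, prev) {
  toks <- regmatches(txt, gregexpr(
    paste0("[@A-Ia-i%J-Rj-r][0-9]*(?:\\.[0-9]+)?", # SQZ/DIF, digit replaced
           "|[S-Zs][0-9]*",                        # DUP count
           "|[+-]?[0-9]*\\.?[0-9]+(?:[eE][+-]?[0-9]+)?"), # plain AFFN
    txt))[[1L]]
  y <- numeric(0)
  last_mode <- "affn"
  for (tk in toks) {
    c1 <- substr(tk, 1L, 1L)
    rest <- substring(tk, 2L)
    if (c1 %in% .dup_chars) {
      count_digits <- paste0(.dup_vals[match(c1, .dup_chars)], rest)
      count <- as.numeric(count_digits)
      if (!length(y) && is.na(prev))
        stop("JCAMP DUP token with no preceding ordinate")
      if (last_mode == "dif") {
        # repeat the previous difference (count includes its first use)
        d <- y[length(y)] - if (length(y) >= 2) y[length(y) - 1L] else prev
        for (k in seq_len(count - 1L)) y <- c(y, y[length(y)] + d)
      } else {
        v <- if (length(y)) y[length(y)] else prev
        y <- c(y, rep(v, count - 1L))
      }
    } else if (c1 %in% .dif_chars) {
      d <- as.numeric(paste0(.dif_vals[match(c1, .dif_chars)], rest))
      base <- if (length(y)) y[length(y)] else prev
      if (is.na(base)) stop("JCAMP DIF token with no preceding ordinate")
      y <- c(y, base + d)
      last_mode <- "dif"
    } else if (c1 %in% .sqz_chars) {
      y <- c(y, as.numeric(paste0(.sqz_vals[match(c1, .sqz_chars)], rest)))
      last_mode <- "sqz"
    } else {
      y <- c(y, as.numeric(tk))
      last_mode <- "affn"
    }
  }
  y
}

read_spectrum_jcamp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (sum(grepl("^##TITLE=", lines)) > 1L || any(grepl("^##BLOCKS=", lines)))
    stop("multi-block JCAMP-DX files are not supported (", path,
         "): split the blocks first")
  grab <- function(key) {
    hit <- grep(paste0("^##", key, "="), lines, value = TRUE)
    if (!length(hit)) return(NA_character_)
    sub(paste0("^##", key, "=\\s*"), "", hit[1L])
  }
  xfactor <- as.numeric(grab("XFACTOR")); if (is.na(xfactor)) xfactor <- 1
  yfactor <- as.numeric(grab("YFACTOR")); if (is.na(yfactor)) yfactor <- 1
  npoints <- as.numeric(grab("NPOINTS"))
  ix <- grep("^##XYDATA=", lines)
  if (!length(ix)) stop("no ##XYDATA table in ", path)
  form <- sub("^##XYDATA=\\s*", "", lines[ix[1L]])
  if (!grepl("X\\+\\+\\(Y\\.\\.Y\\)", form))
    stop("unsupported XYDATA form '", form, "' in ", path,
         " (only (X++(Y..Y)) tables are read)")
  iend <- grep("^##", lines)
  iend <- iend[iend > ix[1L]]
  last <- if (length(iend)) iend[1L] - 1L else length(lines)
  body <- lines[(ix[1L] + 1L):last]
  body <- body[nzchar(trimws(body))]
  xs <- numeric(0); ys <- numeric(0)
  for (li in seq_along(body)) {
    ln <- trimws(body[li])
    m <- regexec("^([+-]?[0-9]*\\.?[0-9]+(?:[eE][+-]?[0-9]+)?)[ \t,]*(.*)$", ln)
    g <- regmatches(ln, m)[[1L]]
    if (length(g) < 3L)
      stop("unparseable XYDATA line ", li, " in ", path, ": '", ln, "'")
    x0 <- as.numeric(g[2L])
    prev <- if (length(ys)) ys[length(ys)] / yfactor else NA_real_
    yline <- decode_asdf_line(g[3L], prev)
    if (!length(yline))
      stop("XYDATA line ", li, " in ", path, " carries no ordinates")
    xs <- c(xs, x0) # only the line-start X is given; Y spacing implied
    ys <- c(ys, yline * yfactor)
  }
  n <- length(ys)
  if (!is.na(npoints) && npoints != n)
    stop("JCAMP NPOINTS=", npoints, " but ", n, " ordinates decoded in ", path)
  firstx <- as.numeric(grab("FIRSTX")) * xfactor
  lastx <- as.numeric(grab("LASTX")) * xfactor
  if (is.na(firstx)) firstx <- xs[1L] * xfactor
  if (is.na(lastx)) stop("##LASTX missing in ", path)
  wn <- seq(firstx, lastx, length.out = n)
  meta <- list()
  title <- grab("TITLE")
  if (!is.na(title) && nzchar(title)) meta$title <- title
  ir_spectrum(wn, ys, meta = meta)
}

# Reference sets --------------------------------------------------------

#' Bundle named component spectra on one shared grid
#'
#' A reference set holds the pure-component spectra used for fractional
#' subtraction and deconvolution. All components must share an identical
#' grid; components arriving on a different grid are resampled onto `grid`
#' (which defaults to the first component's grid). The quantitation pipeline
#' expects the names `urea`, `creatinine`, `liquid_water`, `water_vapour`
#' and `cystine`.
#'
#' @param components named list of [ir_spectrum()] objects.
#' @param grid shared wavenumber grid; default taken from the first component.
#' @return An object of class `reference_set` with `components` and `grid`.
#' @export
reference_set <- function(components, grid = NULL) {
  if (!length(components) || is.null(names(components)) ||
      any(!nzchar(names(components))))
    stop("components must be a non-empty named list of spectra")
  if (anyDuplicated(names(components)))
    stop("duplicate component names: ",
         paste(unique(names(components)[duplicated(names(components))]),
               collapse = ", "))
  stopifnot(all(vapply(components, is_ir_spectrum, TRUE)))
  if (is.null(grid)) grid <- components[[1L]]$wavenumbers
  grid <- as.numeric(grid)
  components <- lapply(components, function(s)
    if (length(s$wavenumbers) == length(grid) &&
        all(abs(s$wavenumbers - grid) < 1e-9)) s else resample_to_grid(s, grid))
  structure(list(components = components, grid = grid),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set> %d components on %d-point grid (%.6g to %.6g cm-1)\n",
              length(x$components), length(x$grid), x$grid[1L],
              x$grid[length(x$grid)]))
  cat("  ", paste(names(x$components), collapse = ", "), "\n")
  invisible(x)
}

#' Read / write a reference set as a directory of CSVs plus manifest
#'
#' The on-disk layout is one CSV per component plus `manifest.json` naming
#' the components, their files and the shared grid limits.
#'
#' @param refs a [reference_set()].
#' @param dir directory path (created if missing).
#' @return `write_reference_set()` returns `dir` invisibly;
#'   `read_reference_set()` returns a `reference_set`.
#' @export
write_reference_set <- function(refs, dir) {
  stopifnot(inherits(refs, "reference_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- sprintf("%s.csv", names(refs$components))
  for (i in seq_along(refs$components))
    write_spectrum(refs$components[[i]], file.path(dir, files[i]), "csv")
  manifest <- list(
    components = as.list(stats::setNames(files, names(refs$components))),
    grid = list(first = refs$grid[1L], last = refs$grid[length(refs$grid)],
                n = length(refs$grid)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_reference_set
#' @export
read_reference_set <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(mf)
  comps <- lapply(manifest$components, function(f)
    read_spectrum(file.path(dir, f), "csv"))
  grid <- seq(manifest$grid$first, manifest$grid$last,
              length.out = manifest$grid$n)
  reference_set(comps, grid = grid)
}
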