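#' Construct a Raman spectrum
#'
#' A `raman_spectrum` holds one measured (or simulated) Raman shift spectrum:
#' a strictly monotone wavenumber grid (cm^-1) with one intensity per grid
#' point, plus free-form provenance tags in `meta`. Internally wavenumbers
#' are always stored ascending (600 -> 1800); descending instrument exports
#' are reversed on construction so that range slicing never needs to care
#' about export order.
#'
#' @param wavenumbers numeric vector of Raman shifts in cm^-1, strictly
#'   monotone (ascending or descending), length >= 2.
#' @param intensities numeric vector of intensities (arbitrary units), same
#'   length as `wavenumbers`, finite.
#' @param meta named list of provenance tags (processing steps applied,
#'   source path, ...).
#' @return An object of class `raman_spectrum` with fields `wavenumbers`
#'   (ascending), `intensities`, `meta`.
#' @examples
#' s <- raman_spectrum(c(600, 601.2, 602.4), c(1, 2, 1.5))
#' s$wavenumbers
#' @export
raman_spectrum <- function(wavenumbers, intensities, meta = list()) {
  if (!is.numeric(wavenumbers) || !is.numeric(intensities))
    stop("wavenumbers and intensities must be numeric")
  n <- length(wavenumbers)
  if (n < 2L)
    stop("a spectrum needs at least 2 points, got ", n)
  if (length(intensities) != n)
    stop("length mismatch: ", n, " wavenumbers vs ",
         length(intensities), " intensities")
  if (anyNA(wavenumbers) || any(!is.finite(wavenumbers)))
    stop("non-finite wavenumbers")
  if (anyNA(intensities) || any(!is.finite(intensities)))
    stop("non-finite intensities")
  d <- diff(wavenumbers)
  if (all(d < 0)) {            # descending export: canonicalise
    wavenumbers <- rev(wavenumbers)
    intensities <- rev(intensities)
  } else if (!all(d > 0)) {
    stop("wavenumbers must be strictly monotone")
  }
  structure(list(wavenumbers = as.numeric(wavenumbers),
                 intensities = as.numeric(intensities),
                 meta = meta),
            class = "raman_spectrum")
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum: %d points, %.1f-%.1f cm^-1>\n",
              length(x$wavenumbers),
              min(x$wavenumbers), max(x$wavenumbers)))
  if (length(x$meta$steps))
    cat("  steps:", paste(unlist(x$meta$steps), collapse = " -> "), "\n")
  invisible(x)
}

#' @export
length.raman_spectrum <- function(x) length(x$wavenumbers)

is_spectrum <- function(x) inherits(x, "raman_spectrum")

#' Read a two-column spectrum table
#'
#' Parses a whitespace- or comma-delimited text table of
#' (wavenumber, intensity) rows. Lines starting with `#` and blank lines are
#' skipped. The grid must be strictly monotone; descending files are stored
#' ascending.
#'
#' @param path path to a `.txt`/`.csv` spectrum table.
#' @return A validated [raman_spectrum()]; `meta$source` records `path`.
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) < 2L)
    stop("fewer than 2 data rows in ", path)
  w <- numeric(length(keep)); y <- numeric(length(keep))
  for (i in seq_along(keep)) {
    ln <- keep[i]
    fields <- strsplit(trimws(lines[ln]), "[,;\t ]+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) < 2L || anyNA(vals[1:2]))
      stop("malformed row at line ", ln, " of ", path, ": '",
           lines[ln], "'")
    w[i] <- vals[1]; y[i] <- vals[2]
  }
  d <- diff(w)
  if (any(d == 0))
    stop("duplicated wavenumber at line ",
         keep[which(d == 0)[1] + 1L], " of ", path)
  if (!(all(d > 0) || all(d < 0)))
    stop("non-monotone wavenumber grid at line ",
         keep[which(sign(d) != sign(d[1]))[1] + 1L], " of ", path)
  raman_spectrum(w, y, meta = list(source = path))
}

#' Write a spectrum as a two-column table
#'
#' Writes wavenumber/intensity pairs at 12 significant digits so that a
#' read/write round trip reproduces the spectrum to well beyond float noise.
#'
#' @param spectrum a [raman_spectrum()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(is_spectrum(spectrum))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("# wavenumber_cm-1 intensity", con)
  writeLines(sprintf("%.12g %.12g",
                     spectrum$wavenumbers, spectrum$intensities), con)
  invisible(path)
}
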