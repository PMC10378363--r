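#' @title Dataset manifests and analysis databases
#' @description Helpers that group labelled site spectra into per-cell
#'   records and assemble the four analysis databases (site-averaged and
#'   per-site).
#' @name manifest
NULL

#' Class labels recognised by the pipeline
#' @export
CLASS_LABELS <- c("NFC", "NIH/3T3", "MBM-T")

#' Measurement sites recognised by the pipeline
#' @export
SITE_LABELS <- c("center", "cytoplasm", "membrane")

#' One cell's labelled site spectra
#'
#' @param cell_id opaque cell identifier.
#' @param class_label one of `r toString(CLASS_LABELS)`.
#' @param site_spectra named list mapping a subset of
#'   center/cytoplasm/membrane to [raman_spectrum()] objects; at least one
#'   site must be present.
#' @return A `cell_record` object.
#' @export
cell_record <- function(cell_id, class_label, site_spectra) {
  if (!class_label %in% CLASS_LABELS)
    stop("unknown class label '", class_label, "'")
  if (length(site_spectra) < 1L)
    stop("cell ", cell_id, ": at least one site spectrum required")
  bad <- setdiff(names(site_spectra), SITE_LABELS)
  if (length(bad))
    stop("cell ", cell_id, ": unknown site(s) ", toString(bad))
  if (anyDuplicated(names(site_spectra)))
    stop("cell ", cell_id, ": duplicated site")
  stopifnot(all(vapply(site_spectra, is_spectrum, logical(1))))
  structure(list(cell_id = as.character(cell_id),
                 class_label = class_label,
                 site_spectra = site_spectra),
            class = "cell_record")
}

#' Bundle cell records into a dataset manifest
#'
#' All spectra must share one wavenumber grid (the grid of the first
#' record's first spectrum). Cell ids must be unique.
#'
#' @param records list of [cell_record()] objects.
#' @param provenance free-form list (source paths, checksums, seed, ...).
#' @return A `dataset_manifest` with fields `records`, `grid`, `provenance`.
#' @export
dataset_manifest <- function(records, provenance = list()) {
  if (!length(records)) stop("empty manifest")
  ids <- vapply(records, function(r) r$cell_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicated cell_id: ", ids[anyDuplicated(ids)])
  grid <- records[[1]]$site_spectra[[1]]$wavenumbers
  for (r in records)
    for (s in r$site_spectra)
      if (length(s$wavenumbers) != length(grid) ||
          max(abs(s$wavenumbers - grid)) > 1e-9)
        stop("cell ", r$cell_id, ": spectrum grid differs from manifest grid")
  structure(list(records = records, grid = grid, provenance = provenance),
            class = "dataset_manifest")
}

#' @export
print.dataset_manifest <- function(x, ...) {
  labs <- vapply(x$records, function(r) r$class_label, character(1))
  nspec <- sum(vapply(x$records, function(r) length(r$site_spectra),
                      integer(1)))
  cat(sprintf("<dataset_manifest: %d cells, %d spectra, %d grid points>\n",
              length(x$records), nspec, length(x$grid)))
  print(table(labs))
  invisible(x)
}

#' Load a dataset manifest from a CSV table
#'
#' The manifest CSV has a header and columns `file,cell_id,class,site`.
#' Spectrum files are read with [read_spectrum()] and validated onto a
#' common grid: the first spectrum read defines the reference grid; a later
#' grid whose pointwise deviation is below a quarter of the median grid
#' spacing is snapped to it; a larger mismatch is linearly interpolated onto
#' the reference grid and flagged in the spectrum's `meta$resampled`.
#'
#' @param path manifest CSV path.
#' @param base_dir directory that spectrum `file` entries are relative to
#'   (default: the manifest's directory).
#' @return A [dataset_manifest()]; `provenance` records per-file md5
#'   checksums.
#' @export
load_manifest <- function(path, base_dir = dirname(path)) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         comment.char = "#", strip.white = TRUE)
  need <- c("file", "cell_id", "class", "site")
  if (!all(need %in% names(tab)))
    stop("manifest must have columns ", toString(need))
  bad_class <- setdiff(unique(tab$class), CLASS_LABELS)
  if (length(bad_class))
    stop("unknown class token(s): ", toString(bad_class))
  bad_site <- setdiff(unique(tab$site), SITE_LABELS)
  if (length(bad_site))
    stop("unknown site token(s): ", toString(bad_site))
  key <- paste(tab$cell_id, tab$site, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicate (cell_id, site) pair: ",
         gsub("\r", ", ", d, fixed = TRUE))
  }
  paths <- file.path(base_dir, tab$file)
  grid <- NULL
  spectra <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    s <- read_spectrum(paths[i])
    if (is.null(grid)) {
      grid <- s$wavenumbers
    } else {
      tol <- 0.25 * stats::median(diff(grid))
      if (length(s$wavenumbers) == length(grid) &&
          max(abs(s$wavenumbers - grid)) < tol) {
        s$wavenumbers <- grid          # snap float noise
      } else {
        if (min(s$wavenumbers) > min(grid) || max(s$wavenumbers) < max(grid))
          stop("spectrum ", tab$file[i],
               " does not span the manifest grid; cannot resample")
        yi <- stats::approx(s$wavenumbers, s$intensities, xout = grid)$y
        s <- raman_spectrum(grid, yi,
                            meta = c(s$meta, list(resampled = TRUE)))
      }
    }
    spectra[[i]] <- s
  }
  records <- lapply(split(seq_len(nrow(tab)), tab$cell_id), function(idx) {
    cl <- unique(tab$class[idx])
    if (length(cl) != 1L)
      stop("cell ", tab$cell_id[idx[1]], " listed with conflicting classes")
    ss <- spectra[idx]
    names(ss) <- tab$site[idx]
    cell_record(tab$cell_id[idx[1]], cl, ss)
  })
  dataset_manifest(unname(records),
                   provenance = list(manifest = path,
                                     checksums = tools::md5sum(paths)))
}

#' Write a manifest's spectra and index CSV to a directory
#'
#' Inverse of [load_manifest()]: one two-column text file per site spectrum
#' plus `manifest.csv`.
#'
#' @param manifest a [dataset_manifest()].
#' @param dir output directory (created if needed).
#' @return Path to the written `manifest.csv`, invisibly.
#' @export
write_manifest <- function(manifest, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (r in manifest$records)
    for (site in names(r$site_spectra)) {
      fn <- sprintf("%s_%s.txt", gsub("[^A-Za-z0-9_-]", "_", r$cell_id),
                    site)
      write_spectrum(r$site_spectra[[site]], file.path(dir, fn))
      rows[[length(rows) + 1L]] <-
        data.frame(file = fn, cell_id = r$cell_id,
                   class = r$class_label, site = site)
    }
  idx <- do.call(rbind, rows)
  out <- file.path(dir, "manifest.csv")
  utils::write.csv(idx, out, row.names = FALSE, quote = TRUE)
  invisible(out)
}

DATABASE_SITE_RULE <- c(I = "average", II = "center",
                        III = "cytoplasm", IV = "membrane")

#' Assemble an analysis database from a manifest
#'
#' Database I uses, per cell, the pointwise mean of the available site
#' spectra (1-3 sites); databases II/III/IV use the single center, cytoplasm
#' or membrane spectrum and omit cells lacking that site. The result carries
#' one characteristic vector per cell.
#'
#' @param manifest a [dataset_manifest()].
#' @param database_id `"I"`, `"II"`, `"III"` or `"IV"`.
#' @return A `raman_database`: list with `database_id`, `site_rule`,
#'   `cell_id` (character), `class_label` (character), `grid`, and
#'   `spectra`, a cells x wavenumbers intensity matrix.
#' @export
build_database <- function(manifest, database_id = c("I", "II", "III", "IV")) {
  database_id <- match.arg(database_id)
  rule <- DATABASE_SITE_RULE[[database_id]]
  keep <- list()
  for (r in manifest$records) {
    if (rule == "average") {
      mat <- do.call(rbind, lapply(r$site_spectra,
                                   function(s) s$intensities))
      keep[[length(keep) + 1L]] <-
        list(id = r$cell_id, cl = r$class_label, y = colMeans(mat))
    } else if (rule %in% names(r$site_spectra)) {
      keep[[length(keep) + 1L]] <-
        list(id = r$cell_id, cl = r$class_label,
             y = r$site_spectra[[rule]]$intensities)
    }
  }
  if (!length(keep))
    stop("database ", database_id, ": no cell has a '", rule, "' spectrum")
  structure(list(
    database_id = database_id,
    site_rule = rule,
    cell_id = vapply(keep, `[[`, character(1), "id"),
    class_label = vapply(keep, `[[`, character(1), "cl"),
    grid = manifest$grid,
    spectra = do.call(rbind, lapply(keep, `[[`, "y"))
  ), class = "raman_database")
}

#' @export
print.raman_database <- function(x, ...) {
  cat(sprintf("<raman_database %s (%s): %d cells x %d points>\n",
              x$database_id, x$site_rule, nrow(x$spectra),
              ncol(x$spectra)))
  print(table(x$class_label))
  invisible(x)
}

#' Restrict a database to a wavenumber range
#'
#' Keeps grid columns with `low <= wavenumber <= high` (closed interval).
#' Used by the sub-range analysis; preprocessing is not redone.
#'
#' @param db a `raman_database`.
#' @param low,high range bounds in cm^-1.
#' @return A `raman_database` on the restricted grid.
#' @export
cut_database <- function(db, low, high) {
  keep <- db$grid >= low & db$grid <= high
  if (!any(keep)) stop("no grid points in [", low, ", ", high, "]")
  db$grid <- db$grid[keep]
  db$spectra <- db$spectra[, keep, drop = FALSE]
  db
}
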