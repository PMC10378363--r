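#' Catalogue of fibroblast Raman bands
#'
#' The 35 prominent bands of a fibroblast cell spectrum with their
#' literature strength grades (`vs` very strong ... `vw` very weak), used
#' as the band model of the synthetic spectrum generator.
#'
#' @param width Lorentzian full width at half maximum in cm^-1 applied to
#'   every band (default 12).
#' @return Data frame with columns `position` (cm^-1), `grade`, `width`.
#' @export
band_catalogue <- function(width = 12) {
  stopifnot(width > 0)
  pos <- c(1745, 1657, 1618, 1602, 1578, 1528, 1443, 1398, 1337, 1311,
           1250, 1209, 1175, 1156, 1128, 1096, 1088, 1064, 1045, 1032,
           1001, 971, 957, 934, 889, 874, 850, 826, 811, 781, 750, 721,
           668, 642, 619)
  grade <- c("vw", "vs", "s", "s", "s", "vw", "vs", "s", "s", "s",
             "s", "m", "w", "w", "m", "w", "w", "vw", "vw", "w",
             "s", "vw", "w", "w", "w", "w", "w", "w", "vw", "m", "m",
             "w", "w", "w", "w")
  data.frame(position = pos, grade = grade, width = width)
}

#' Strength grade to base amplitude mapping
#'
#' Monotone `vs > s > m > w > vw` mapping used to turn the qualitative
#' catalogue grades into peak amplitudes. A simulation choice, exposed so
#' it can be varied; it is not claimed to match any instrument.
#'
#' @return Named numeric vector.
#' @export
grade_amplitudes <- function() {
  c(vs = 1.0, s = 0.6, m = 0.35, w = 0.18, vw = 0.08)
}

# Match effect positions to catalogue rows (nearest band within `tol`).
match_bands <- function(positions, catalogue, tol = 2) {
  idx <- vapply(positions, function(p) {
    i <- which.min(abs(catalogue$position - p))
    if (abs(catalogue$position[i] - p) > tol)
      stop("no catalogue band within ", tol, " cm^-1 of ", p)
    i
  }, integer(1))
  if (anyDuplicated(idx)) stop("effect positions map to a duplicate band")
  idx
}

#' Per-band class-effect multipliers
#'
#' Builds a multiplier vector (one entry per catalogue band, default 1)
#' with `1 + delta` at the listed band positions. Class differences in the
#' simulator are multiplicative on band amplitudes, emulating
#' class-dependent intensity changes at fixed wavenumbers.
#'
#' @param positions band positions (cm^-1); each must match a catalogue
#'   band within 2 cm^-1.
#' @param deltas relative amplitude changes at those positions.
#' @param catalogue a [band_catalogue()].
#' @return Numeric multiplier vector of length `nrow(catalogue)`.
#' @export
class_effect <- function(positions, deltas, catalogue = band_catalogue()) {
  stopifnot(length(positions) == length(deltas))
  mult <- rep(1, nrow(catalogue))
  mult[match_bands(positions, catalogue)] <- 1 + deltas
  pmax(mult, 0)
}

# Shared difference pattern: the bands where average spectra of the three
# systems visibly differ (700-800 cm^-1 triplet, 1064, 1088/1096, 1128,
# 1250, 1311, 1337, 1443, 1578, 1602/1618). Signs mix enrichment and
# depletion.
diff_pattern <- function() {
  list(positions = c(721, 750, 781, 1064, 1088, 1096, 1128, 1250, 1311,
                     1337, 1443, 1578, 1602, 1618),
       deltas = c(0.5, 0.6, 0.6, 0.8, 0.4, 0.4, 0.4, 0.35, -0.35,
                  0.35, -0.3, 0.4, 0.3, 0.3))
}

# Secondary pattern distinguishing fully malignant from precancerous cells
# only: small changes at bands outside the main difference set.
extra_pattern <- function() {
  list(positions = c(1001, 1657, 957, 874, 1398),
       deltas = c(-0.12, -0.10, 0.18, 0.18, -0.12))
}

#' Default class effects of the three biological systems
#'
#' NFC (normal) is the reference (all multipliers 1). The precancerous and
#' malignant classes scale a shared difference pattern at the
#' difference-band positions; the malignant class additionally carries a
#' small secondary pattern. The scalings are calibrated once so that the
#' pairwise separations order as NFC/MBM-T > NFC/NIH-3T3 > NIH-3T3/MBM-T:
#' the precancerous-vs-malignant contrast is dominated by the small
#' secondary pattern, making it the hard task.
#'
#' @param nih_sep scaling of the shared pattern for NIH/3T3 (default 0.45).
#' @param mbm_sep scaling of the shared pattern for MBM-T (default 0.60).
#' @param mbm_extra scaling of the secondary MBM-T pattern (default 0.30).
#' @param catalogue a [band_catalogue()].
#' @return Named list of per-band multiplier vectors, one per class.
#' @export
default_class_effects <- function(nih_sep = 0.45, mbm_sep = 0.60,
                                  mbm_extra = 0.30,
                                  catalogue = band_catalogue()) {
  d1 <- diff_pattern(); d2 <- extra_pattern()
  mbm <- class_effect(d1$positions, mbm_sep * d1$deltas, catalogue) *
    class_effect(d2$positions, mbm_extra * d2$deltas, catalogue)
  list("NFC" = rep(1, nrow(catalogue)),
       "NIH/3T3" = class_effect(d1$positions, nih_sep * d1$deltas,
                                catalogue),
       "MBM-T" = pmax(mbm, 0))
}

#' Simulation configuration
#'
#' The defaults state the emulated world: a 600-1800 cm^-1 grid at
#' 1.2 cm^-1 dispersion, the study's cell counts per class
#' (169/136/152 = 457) with its per-site measurement sparsity
#' (444/274/279 site spectra), a slowly varying positive fluorescence
#' background that dominates the Raman signal, additive detector noise,
#' per-cell biological amplitude variability, and the calibrated class
#' effects of [default_class_effects()].
#'
#' @param grid_low,grid_high,grid_step wavenumber grid (cm^-1).
#' @param n_cells named integer vector of cells per class.
#' @param site_counts 3 x 3 matrix (rows center/cytoplasm/membrane,
#'   columns classes) of per-site measurement counts, or `NULL` for all
#'   sites on every cell.
#' @param class_effects per-class band multipliers
#'   ([default_class_effects()]).
#' @param catalogue a [band_catalogue()].
#' @param background_amplitude scale of the fluorescence background
#'   relative to the strongest Raman band (default 2).
#' @param background_degree polynomial degree of the background (default 3).
#' @param noise_sd additive Gaussian noise sd in band-amplitude units
#'   (default 0.01).
#' @param cell_sd log-sd of the per-cell global amplitude factor
#'   (default 0.10).
#' @param band_jitter_sd log-sd of the per-cell per-band amplitude jitter
#'   (default 0.06).
#' @param pattern_sd sd of a per-cell scalar that scales the shared
#'   difference pattern (default 0.15): correlated biological variability
#'   along the same direction that separates the classes, which puts that
#'   direction among the dominant PCA modes — so easy pairs plateau at few
#'   PCs while the secondary malignant pattern stays in late PCs.
#' @param site_effects named multipliers of the overall signal per site.
#' @return A `sim_config` list.
#' @export
sim_config <- function(grid_low = 600, grid_high = 1800, grid_step = 1.2,
                       n_cells = c("NFC" = 169L, "NIH/3T3" = 136L,
                                   "MBM-T" = 152L),
                       site_counts = default_site_counts(),
                       class_effects = default_class_effects(),
                       catalogue = band_catalogue(),
                       background_amplitude = 2,
                       background_degree = 3L,
                       noise_sd = 0.01,
                       cell_sd = 0.10,
                       band_jitter_sd = 0.06,
                       pattern_sd = 0.15,
                       site_effects = c(center = 1, cytoplasm = 0.92,
                                        membrane = 0.85)) {
  stopifnot(grid_step > 0, grid_low < grid_high,
            background_amplitude >= 0, noise_sd >= 0, cell_sd >= 0,
            band_jitter_sd >= 0, pattern_sd >= 0,
            all(names(n_cells) %in% CLASS_LABELS),
            all(names(class_effects) %in% CLASS_LABELS))
  if (!is.null(site_counts)) {
    stopifnot(is.matrix(site_counts),
              identical(rownames(site_counts), SITE_LABELS),
              identical(colnames(site_counts), names(n_cells)))
    if (any(site_counts > rep(n_cells, each = 3L)))
      stop("site_counts cannot exceed n_cells")
  }
  structure(list(grid = seq(grid_low, grid_high, by = grid_step),
                 n_cells = n_cells, site_counts = site_counts,
                 class_effects = class_effects, catalogue = catalogue,
                 background_amplitude = background_amplitude,
                 background_degree = as.integer(background_degree),
                 noise_sd = noise_sd, cell_sd = cell_sd,
                 band_jitter_sd = band_jitter_sd,
                 pattern_sd = pattern_sd,
                 site_effects = site_effects),
            class = "sim_config")
}

#' Per-site measurement counts of the emulated study design
#'
#' @return 3 x 3 integer matrix, rows = sites, columns = classes; column
#'   sums are 400/309/288 site spectra (997 total) over 169/136/152 cells.
#' @export
default_site_counts <- function() {
  m <- matrix(c(169L, 115L, 116L,
                132L,  86L,  91L,
                143L,  73L,  72L), nrow = 3L,
              dimnames = list(SITE_LABELS,
                              c("NFC", "NIH/3T3", "MBM-T")))
  m
}

# Lorentzian band profile matrix for a grid: n_w x n_bands, unit peak
# height per band.
band_profiles <- function(grid, catalogue) {
  g <- catalogue$width / 2
  sapply(seq_len(nrow(catalogue)), function(b) {
    g2 <- g[b]^2
    g2 / ((grid - catalogue$position[b])^2 + g2)
  })
}

#' Render a noise-free synthetic Raman spectrum
#'
#' Sum of Lorentzian peaks at the catalogue band positions; each band's
#' amplitude is its grade's base amplitude times the supplied multiplier.
#' Strictly non-negative.
#'
#' @param catalogue a [band_catalogue()].
#' @param multipliers per-band multiplier vector (default all 1), e.g. a
#'   class effect times cell and site effects.
#' @param grid wavenumber grid (cm^-1).
#' @return A [raman_spectrum()].
#' @export
render_clean_spectrum <- function(catalogue = band_catalogue(),
                                  multipliers = rep(1, nrow(catalogue)),
                                  grid = seq(600, 1800, by = 1.2)) {
  stopifnot(length(multipliers) == nrow(catalogue))
  amps <- grade_amplitudes()[catalogue$grade] * pmax(multipliers, 0)
  y <- as.numeric(band_profiles(grid, catalogue) %*% amps)
  raman_spectrum(grid, y, meta = list(kind = "clean"))
}

# Draw a positive, slowly varying polynomial background on [0,1]-scaled
# wavenumber. Coefficients uniform in [0.2, 1] keep it positive and smooth.
draw_background <- function(grid, amplitude, degree) {
  t <- (grid - min(grid)) / (max(grid) - min(grid))
  cf <- stats::runif(degree + 1L, 0.2, 1)
  amplitude * as.numeric(outer(t, 0:degree, `^`) %*% cf) / (degree + 1L)
}

#' Add fluorescence background and detector noise to a clean spectrum
#'
#' Adds a smooth positive low-order polynomial background (random
#' coefficients) plus i.i.d. Gaussian noise. The true background curve is
#' stored in `meta$true_background` so baseline-recovery tests have an
#' oracle. Uses the current RNG state: seed upstream for reproducibility.
#'
#' @param clean a [raman_spectrum()].
#' @param config a [sim_config()].
#' @return A [raman_spectrum()] of the degraded signal.
#' @export
add_background_and_noise <- function(clean, config = sim_config()) {
  stopifnot(is_spectrum(clean))
  bg <- if (config$background_amplitude > 0)
    draw_background(clean$wavenumbers, config$background_amplitude,
                    config$background_degree)
  else rep(0, length(clean$wavenumbers))
  noise <- if (config$noise_sd > 0)
    stats::rnorm(length(clean$wavenumbers), 0, config$noise_sd)
  else rep(0, length(clean$wavenumbers))
  raman_spectrum(clean$wavenumbers, clean$intensities + bg + noise,
                 meta = c(clean$meta, list(true_background = bg)))
}

# Deterministic per-site presence masks reproducing exact per-site counts:
# the first `n_center` cells carry a center spectrum, the last
# `n_cytoplasm` / `n_membrane` cells the other sites, guaranteeing every
# cell at least one site whenever the counts allow it.
site_masks <- function(n, counts) {
  if (is.null(counts))
    return(list(center = rep(TRUE, n), cytoplasm = rep(TRUE, n),
                membrane = rep(TRUE, n)))
  m <- list(center = seq_len(n) <= counts["center"],
            cytoplasm = seq_len(n) > n - counts["cytoplasm"],
            membrane = seq_len(n) > n - counts["membrane"])
  if (any(!(m$center | m$cytoplasm | m$membrane)))
    stop("site counts leave a cell with no measurement site")
  m
}

#' Generate a labelled synthetic Raman dataset
#'
#' Draws, per cell: a global amplitude factor and per-band amplitude
#' jitter (log-normal); renders each present site's spectrum as the band
#' model times class, cell and site effects; and degrades it with a random
#' fluorescence background plus noise. Site presence follows the
#' configured per-site counts exactly. All randomness flows through the
#' single `seed`.
#'
#' @param config a [sim_config()].
#' @param seed integer seed recorded in the manifest provenance.
#' @return A [dataset_manifest()]; `provenance` holds `seed` and per-cell
#'   truth (`truth`: class effects and per-cell multipliers).
#' @export
generate_dataset <- function(config = sim_config(), seed = 1L) {
  grid <- config$grid
  catalogue <- config$catalogue
  profiles <- band_profiles(grid, catalogue)
  base_amp <- grade_amplitudes()[catalogue$grade]
  nb <- nrow(catalogue)
  d1 <- diff_pattern()
  pattern <- class_effect(d1$positions, d1$deltas, catalogue) - 1
  with_seed(seed, {
    records <- list()
    truth <- list()
    for (cl in names(config$n_cells)) {
      n <- config$n_cells[[cl]]
      if (n < 1L) next
      cmult <- config$class_effects[[cl]]
      if (is.null(cmult)) cmult <- rep(1, nb)
      masks <- site_masks(n, if (is.null(config$site_counts)) NULL
                          else config$site_counts[, cl])
      tag <- gsub("[^A-Za-z0-9]", "", cl)
      for (i in seq_len(n)) {
        id <- sprintf("%s_%03d", tag, i)
        cell_mult <- exp(stats::rnorm(1L, 0, config$cell_sd)) *
          exp(stats::rnorm(nb, 0, config$band_jitter_sd)) *
          pmax(1 + stats::rnorm(1L, 0, config$pattern_sd) * pattern, 0)
        amps_cell <- base_amp * pmax(cmult * cell_mult, 0)
        ss <- list()
        for (site in SITE_LABELS) {
          if (!masks[[site]][i]) next
          clean <- raman_spectrum(
            grid,
            as.numeric(profiles %*% (amps_cell *
                                       config$site_effects[[site]])),
            meta = list(class = cl, site = site))
          ss[[site]] <- add_background_and_noise(clean, config)
        }
        records[[length(records) + 1L]] <- cell_record(id, cl, ss)
        truth[[id]] <- list(class = cl, cell_mult = cell_mult)
      }
    }
    dataset_manifest(records,
                     provenance = list(generator = "ramancell-synthetic",
                                       seed = seed, truth = truth))
  })
}

#' Grid points far from every catalogued band
#'
#' @param grid wavenumber grid.
#' @param catalogue a [band_catalogue()].
#' @param min_dist minimum distance (cm^-1) to any band position.
#' @return Logical mask over `grid`.
#' @export
peak_free_mask <- function(grid, catalogue = band_catalogue(),
                           min_dist = 24) {
  dmin <- apply(abs(outer(grid, catalogue$position, `-`)), 1L, min)
  dmin >= min_dist
}
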