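#' Baseline-correction configuration
#'
#' The baseline estimator splits the working range at `region_split`: in the
#' upper sub-region (wavenumber > split) anchor points are the intensity
#' minima found within `anchor_window` cm^-1 of each fixed anchor
#' wavenumber; the lower sub-region is tiled into `n_ranges` equal-width
#' ranges and the minimum of each range becomes an anchor. The anchors are
#' joined by straight lines to form the baseline, which is subtracted; the
#' whole process is repeated `n_iterations` times on the evolving spectrum.
#'
#' @param region_split boundary between the two sub-regions (cm^-1).
#' @param fixed_anchors anchor wavenumbers in the upper sub-region (cm^-1).
#' @param n_ranges number of equal-width ranges tiling the lower sub-region.
#' @param n_iterations number of subtract-and-refit iterations.
#' @param anchor_window half-width (cm^-1) of the neighbourhood searched for
#'   the minimum around each fixed anchor.
#' @return A `baseline_config` list.
#' @export
baseline_config <- function(region_split = 1200,
                            fixed_anchors = c(1800, 1750, 1720,
                                              1560, 1530, 1490),
                            n_ranges = 50L,
                            n_iterations = 5L,
                            anchor_window = 10) {
  stopifnot(n_ranges >= 1L, n_iterations >= 1L, anchor_window > 0,
            all(fixed_anchors > region_split))
  structure(list(region_split = region_split,
                 fixed_anchors = sort(fixed_anchors),
                 n_ranges = as.integer(n_ranges),
                 n_iterations = as.integer(n_iterations),
                 anchor_window = anchor_window),
            class = "baseline_config")
}

#' Preprocessing configuration
#'
#' @param cut_range working range `(low, high)` in cm^-1.
#' @param sg_window Savitzky-Golay window length in points (odd).
#' @param sg_polyorder Savitzky-Golay polynomial order (< window).
#' @param baseline a [baseline_config()].
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(cut_range = c(600, 1800),
                              sg_window = 5L,
                              sg_polyorder = 2L,
                              baseline = baseline_config()) {
  stopifnot(length(cut_range) == 2L, cut_range[1] < cut_range[2],
            sg_polyorder < sg_window)
  structure(list(cut_range = as.numeric(cut_range),
                 sg_window = as.integer(sg_window),
                 sg_polyorder = as.integer(sg_polyorder),
                 baseline = baseline),
            class = "preprocess_config")
}

#' Cut a spectrum to a wavenumber range
#'
#' @param spectrum a [raman_spectrum()].
#' @param low,high closed-interval bounds in cm^-1.
#' @return The spectrum restricted to `low <= w <= high`.
#' @export
cut_to_range <- function(spectrum, low = 600, high = 1800) {
  stopifnot(is_spectrum(spectrum), low < high)
  keep <- spectrum$wavenumbers >= low & spectrum$wavenumbers <= high
  if (sum(keep) < 2L)
    stop("fewer than 2 grid points in [", low, ", ", high, "]")
  raman_spectrum(spectrum$wavenumbers[keep], spectrum$intensities[keep],
                 meta = append_step(spectrum$meta,
                                    sprintf("cut[%g,%g]", low, high)))
}

append_step <- function(meta, step) {
  meta$steps <- c(meta$steps, step)
  meta
}

# Savitzky-Golay convolution coefficients for the smoothing (0th-derivative)
# filter: first row of the pseudo-inverse of the local Vandermonde design.
savgol_coefficients <- function(window, polyorder) {
  h <- (window - 1L) %/% 2L
  A <- outer(-h:h, 0:polyorder, `^`)
  (A %*% solve(crossprod(A), t(A)))[h + 1L, ]
}

# Apply SG smoothing to a plain vector, mirror-padding (without repeating
# the edge point) so the output has the input's length.
savgol_vector <- function(y, window, polyorder) {
  n <- length(y)
  h <- (window - 1L) %/% 2L
  ypad <- c(y[(h + 1L):2L], y, y[(n - 1L):(n - h)])
  cf <- savgol_coefficients(window, polyorder)
  as.numeric(stats::filter(ypad, cf, sides = 2L))[(h + 1L):(h + n)]
}

#' Savitzky-Golay smoothing
#'
#' Replaces each intensity by the value at that point of the least-squares
#' polynomial of degree `polyorder` fitted over the centred `window`. Edges
#' are handled by mirror-padding the signal by `(window-1)/2` points.
#'
#' @param spectrum a [raman_spectrum()].
#' @param window odd window length in points.
#' @param polyorder polynomial degree, `< window`.
#' @return The smoothed spectrum.
#' @export
smooth_savgol <- function(spectrum, window = 5L, polyorder = 2L) {
  stopifnot(is_spectrum(spectrum))
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("window must be odd")
  if (polyorder >= window) stop("polyorder must be < window")
  n <- length(spectrum$wavenumbers)
  if (n < window) stop("window (", window, ") exceeds spectrum length ", n)
  raman_spectrum(spectrum$wavenumbers,
                 savgol_vector(spectrum$intensities, window, polyorder),
                 meta = append_step(spectrum$meta,
                                    sprintf("savgol[%d,%d]", window,
                                            polyorder)))
}

# Precompute, for a fixed grid, the index sets over which baseline anchor
# minima are searched. Returned as a list of integer index vectors; reused
# across spectra and iterations.
baseline_index_sets <- function(w, config) {
  sets <- list()
  for (a in config$fixed_anchors) {
    idx <- which(w > config$region_split &
                 abs(w - a) <= config$anchor_window)
    if (length(idx)) sets[[length(sets) + 1L]] <- idx
  }
  lo <- w[w <= config$region_split]
  if (length(lo)) {
    edges <- seq(min(lo), config$region_split,
                 length.out = config$n_ranges + 1L)
    for (k in seq_len(config$n_ranges)) {
      # half-open [a, b) except the last range, which is closed
      if (k < config$n_ranges)
        idx <- which(w >= edges[k] & w < edges[k + 1L])
      else
        idx <- which(w >= edges[k] & w <= edges[k + 1L])
      if (length(idx)) sets[[length(sets) + 1L]] <- idx
    }
  }
  sets
}

# Core baseline estimate on plain vectors; `sets` from baseline_index_sets.
# Piecewise-linear through the anchor minima; beyond the outermost anchors
# the adjacent segment is continued linearly so that an exactly linear
# spectrum is reproduced over the whole grid.
baseline_from_sets <- function(w, y, sets) {
  ai <- vapply(sets, function(idx) idx[which.min(y[idx])], integer(1))
  ai <- sort(unique(ai))
  if (length(ai) < 2L)
    stop("fewer than 2 resolvable baseline anchor points")
  xa <- w[ai]; ya <- y[ai]
  b <- stats::approx(xa, ya, xout = w, rule = 2)$y
  k <- length(ai)
  left <- w < xa[1]
  if (any(left)) {
    sl <- (ya[2] - ya[1]) / (xa[2] - xa[1])
    b[left] <- ya[1] + sl * (w[left] - xa[1])
  }
  right <- w > xa[k]
  if (any(right)) {
    sl <- (ya[k] - ya[k - 1]) / (xa[k] - xa[k - 1])
    b[right] <- ya[k] + sl * (w[right] - xa[k])
  }
  b
}

#' Estimate the fluorescence baseline of a spectrum
#'
#' Anchor points are local minima: around each fixed anchor wavenumber in
#' the upper sub-region, and per equal-width range in the lower sub-region.
#' The baseline is the piecewise-linear interpolant through these anchors,
#' continued linearly beyond the outermost anchors.
#'
#' @param spectrum a [raman_spectrum()] spanning both sub-regions.
#' @param config a [baseline_config()].
#' @return A [raman_spectrum()] holding the baseline curve on the same grid.
#' @export
compute_baseline <- function(spectrum, config = baseline_config()) {
  stopifnot(is_spectrum(spectrum))
  sets <- baseline_index_sets(spectrum$wavenumbers, config)
  b <- baseline_from_sets(spectrum$wavenumbers, spectrum$intensities, sets)
  raman_spectrum(spectrum$wavenumbers, b, meta = list(kind = "baseline"))
}

#' Iterative anchored-minima baseline correction
#'
#' Repeats `config$n_iterations` times: estimate the baseline of the current
#' spectrum ([compute_baseline()], with anchors recomputed each pass) and
#' subtract it. Negative residuals are not clipped; they are handled only by
#' the final normalization shift.
#'
#' @param spectrum a [raman_spectrum()].
#' @param config a [baseline_config()].
#' @return The baseline-corrected spectrum; `meta$baseline_iterations`
#'   records the iteration count.
#' @export
correct_baseline <- function(spectrum, config = baseline_config()) {
  stopifnot(is_spectrum(spectrum))
  w <- spectrum$wavenumbers
  sets <- baseline_index_sets(w, config)
  y <- spectrum$intensities
  for (i in seq_len(config$n_iterations))
    y <- y - baseline_from_sets(w, y, sets)
  meta <- append_step(spectrum$meta,
                      sprintf("baseline[x%d]", config$n_iterations))
  meta$baseline_iterations <- config$n_iterations
  raman_spectrum(w, y, meta = meta)
}

#' Vector normalization with minimum shift
#'
#' Three steps: (1) subtract the mean intensity; (2) divide by the Euclidean
#' norm of the mean-subtracted vector, so the spectrum has unit norm;
#' (3) shift so the minimum intensity is exactly zero. The pre-shift vector
#' is recoverable from the output as `y - mean(y)`.
#'
#' @param spectrum a [raman_spectrum()] with non-constant intensities.
#' @return The normalized spectrum (`min == 0`).
#' @export
vector_normalize <- function(spectrum) {
  stopifnot(is_spectrum(spectrum))
  y <- spectrum$intensities - mean(spectrum$intensities)
  nrm <- sqrt(sum(y^2))
  if (nrm < .Machine$double.eps * length(y))
    stop("degenerate input: constant spectrum has zero norm")
  y <- y / nrm
  y <- y - min(y)
  raman_spectrum(spectrum$wavenumbers, y,
                 meta = append_step(spectrum$meta, "vecnorm"))
}

#' Full preprocessing pipeline
#'
#' Composition cut -> Savitzky-Golay smooth -> iterative baseline
#' correction -> vector normalization, in that order. Deterministic; the
#' output minimum is exactly 0 and the mean-centred output has unit norm.
#'
#' @param spectrum a raw [raman_spectrum()].
#' @param config a [preprocess_config()].
#' @return The preprocessed spectrum; `meta$steps` records each stage.
#' @export
preprocess_pipeline <- function(spectrum, config = preprocess_config()) {
  s <- cut_to_range(spectrum, config$cut_range[1], config$cut_range[2])
  s <- smooth_savgol(s, config$sg_window, config$sg_polyorder)
  s <- correct_baseline(s, config$baseline)
  vector_normalize(s)
}

#' Preprocess every spectrum of a manifest
#'
#' Applies [preprocess_pipeline()] to each site spectrum; the heavy lifting
#' (index sets, SG coefficients) is shared across spectra since all sit on
#' one grid.
#'
#' @param manifest a [dataset_manifest()].
#' @param config a [preprocess_config()].
#' @return A new [dataset_manifest()] on the cut grid.
#' @export
preprocess_manifest <- function(manifest, config = preprocess_config()) {
  grid <- manifest$grid
  keep <- grid >= config$cut_range[1] & grid <= config$cut_range[2]
  if (sum(keep) < config$sg_window)
    stop("cut range leaves fewer points than the SG window")
  w <- grid[keep]
  sets <- baseline_index_sets(w, config$baseline)
  n_it <- config$baseline$n_iterations
  process <- function(y) {
    y <- savgol_vector(y[keep], config$sg_window, config$sg_polyorder)
    for (i in seq_len(n_it)) y <- y - baseline_from_sets(w, y, sets)
    y <- y - mean(y)
    nrm <- sqrt(sum(y^2))
    if (nrm < .Machine$double.eps * length(y))
      stop("degenerate spectrum after baseline correction")
    y <- y / nrm
    y - min(y)
  }
  records <- lapply(manifest$records, function(r) {
    r$site_spectra <- lapply(r$site_spectra, function(s) {
      raman_spectrum(w, process(s$intensities),
                     meta = append_step(s$meta, "preprocessed"))
    })
    r
  })
  dataset_manifest(records,
                   provenance = c(manifest$provenance,
                                  list(preprocessed = TRUE)))
}
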