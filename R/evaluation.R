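#' Confusion matrix of a binary classifier
#'
#' @param TP,FN,FP,TN non-negative integer counts; their total must be > 0.
#' @return A `confusion_matrix` object.
#' @export
confusion_matrix <- function(TP, FN, FP, TN) {
  cnt <- c(TP = unname(TP), FN = unname(FN), FP = unname(FP),
           TN = unname(TN))
  if (any(cnt < 0) || any(cnt != round(cnt)))
    stop("counts must be non-negative integers")
  if (sum(cnt) == 0) stop("all-zero confusion matrix")
  structure(as.list(cnt), class = "confusion_matrix")
}

#' Performance metrics from a confusion matrix
#'
#' Computes, as percentages: accuracy `(TP+TN)/total`, sensitivity
#' `TP/(TP+FN)`, specificity `TN/(TN+FP)`, positive predictive value
#' `TP/(TP+FP)` and negative predictive value `TN/(TN+FN)`. A metric whose
#' denominator is zero is returned as `NA` (undefined), never an error.
#'
#' @param cm a [confusion_matrix()].
#' @return Named numeric vector `c(ACC, SE, SP, PPV, NPV)` in percent;
#'   undefined entries are `NA`.
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  rate <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  with(cm, c(
    ACC = rate(TP + TN, TP + TN + FP + FN),
    SE  = rate(TP, TP + FN),
    SP  = rate(TN, TN + FP),
    PPV = rate(TP, TP + FP),
    NPV = rate(TN, TN + FN)))
}

#' Cross-validation configuration
#'
#' @param k number of folds (>= 2; default 5).
#' @param seed integer seed controlling the fold shuffle.
#' @param stratified balance class proportions across folds (default TRUE).
#' @param group_by_cell keep all entries of one cell in one fold (default
#'   TRUE; database entries are per cell, so this guards against leakage if
#'   a caller ever passes per-spectrum entries).
#' @param n_repeats repetitions of the whole CV with derived seeds
#'   (default 1: the k folds are the repetitions).
#' @return A `cv_config` list.
#' @export
cv_config <- function(k = 5L, seed = 1L, stratified = TRUE,
                      group_by_cell = TRUE, n_repeats = 1L) {
  stopifnot(k >= 2L, n_repeats >= 1L)
  structure(list(k = as.integer(k), seed = as.integer(seed),
                 stratified = isTRUE(stratified),
                 group_by_cell = isTRUE(group_by_cell),
                 n_repeats = as.integer(n_repeats)),
            class = "cv_config")
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Split entries into k disjoint folds
#'
#' Stratified: within each class the (shuffled) entries are dealt
#' round-robin, so per-class fold sizes differ by at most one. With
#' `group_by_cell`, entries sharing a `cell_id` are assigned as a block.
#' The same seed always yields the same folds.
#'
#' @param labels class label per entry.
#' @param config a [cv_config()].
#' @param cell_id optional cell identifier per entry (for grouping).
#' @return Integer vector of fold ids in `1..k`, one per entry.
#' @export
kfold_split <- function(labels, config = cv_config(), cell_id = NULL) {
  n <- length(labels)
  k <- config$k
  if (is.null(cell_id) || !config$group_by_cell)
    cell_id <- as.character(seq_len(n))
  units <- !duplicated(cell_id)
  ulab <- labels[units]; uid <- cell_id[units]
  if (config$stratified) {
    cnt <- table(ulab)
    if (any(cnt < k))
      stop("class '", names(cnt)[which.min(cnt)], "' has ",
           min(cnt), " members: fewer than k = ", k, " folds")
  }
  fold_of <- with_seed(config$seed, {
    f <- integer(length(uid))
    if (config$stratified) {
      totals <- integer(k)
      for (g in unique(ulab)) {
        idx <- which(ulab == g)
        idx <- idx[sample.int(length(idx))]
        ng <- length(idx)
        sizes <- rep(ng %/% k, k)
        r <- ng %% k
        if (r > 0L) {
          # give the remainder to the currently smallest folds so overall
          # fold sizes also stay within one of each other
          pick <- order(totals + stats::runif(k) * 0.1)[seq_len(r)]
          sizes[pick] <- sizes[pick] + 1L
        }
        f[idx] <- rep.int(seq_len(k), sizes)
        totals <- totals + sizes
      }
    } else {
      idx <- sample.int(length(uid))
      f[idx] <- ((seq_along(idx) - 1L) %% k) + 1L
    }
    f
  })
  names(fold_of) <- uid
  unname(fold_of[cell_id])
}

# Shared inner loop: per fold, fit PCA on the training spectra only,
# project, fit LDA, predict the held-out fold. Returns per-fold confusion
# counts for each requested n_pcs (a list over n_pcs of 4-vectors summed
# over folds plus per-fold accuracies).
cv_engine <- function(x, y, folds, n_pcs_values, regularization = NULL) {
  k <- max(folds)
  npv <- as.integer(n_pcs_values)
  counts <- matrix(0L, nrow = length(npv), ncol = 4L,
                   dimnames = list(NULL, c("TP", "FN", "FP", "TN")))
  fold_acc <- matrix(NA_real_, nrow = length(npv), ncol = k)
  for (f in seq_len(k)) {
    tr <- folds != f; te <- !tr
    if (length(unique(y[tr])) < 2L || !any(te))
      stop("fold ", f, " is degenerate (missing a class)")
    basis <- pca_fit(x[tr, , drop = FALSE])
    maxp <- max(npv)
    if (maxp > ncol(basis$components))
      stop("n_pcs = ", maxp, " exceeds available components (",
           ncol(basis$components), ") in fold ", f)
    ztr <- pca_project(basis, x[tr, , drop = FALSE], maxp)
    zte <- pca_project(basis, x[te, , drop = FALSE], maxp)
    ytr <- factor(y[tr], levels = c("negative", "positive"))
    yte <- y[te]
    for (j in seq_along(npv)) {
      p <- npv[j]
      model <- lda_fit(ztr[, seq_len(p), drop = FALSE], ytr,
                       regularization = regularization)
      pred <- lda_predict(model, zte[, seq_len(p), drop = FALSE])$labels
      tp <- sum(pred == "positive" & yte == "positive")
      fn <- sum(pred == "negative" & yte == "positive")
      fp <- sum(pred == "positive" & yte == "negative")
      tn <- sum(pred == "negative" & yte == "negative")
      counts[j, ] <- counts[j, ] + c(tp, fn, fp, tn)
      fold_acc[j, f] <- 100 * (tp + tn) / (tp + fn + fp + tn)
    }
  }
  list(counts = counts, fold_acc = fold_acc)
}

#' Cross-validated PCA-LDA classification
#'
#' For each fold: the PCA basis is fitted on the training spectra only,
#' train and test spectra are projected onto the first `n_pcs` components,
#' an LDA model is fitted on the training features and the held-out fold is
#' predicted. Confusion counts are summed over folds; metrics are computed
#' once from the summed counts; `acc_std` is the standard deviation of the
#' per-fold accuracies.
#'
#' @param db a `raman_database` of preprocessed spectra
#'   (see [build_database()]).
#' @param task a [make_task()] result (or a task id string).
#' @param n_pcs number of principal components used as features.
#' @param cv a [cv_config()].
#' @param regularization passed to [lda_fit()].
#' @return A `cv_result`: `confusion` ([confusion_matrix()]), `metrics`
#'   (with `acc_std` appended), `fold_accuracies`, `folds`, `n_pcs`,
#'   `task_id`, `n_negative`, `n_positive`.
#' @export
run_cv <- function(db, task, n_pcs, cv = cv_config(),
                   regularization = NULL) {
  if (is.character(task)) task <- make_task(task)
  y <- apply_task(task, db$class_label)
  keep <- !is.na(y)
  if (!any(keep)) stop("no entries belong to task ", task$task_id)
  x <- db$spectra[keep, , drop = FALSE]
  y <- as.character(y[keep])
  if (length(unique(y)) < 2L)
    stop("task ", task$task_id, ": only one class present")
  folds <- kfold_split(y, cv, cell_id = db$cell_id[keep])
  eng <- cv_engine(x, y, folds, n_pcs, regularization)
  cm <- confusion_matrix(eng$counts[1, "TP"], eng$counts[1, "FN"],
                         eng$counts[1, "FP"], eng$counts[1, "TN"])
  met <- compute_metrics(cm)
  facc <- eng$fold_acc[1, ]
  structure(list(confusion = cm,
                 metrics = c(met, acc_std = stats::sd(facc)),
                 fold_accuracies = facc,
                 folds = folds, n_pcs = as.integer(n_pcs),
                 task_id = task$task_id,
                 n_negative = sum(y == "negative"),
                 n_positive = sum(y == "positive")),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result %s: n_pcs = %d, %d neg / %d pos>\n",
              x$task_id, x$n_pcs, x$n_negative, x$n_positive))
  m <- x$metrics
  cat(sprintf("  ACC %.1f +/- %.1f | SE %.1f | SP %.1f | PPV %.1f | NPV %.1f\n",
              m["ACC"], m["acc_std"], m["SE"], m["SP"], m["PPV"],
              m["NPV"]))
  invisible(x)
}

#' Cross-validated accuracy as a function of the number of PCs
#'
#' Sweeps `n_pcs = 1..max_pcs` using identical folds (same seed) across the
#' sweep, so the curves are a controlled comparison. Within each fold the
#' PCA basis is fitted once and truncated, which is equivalent to running
#' [run_cv()] per `n_pcs`.
#'
#' @param db a `raman_database` of preprocessed spectra.
#' @param task a [make_task()] result or task id.
#' @param cv a [cv_config()].
#' @param max_pcs largest number of PCs (default 25).
#' @param regularization passed to [lda_fit()].
#' @return A `pc_curve` data frame with columns `n_pcs`, `mean_accuracy`
#'   (percent, from summed fold counts), `acc_std` (fold-wise sd); the fold
#'   assignment hash is attached as attribute `fold_hash`.
#' @export
accuracy_vs_pcs <- function(db, task, cv = cv_config(), max_pcs = 25L,
                            regularization = NULL) {
  if (is.character(task)) task <- make_task(task)
  y <- apply_task(task, db$class_label)
  keep <- !is.na(y)
  x <- db$spectra[keep, , drop = FALSE]
  y <- as.character(y[keep])
  folds <- kfold_split(y, cv, cell_id = db$cell_id[keep])
  eng <- cv_engine(x, y, folds, seq_len(max_pcs), regularization)
  acc <- 100 * (eng$counts[, "TP"] + eng$counts[, "TN"]) /
    rowSums(eng$counts)
  out <- data.frame(n_pcs = seq_len(max_pcs), mean_accuracy = acc,
                    acc_std = apply(eng$fold_acc, 1L, stats::sd))
  attr(out, "fold_hash") <- paste(folds, collapse = ",")
  class(out) <- c("pc_curve", "data.frame")
  out
}

#' Plateau-based choice of the number of PCs
#'
#' Returns the smallest `n_pcs` whose accuracy is within `tolerance`
#' percentage points of the curve's maximum — the smallest dimension that
#' reaches the accuracy plateau.
#'
#' @param curve a [accuracy_vs_pcs()] result (or any data frame with
#'   `n_pcs` and `mean_accuracy` columns).
#' @param tolerance plateau tolerance in percentage points (default 0.5).
#' @return The selected `n_pcs` (integer).
#' @export
select_n_pcs <- function(curve, tolerance = 0.5) {
  if (!nrow(curve)) stop("empty curve")
  acc <- curve$mean_accuracy
  curve$n_pcs[which(acc >= max(acc) - tolerance)[1]]
}

#' Default biomolecular sub-ranges
#'
#' Four wavenumber windows dominated by, respectively, carbohydrates,
#' proteins (amide III) + lipids, nucleic acids, and proteins
#' (amide I + II).
#'
#' @return Data frame with columns `name`, `low`, `high` (cm^-1).
#' @export
default_subranges <- function() {
  data.frame(
    name = c("carbohydrates", "proteins_amideIII_lipids",
             "nucleic_acids", "proteins_amideI_II"),
    low  = c(600, 1196, 1381, 1521),
    high = c(1195, 1380, 1520, 1728))
}

#' Sub-range classification analysis
#'
#' For every (task, wavenumber range) pair: restrict the preprocessed
#' spectra to the range (cut only; preprocessing is not redone), sweep the
#' number of PCs with identical folds, pick the plateau dimension, and
#' report the metrics at that dimension.
#'
#' @param db a `raman_database` of preprocessed full-range spectra
#'   (typically database I).
#' @param tasks character vector of task ids (default: all four).
#' @param ranges data frame as from [default_subranges()].
#' @param cv a [cv_config()].
#' @param max_pcs PC sweep upper limit per (task, range).
#' @param tolerance plateau tolerance for [select_n_pcs()].
#' @return Data frame with one row per (task, range): `task`, `range`,
#'   `low`, `high`, `n_pcs`, `ACC`, `SE`, `SP`, `PPV`, `NPV`, `acc_std`.
#' @export
subrange_analysis <- function(db, tasks = TASK_IDS,
                              ranges = default_subranges(),
                              cv = cv_config(), max_pcs = 25L,
                              tolerance = 0.5) {
  rows <- list()
  for (task_id in tasks) {
    for (i in seq_len(nrow(ranges))) {
      sub <- cut_database(db, ranges$low[i], ranges$high[i])
      curve <- accuracy_vs_pcs(sub, task_id, cv, max_pcs)
      np <- select_n_pcs(curve, tolerance)
      res <- run_cv(sub, task_id, np, cv)
      rows[[length(rows) + 1L]] <- data.frame(
        task = task_id, range = ranges$name[i],
        low = ranges$low[i], high = ranges$high[i], n_pcs = np,
        ACC = res$metrics[["ACC"]], SE = res$metrics[["SE"]],
        SP = res$metrics[["SP"]], PPV = res$metrics[["PPV"]],
        NPV = res$metrics[["NPV"]], acc_std = res$metrics[["acc_std"]])
    }
  }
  do.call(rbind, rows)
}

#' Per-site class mean spectra and pairwise differences
#'
#' For each measurement site: the pointwise class-mean spectrum with its
#' pointwise standard deviation, and the difference of class means for
#' every ordered class pair (the difference-spectrum analogue of comparing
#' average spectra between biological systems).
#'
#' @param manifest a preprocessed [dataset_manifest()].
#' @param sites sites to analyse (default: all three).
#' @return Named list per site, each with `grid`, `n` (spectra per class),
#'   `mean` (class x wavenumber matrix), `sd` (same shape), and `diff`, a
#'   named list of `A - B` difference vectors for every unordered class
#'   pair (antisymmetric counterparts implied).
#' @export
difference_spectra <- function(manifest, sites = SITE_LABELS) {
  out <- list()
  for (site in sites) {
    by_class <- list()
    for (r in manifest$records)
      if (site %in% names(r$site_spectra))
        by_class[[r$class_label]] <-
          c(by_class[[r$class_label]],
            list(r$site_spectra[[site]]$intensities))
    present <- intersect(CLASS_LABELS, names(by_class))
    if (length(present) < 2L)
      stop("site '", site, "': fewer than 2 classes have spectra")
    mats <- lapply(by_class[present], function(l) do.call(rbind, l))
    mu <- t(sapply(mats, colMeans))
    sdm <- t(sapply(mats, function(m) apply(m, 2L, stats::sd)))
    diffs <- list()
    for (i in seq_along(present))
      for (j in seq_along(present))
        if (i < j)
          diffs[[paste(present[i], present[j], sep = " - ")]] <-
            mu[present[i], ] - mu[present[j], ]
    out[[site]] <- list(grid = manifest$grid,
                        n = vapply(mats, nrow, integer(1)),
                        mean = mu, sd = sdm, diff = diffs)
  }
  out
}
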