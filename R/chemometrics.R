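#' Fit a principal component basis
#'
#' Eigendecomposition of the sample covariance (divisor `n - 1`) of the
#' mean-centred training spectra, computed via the thin SVD of the centred
#' matrix. The sign of each component is fixed so that its
#' largest-magnitude element is positive, making projections reproducible
#' across eigensolvers.
#'
#' @param x numeric matrix, rows = training spectra, columns = grid points;
#'   at least 2 rows.
#' @return A `pca_basis`: `mean` (length-p), `components` (p x k, columns
#'   orthonormal), `eigenvalues` (length k, non-increasing, >= 0).
#' @export
pca_fit <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2L) stop("PCA needs at least 2 spectra, got ", n)
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  sv <- svd(xc, nu = 0L)
  ev <- sv$d^2 / (n - 1)
  comp <- sv$v
  for (j in seq_len(ncol(comp))) {
    i <- which.max(abs(comp[, j]))
    if (comp[i, j] < 0) comp[, j] <- -comp[, j]
  }
  structure(list(mean = mu, components = comp, eigenvalues = ev),
            class = "pca_basis")
}

#' Project spectra onto a PCA basis
#'
#' Coefficients are inner products of the mean-centred spectrum with the
#' first `n_pcs` components; they are the feature vectors fed to the LDA
#' classifier.
#'
#' @param basis a [pca_fit()] result.
#' @param x numeric vector (one spectrum) or matrix (rows = spectra).
#' @param n_pcs number of leading components to keep.
#' @return A matrix of PC coefficients (rows = spectra, `n_pcs` columns).
#' @export
pca_project <- function(basis, x, n_pcs = ncol(basis$components)) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != length(basis$mean))
    stop("spectrum length ", ncol(x), " does not match basis (",
         length(basis$mean), ")")
  if (n_pcs < 1L || n_pcs > ncol(basis$components))
    stop("n_pcs must be in 1..", ncol(basis$components))
  sweep(x, 2L, basis$mean) %*% basis$components[, seq_len(n_pcs),
                                                drop = FALSE]
}

#' Reconstruct spectra from PC coefficients
#'
#' @param basis a [pca_fit()] result.
#' @param scores matrix of coefficients (rows = spectra).
#' @return Reconstructed spectra matrix (`mean + scores %*% t(components)`).
#' @export
pca_reconstruct <- function(basis, scores) {
  scores <- as.matrix(scores)
  k <- ncol(scores)
  sweep(scores %*% t(basis$components[, seq_len(k), drop = FALSE]),
        2L, basis$mean, `+`)
}

#' Fit a binary LDA model
#'
#' Gaussian classes with a shared covariance: per-class mean feature
#' vectors plus the pooled within-class covariance (divisor `n - 2`), with
#' a small ridge added to the diagonal to keep high-PC fits on small folds
#' well conditioned. Priors are uniform, so classification reduces to the
#' minimum Mahalanobis distance rule.
#'
#' @param features numeric matrix of feature vectors (rows = observations).
#' @param labels factor or character vector with exactly two levels; the
#'   first level is the negative class, the second the positive class.
#' @param regularization ridge added to the covariance diagonal; default
#'   `1e-8 * trace/dim`. Pass `0` to disable.
#' @return An `lda_model` with `class_labels` (negative, positive),
#'   `class_means`, `pooled_covariance`, `priors`, `regularization` and a
#'   cached Cholesky factor.
#' @export
lda_fit <- function(features, labels, regularization = NULL) {
  features <- as.matrix(features)
  labels <- as.factor(labels)
  lev <- levels(droplevels(labels))
  if (length(lev) != 2L)
    stop("binary LDA needs exactly 2 classes, got ", length(lev))
  n <- nrow(features)
  cnt <- table(labels)[lev]
  if (any(cnt < 2L))
    stop("each class needs >= 2 members (got ",
         paste(cnt, collapse = "/"), ")")
  p <- ncol(features)
  means <- rbind(colMeans(features[labels == lev[1], , drop = FALSE]),
                 colMeans(features[labels == lev[2], , drop = FALSE]))
  rownames(means) <- lev
  s <- matrix(0, p, p)
  for (g in lev) {
    xg <- sweep(features[labels == g, , drop = FALSE], 2L, means[g, ])
    s <- s + crossprod(xg)
  }
  s <- s / (n - 2)
  if (is.null(regularization))
    regularization <- 1e-8 * sum(diag(s)) / p
  sig <- s + diag(regularization, p)
  ch <- tryCatch(chol(sig), error = function(e) NULL)
  if (is.null(ch))
    stop("pooled covariance is singular; use fewer PCs or a larger ",
         "regularization (n = ", n, ", dim = ", p, ")")
  structure(list(class_labels = lev, class_means = means,
                 pooled_covariance = sig,
                 priors = c(0.5, 0.5), regularization = regularization,
                 chol = ch),
            class = "lda_model")
}

#' Classify feature vectors by minimum Mahalanobis distance
#'
#' With uniform priors and a shared covariance the LDA rule assigns the
#' class whose mean is nearest in squared Mahalanobis distance
#' `d^2(x, mu_k) = (x - mu_k)' Sigma^-1 (x - mu_k)`. Ties go to the
#' negative (first) class.
#'
#' @param model an [lda_fit()] result.
#' @param features numeric vector or matrix of feature vectors.
#' @return List with `labels` (character) and `distances` (n x 2 matrix of
#'   squared Mahalanobis distances, columns in `model$class_labels` order).
#' @export
lda_predict <- function(model, features) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L)
  p <- ncol(model$class_means)
  if (ncol(features) != p)
    stop("feature dimension ", ncol(features),
         " does not match model (", p, ")")
  d2 <- sapply(seq_len(2L), function(k) {
    z <- backsolve(model$chol,
                   t(sweep(features, 2L, model$class_means[k, ])),
                   transpose = TRUE)
    colSums(z^2)
  })
  d2 <- matrix(d2, ncol = 2L,
               dimnames = list(NULL, model$class_labels))
  lab <- unname(ifelse(d2[, 2L] < d2[, 1L],
                       model$class_labels[2L], model$class_labels[1L]))
  list(labels = lab, distances = d2)
}

TASK_IDS <- c("normal-vs-abnormal", "NIH/3T3-vs-MBM-T",
              "NFC-vs-NIH/3T3", "NFC-vs-MBM-T")

#' Define a binary classification task
#'
#' Encodes the positive-class conventions: the pooled abnormal category
#' (NIH/3T3 + MBM-T) is positive against NFC; MBM-T is positive in any pure
#' pairing that contains it; NIH/3T3 is positive against NFC.
#'
#' @param task_id one of `r toString(TASK_IDS)`.
#' @return A `binary_task` with `task_id`, `negative` / `positive` label
#'   sets, and `negative_name` / `positive_name` display names.
#' @export
make_task <- function(task_id) {
  if (!task_id %in% TASK_IDS)
    stop("unknown task_id '", task_id, "'; valid: ", toString(TASK_IDS))
  def <- switch(task_id,
    "normal-vs-abnormal" = list(neg = "NFC", pos = c("NIH/3T3", "MBM-T"),
                                nn = "NFC", pn = "abnormal"),
    "NIH/3T3-vs-MBM-T"   = list(neg = "NIH/3T3", pos = "MBM-T",
                                nn = "NIH/3T3", pn = "MBM-T"),
    "NFC-vs-NIH/3T3"     = list(neg = "NFC", pos = "NIH/3T3",
                                nn = "NFC", pn = "NIH/3T3"),
    "NFC-vs-MBM-T"       = list(neg = "NFC", pos = "MBM-T",
                                nn = "NFC", pn = "MBM-T"))
  structure(list(task_id = task_id, negative = def$neg,
                 positive = def$pos, negative_name = def$nn,
                 positive_name = def$pn),
            class = "binary_task")
}

#' Map raw class labels to a task's negative/positive coding
#'
#' Labels outside the task's classes are returned as `NA` (excluded); the
#' number excluded is attached as attribute `n_excluded`.
#'
#' @param task a [make_task()] result.
#' @param labels character vector of raw class labels.
#' @return Factor with levels `c("negative", "positive")`, `NA` for
#'   excluded labels.
#' @export
apply_task <- function(task, labels) {
  out <- rep(NA_character_, length(labels))
  out[labels %in% task$negative] <- "negative"
  out[labels %in% task$positive] <- "positive"
  res <- factor(out, levels = c("negative", "positive"))
  attr(res, "n_excluded") <- sum(is.na(out))
  res
}

#' Serialize a fitted PCA basis and LDA model to JSON
#'
#' @param pca a [pca_fit()] result (or `NULL`).
#' @param lda an [lda_fit()] result (or `NULL`).
#' @param path output path.
#' @param n_pcs number of components retained for classification.
#' @return `path`, invisibly.
#' @export
write_model <- function(path, pca = NULL, lda = NULL, n_pcs = NULL) {
  obj <- list(format = "ramancell-model", version = 1L, n_pcs = n_pcs)
  if (!is.null(pca))
    obj$pca <- list(mean = pca$mean,
                    components = as.vector(pca$components),
                    dim = dim(pca$components),
                    eigenvalues = pca$eigenvalues)
  if (!is.null(lda))
    obj$lda <- list(class_labels = lda$class_labels,
                    class_means = as.vector(lda$class_means),
                    dim = dim(lda$class_means),
                    pooled_covariance = as.vector(lda$pooled_covariance),
                    priors = lda$priors,
                    regularization = lda$regularization)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model written by [write_model()]
#' @param path JSON model path.
#' @return List with `pca`, `lda`, `n_pcs` components (those present).
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "ramancell-model"))
    stop("not a ramancell model file: ", path)
  out <- list(n_pcs = obj$n_pcs)
  if (!is.null(obj$pca)) {
    comp <- matrix(obj$pca$components, obj$pca$dim[1], obj$pca$dim[2])
    out$pca <- structure(list(mean = obj$pca$mean, components = comp,
                              eigenvalues = obj$pca$eigenvalues),
                         class = "pca_basis")
  }
  if (!is.null(obj$lda)) {
    mns <- matrix(obj$lda$class_means, obj$lda$dim[1], obj$lda$dim[2],
                  dimnames = list(obj$lda$class_labels, NULL))
    sig <- matrix(obj$lda$pooled_covariance, obj$lda$dim[2], obj$lda$dim[2])
    out$lda <- structure(list(class_labels = obj$lda$class_labels,
                              class_means = mns, pooled_covariance = sig,
                              priors = obj$lda$priors,
                              regularization = obj$lda$regularization,
                              chol = chol(sig)),
                         class = "lda_model")
  }
  out
}
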