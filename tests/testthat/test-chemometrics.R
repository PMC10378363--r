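test_that("pca_fit matches a dense covariance eigendecomposition oracle", {
  set.seed(11)
  x <- matrix(rnorm(20 * 50), 20, 50)
  basis <- pca_fit(x)
  eo <- eigen(cov(x), symmetric = TRUE)
  k <- 19                              # rank of 20 centred rows
  expect_equal(basis$eigenvalues[1:k], eo$values[1:k], tolerance = 1e-8)
  for (j in 1:k) {
    v <- eo$vectors[, j]
    expect_equal(abs(sum(v * basis$components[, j])), 1,
                 tolerance = 1e-8)     # same direction up to sign
  }
  # orthonormality and ordering invariants
  g <- crossprod(basis$components[, 1:k])
  expect_equal(g, diag(k), tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(basis$eigenvalues) <= 1e-10))
  # sign convention: largest-magnitude element positive
  for (j in 1:k)
    expect_gt(basis$components[which.max(abs(basis$components[, j])), j], 0)
})

test_that("pca_fit handles rank-1 and degenerate data", {
  set.seed(2)
  v <- rnorm(30); v <- v / sqrt(sum(v^2))
  m <- rnorm(30)
  x <- t(sapply(rnorm(15), function(a) m + a * v))
  basis <- pca_fit(x)
  expect_gt(basis$eigenvalues[1] / sum(basis$eigenvalues), 0.999)
  expect_equal(abs(sum(v * basis$components[, 1])), 1, tolerance = 1e-8)
  dup <- matrix(1, 5, 4) * rnorm(4)[col(matrix(1, 5, 4))]
  expect_lt(max(pca_fit(dup)$eigenvalues), 1e-12)
  expect_error(pca_fit(matrix(1, 1, 4)), "at least 2")
})

test_that("pca_project/reconstruct satisfy the projection contracts", {
  set.seed(3)
  x <- matrix(rnorm(12 * 30), 12, 30)
  basis <- pca_fit(x)
  expect_equal(as.numeric(pca_project(basis, basis$mean, 5)), rep(0, 5))
  s <- basis$mean + 2 * basis$components[, 1]
  z <- as.numeric(pca_project(basis, s, 4))
  expect_equal(z, c(2, 0, 0, 0), tolerance = 1e-8)
  # full-basis reconstruction and monotone truncation error
  full <- ncol(basis$components)
  err <- sapply(1:full, function(k) {
    xr <- pca_reconstruct(basis, pca_project(basis, x, k))
    sqrt(sum((x - xr)^2))
  })
  expect_lt(err[full], 1e-8)
  expect_true(all(diff(err) <= 1e-8))
  expect_error(pca_project(basis, x, full + 1), "n_pcs")
  expect_error(pca_project(basis, x[, 1:10], 2), "does not match")
})

test_that("lda_fit recovers means and the pooled-scatter oracle", {
  x <- rbind(matrix(0, 4, 2), matrix(1, 4, 2))
  y <- rep(c("negative", "positive"), each = 4)
  m <- lda_fit(x, y, regularization = 1e-6)
  expect_equal(unname(m$class_means),
               rbind(c(0, 0), c(1, 1)))
  # explicit-summation pooled covariance oracle on random data
  set.seed(9)
  x <- matrix(rnorm(30 * 3), 30, 3)
  y <- rep(c("a", "b"), times = c(13, 17))
  m <- lda_fit(x, y, regularization = 0)
  s <- matrix(0, 3, 3)
  for (g in c("a", "b")) {
    xg <- x[y == g, , drop = FALSE]
    mu <- colMeans(xg)
    for (i in seq_len(nrow(xg)))
      s <- s + tcrossprod(xg[i, ] - mu)
  }
  expect_equal(m$pooled_covariance, s / (30 - 2), tolerance = 1e-10)
  expect_error(lda_fit(x, rep("a", 30)), "2 classes")
  expect_error(lda_fit(x[1:3, ], c("a", "a", "b")), ">= 2 members")
})

test_that("lda_fit mean recovery on simulated Gaussian classes", {
  set.seed(123)
  n <- 500
  x <- rbind(cbind(rnorm(n, -1), rnorm(n)), cbind(rnorm(n, 1), rnorm(n)))
  y <- rep(c("negative", "positive"), each = n)
  m <- lda_fit(x, y)
  expect_lt(max(abs(m$class_means - rbind(c(-1, 0), c(1, 0)))), 0.15)
})

test_that("singular covariance without regularization raises", {
  x <- matrix(rnorm(8), 4, 2)
  x <- cbind(x, x[, 1] + x[, 2])      # exactly collinear feature
  y <- c("a", "a", "b", "b")
  expect_error(lda_fit(x, y, regularization = 0), "singular")
  expect_s3_class(lda_fit(x, y), "lda_model")   # default ridge rescues
})

test_that("lda_predict agrees with the explicit quadratic-form oracle", {
  set.seed(17)
  x <- rbind(matrix(rnorm(40 * 4), 40, 4),
             matrix(rnorm(40 * 4, mean = 0.8), 40, 4))
  y <- rep(c("negative", "positive"), each = 40)
  m <- lda_fit(x, y)
  feats <- matrix(rnorm(200 * 4, mean = 0.4), 200, 4)
  pred <- lda_predict(m, feats)
  sinv <- solve(m$pooled_covariance)
  for (i in 1:200) {
    d <- sapply(1:2, function(k) {
      v <- feats[i, ] - m$class_means[k, ]
      drop(t(v) %*% sinv %*% v)
    })
    expect_equal(unname(pred$distances[i, ]), d, tolerance = 1e-8)
    expect_identical(pred$labels[i],
                     m$class_labels[if (d[2] < d[1]) 2 else 1])
  }
})

test_that("prediction at a class mean and tie-breaking", {
  x <- rbind(matrix(rnorm(20), 10, 2), matrix(rnorm(20, 3), 10, 2))
  y <- rep(c("negative", "positive"), each = 10)
  m <- lda_fit(x, y)
  at_mean <- lda_predict(m, m$class_means["positive", ])
  expect_identical(at_mean$labels, "positive")
  expect_equal(unname(at_mean$distances[1, "positive"]), 0)
  # symmetric construction: exact tie goes to the negative class
  m$class_means <- rbind(negative = c(-1, 0), positive = c(1, 0))
  m$pooled_covariance <- diag(2)
  m$chol <- chol(diag(2))
  tie <- lda_predict(m, c(0, 5))
  expect_equal(unname(tie$distances[1, 1]), unname(tie$distances[1, 2]))
  expect_identical(tie$labels, "negative")
  expect_error(lda_predict(m, c(1, 2, 3)), "dimension")
})

test_that("LDA decision is invariant to invertible linear feature maps", {
  set.seed(5)
  x <- rbind(matrix(rnorm(30 * 3), 30, 3),
             matrix(rnorm(30 * 3, 1), 30, 3))
  y <- rep(c("negative", "positive"), each = 30)
  te <- matrix(rnorm(50 * 3, 0.5), 50, 3)
  a <- matrix(c(2, 0.3, -1, 0.5, 1.5, 0.2, 0, -0.7, 1.1), 3, 3)
  base <- lda_predict(lda_fit(x, y, regularization = 0), te)$labels
  mapped <- lda_predict(lda_fit(x %*% a, y, regularization = 0),
                        te %*% a)$labels
  expect_identical(base, mapped)
})

test_that("uniform-prior LDA yields a linear decision boundary", {
  set.seed(19)
  x <- rbind(matrix(rnorm(100 * 2), 100, 2),
             matrix(rnorm(100 * 2, 1.5), 100, 2))
  y <- rep(c("negative", "positive"), each = 100)
  m <- lda_fit(x, y)
  # difference of the two quadratic forms must be affine in the feature
  g <- expand.grid(x1 = seq(-2, 3, 0.5), x2 = seq(-2, 3, 0.5))
  d <- lda_predict(m, as.matrix(g))$distances
  delta <- d[, 2] - d[, 1]
  fit <- lm(delta ~ x1 + x2, data = g)
  expect_lt(max(abs(residuals(fit))), 1e-6)
})

test_that("make_task encodes the positive-class conventions", {
  labels <- c(rep("NFC", 169), rep("NIH/3T3", 136), rep("MBM-T", 152))
  t1 <- make_task("normal-vs-abnormal")
  y1 <- apply_task(t1, labels)
  expect_identical(sum(y1 == "negative", na.rm = TRUE), 169L)
  expect_identical(sum(y1 == "positive", na.rm = TRUE), 288L)
  expect_identical(attr(y1, "n_excluded"), 0L)

  y2 <- apply_task(make_task("NFC-vs-MBM-T"), labels)
  expect_identical(attr(y2, "n_excluded"), 136L)  # NIH/3T3 excluded
  expect_true(all(is.na(y2[labels == "NIH/3T3"])))

  # MBM-T positive whenever present pure; NIH/3T3 positive vs NFC
  expect_identical(make_task("NIH/3T3-vs-MBM-T")$positive, "MBM-T")
  expect_identical(make_task("NFC-vs-MBM-T")$positive, "MBM-T")
  expect_identical(make_task("NFC-vs-NIH/3T3")$positive, "NIH/3T3")
  expect_error(make_task("cats-vs-dogs"), "unknown task_id")
})

test_that("model serialization round trips through JSON", {
  set.seed(33)
  x <- matrix(rnorm(20 * 6), 20, 6)
  basis <- pca_fit(x)
  y <- rep(c("negative", "positive"), 10)
  m <- lda_fit(pca_project(basis, x, 3), y)
  p <- withr::local_tempfile(fileext = ".json")
  write_model(p, pca = basis, lda = m, n_pcs = 3)
  back <- read_model(p)
  expect_equal(back$pca$components, basis$components, tolerance = 1e-12)
  expect_equal(back$lda$class_means, m$class_means, tolerance = 1e-12)
  te <- matrix(rnorm(5 * 3), 5, 3)
  expect_identical(lda_predict(back$lda, te)$labels,
                   lda_predict(m, te)$labels)
})
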