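test_that("compute_metrics matches hand arithmetic and flags undefined", {
  m <- compute_metrics(confusion_matrix(50, 0, 0, 50))
  expect_equal(unname(m), rep(100, 5))
  m <- compute_metrics(confusion_matrix(30, 10, 5, 55))
  expect_equal(m[["ACC"]], 85.0)
  expect_equal(m[["SE"]], 75.0)
  expect_equal(m[["SP"]], 91.667, tolerance = 1e-4)
  expect_equal(m[["PPV"]], 85.714, tolerance = 1e-4)
  expect_equal(m[["NPV"]], 84.615, tolerance = 1e-4)
  # zero positive truth: SE undefined; zero predicted positive: PPV too
  m <- compute_metrics(confusion_matrix(0, 0, 5, 95))
  expect_true(is.na(m[["SE"]]))
  expect_true(is.na(m[["NPV"]]) == FALSE)
  expect_equal(m[["SP"]], 95.0)
  m2 <- compute_metrics(confusion_matrix(0, 5, 0, 95))
  expect_true(is.na(m2[["PPV"]]))
  expect_error(confusion_matrix(0, 0, 0, 0), "all-zero")
  expect_error(confusion_matrix(-1, 0, 0, 5), "non-negative")
})

test_that("kfold_split partitions, balances and respects the seed", {
  labels <- c(rep("NFC", 169), rep("NIH/3T3", 136), rep("MBM-T", 152))
  cfg <- cv_config(k = 5, seed = 42)
  f <- kfold_split(labels, cfg)
  expect_length(f, 457L)
  expect_setequal(unique(f), 1:5)
  expect_true(all(table(f) %in% c(91, 92)))        # overall balance
  for (g in unique(labels)) {                      # per-stratum balance
    t <- table(f[labels == g])
    expect_lte(max(t) - min(t), 1)
  }
  expect_identical(kfold_split(labels, cfg), f)    # determinism
  expect_false(identical(kfold_split(labels, cv_config(k = 5, seed = 43)),
                         f))
  # stratified two-class ratios within one entry of global per fold
  lab2 <- rep(c("neg", "pos"), times = c(169, 288))
  f2 <- kfold_split(lab2, cv_config(k = 5, seed = 1))
  for (k in 1:5) {
    expect_true(abs(sum(lab2[f2 == k] == "neg") - 169 / 5) <= 1)
    expect_true(abs(sum(lab2[f2 == k] == "pos") - 288 / 5) <= 1)
  }
  expect_error(kfold_split(c("a", "a", "b"), cv_config(k = 2)),
               "fewer than k")
})

test_that("kfold_split keeps grouped cells together", {
  labels <- rep(c("a", "b"), each = 30)
  cells <- paste0("c", rep(1:20, each = 3))
  f <- kfold_split(labels, cv_config(k = 4, seed = 3), cell_id = cells)
  expect_true(all(tapply(f, cells, function(v) length(unique(v))) == 1))
})

test_that("run_cv is perfect in the separable limit and counts entries", {
  set.seed(50)
  n <- 40L
  x <- rbind(matrix(rnorm(n * 20), n, 20),
             matrix(rnorm(n * 20, mean = 50), n, 20))
  db <- structure(list(database_id = "I", site_rule = "average",
                       cell_id = as.character(1:(2 * n)),
                       class_label = rep(c("NFC", "MBM-T"), each = n),
                       grid = seq_len(20), spectra = x),
                  class = "raman_database")
  res <- run_cv(db, "NFC-vs-MBM-T", n_pcs = 2, cv_config(seed = 7))
  expect_equal(res$metrics[["ACC"]], 100)
  expect_equal(res$metrics[["acc_std"]], 0)
  # every entry tested exactly once: counts sum to task size
  cm <- res$confusion
  expect_identical(cm$TP + cm$FN + cm$FP + cm$TN, 2L * n)
  expect_identical(cm$TP + cm$FN, n)   # positives = MBM-T entries
})

test_that("accuracy_vs_pcs matches run_cv pointwise with shared folds", {
  man <- generate_dataset(small_sim_config(), seed = 77)
  db <- build_database(preprocess_manifest(man), "I")
  cv <- cv_config(seed = 5)
  curve <- accuracy_vs_pcs(db, "NFC-vs-MBM-T", cv, max_pcs = 8)
  expect_identical(nrow(curve), 8L)
  expect_true(all(curve$mean_accuracy >= 0 & curve$mean_accuracy <= 100))
  for (np in c(1L, 4L, 8L)) {
    res <- run_cv(db, "NFC-vs-MBM-T", np, cv)
    expect_identical(paste(res$folds, collapse = ","),
                     attr(curve, "fold_hash"))
    expect_equal(curve$mean_accuracy[np], res$metrics[["ACC"]])
    expect_equal(curve$acc_std[np], res$metrics[["acc_std"]])
  }
})

test_that("select_n_pcs agrees with the brute-force scan oracle", {
  curve <- data.frame(n_pcs = 1:6,
                      mean_accuracy = c(80, 90, 93, 93.1, 93.0, 93.05))
  expect_identical(select_n_pcs(curve, 0.5), 3L)
  expect_identical(select_n_pcs(data.frame(n_pcs = 1:4,
                                           mean_accuracy = c(1, 2, 3, 4)),
                                0.5), 4L)   # strictly increasing -> last
  expect_identical(select_n_pcs(data.frame(n_pcs = 1:4,
                                           mean_accuracy = rep(9, 4)),
                                0.5), 1L)   # constant -> first
  set.seed(61)
  for (i in 1:1000) {
    acc <- runif(sample(2:30, 1), 0, 100)
    tol <- runif(1, 0, 5)
    cv <- data.frame(n_pcs = seq_along(acc), mean_accuracy = acc)
    expect_identical(select_n_pcs(cv, tol), select_oracle(acc, tol))
  }
  # monotone in tolerance: larger tolerance never selects more PCs
  set.seed(62)
  for (i in 1:200) {
    acc <- runif(15, 50, 100)
    cv <- data.frame(n_pcs = 1:15, mean_accuracy = acc)
    tols <- sort(runif(2, 0, 10))
    expect_lte(select_n_pcs(cv, tols[2]), select_n_pcs(cv, tols[1]))
  }
})

test_that("subrange analysis separates a range-confined class signal", {
  # class effect confined to the 700-800 cm^-1 triplet: the carbohydrate
  # range must beat the amide range decisively
  eff <- list("NFC" = rep(1, 35),
              "MBM-T" = class_effect(c(721, 750, 781),
                                     c(0.6, 0.7, 0.7)))
  cfg <- sim_config(n_cells = c("NFC" = 30L, "MBM-T" = 30L),
                    site_counts = NULL, class_effects = eff,
                    pattern_sd = 0)
  db <- build_database(preprocess_manifest(generate_dataset(cfg, 91)), "I")
  cv <- cv_config(seed = 9)
  carb <- run_cv(cut_database(db, 600, 1195), "NFC-vs-MBM-T", 3, cv)
  amide <- run_cv(cut_database(db, 1521, 1728), "NFC-vs-MBM-T", 3, cv)
  expect_gte(carb$metrics[["ACC"]] - amide$metrics[["ACC"]], 10)
})

test_that("degenerate full-range subrange reproduces the full run", {
  man <- generate_dataset(small_sim_config(), seed = 31)
  db <- build_database(preprocess_manifest(man), "I")
  cv <- cv_config(seed = 4)
  full <- run_cv(db, "NFC-vs-NIH/3T3", 5, cv)
  sub <- run_cv(cut_database(db, 600, 1800), "NFC-vs-NIH/3T3", 5, cv)
  expect_identical(sub$confusion, full$confusion)
  expect_identical(sub$fold_accuracies, full$fold_accuracies)
})

test_that("subrange_analysis returns the 4x4 table", {
  man <- generate_dataset(small_sim_config(), seed = 13)
  db <- build_database(preprocess_manifest(man), "I")
  tab <- subrange_analysis(db, tasks = c("NFC-vs-MBM-T",
                                         "NIH/3T3-vs-MBM-T"),
                           cv = cv_config(seed = 2), max_pcs = 6)
  expect_identical(nrow(tab), 8L)   # 2 tasks x 4 ranges
  expect_setequal(unique(tab$range), default_subranges()$name)
  expect_true(all(tab$n_pcs >= 1 & tab$n_pcs <= 6))
  expect_true(all(tab$ACC >= 0 & tab$ACC <= 100))
})

test_that("difference spectra locate injected effects, antisymmetric", {
  # identical class distributions -> differences within noise
  eff0 <- list("NFC" = rep(1, 35), "MBM-T" = rep(1, 35))
  cfg0 <- sim_config(n_cells = c("NFC" = 25L, "MBM-T" = 25L),
                     site_counts = NULL, class_effects = eff0,
                     pattern_sd = 0)
  d0 <- difference_spectra(preprocess_manifest(generate_dataset(cfg0, 3)),
                           sites = "center")$center
  sem <- sqrt(d0$sd["NFC", ]^2 / d0$n[["NFC"]] +
              d0$sd["MBM-T", ]^2 / d0$n[["MBM-T"]])
  expect_lt(mean(abs(d0$diff[["NFC - MBM-T"]]) > 3 * sem), 0.05)

  # effect injected at 1443 only -> |delta| peaks within +/-5 cm^-1
  eff1 <- list("NFC" = rep(1, 35),
               "MBM-T" = class_effect(1443, 0.5))
  cfg1 <- sim_config(n_cells = c("NFC" = 25L, "MBM-T" = 25L),
                     site_counts = NULL, class_effects = eff1,
                     pattern_sd = 0)
  man1 <- preprocess_manifest(generate_dataset(cfg1, 4))
  d1 <- difference_spectra(man1, sites = "center")$center
  delta <- d1$diff[["NFC - MBM-T"]]
  expect_lt(abs(d1$grid[which.max(abs(delta))] - 1443), 5)
  # antisymmetry: delta(A,B) = -delta(B,A) by construction of class means
  expect_equal(d1$mean["NFC", ] - d1$mean["MBM-T", ], delta)
})
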