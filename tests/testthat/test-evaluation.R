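# AUC, cross-validation, threshold scans and the grid search.

test_that("auc_mw matches pair enumeration, including ties", {
  expect_identical(auc_mw(c(3, 2, 1), c(1, 0, 1)), 0.5)
  expect_identical(auc_mw(c(5, 4, 1), c(1, 1, 0)), 1)
  expect_identical(auc_mw(rep(2, 6), c(1, 1, 0, 0, 0, 1)), 0.5)
  withr::with_seed(13, {
    for (rep in 1:200) {
      n <- sample(4:12, 1)
      scores <- sample(seq(0, 1, 0.25), n, replace = TRUE)  # force ties
      labels <- c(1L, 0L, sample(0:1, n - 2, replace = TRUE))
      expect_equal(auc_mw(scores, labels), oracle_auc(scores, labels),
                   tolerance = 1e-12)
    }
  })
  expect_error(auc_mw(1:3, c(1, 1, 1)), "both classes")
})

test_that("a two-structure dataset scores a single pair without error", {
  sets <- list(c("a", "b"), c("b", "c"))
  fit <- sprpep:::.spr_fit_sets(sets, c(1L, 0L), 0L, NA_integer_, "t")
  a <- auc_mw(fit$loo_scores, fit$labels)
  expect_true(a %in% c(0, 0.5, 1))
})

test_that("LOO AUC is invariant under dataset shuffling", {
  sim <- simulate_resistance_data(n_substitutions = 80, seq_length = 250,
                                  positive_fraction = 0.25,
                                  signal_strength = 0.6, seed = 8)
  ds <- build_dataset(sim$substitutions, sim$protein, "resistance", 5)
  a1 <- loo_auc(ds, level = 1)
  shuf <- withr::with_seed(1, ds[sample(nrow(ds)), ])
  expect_equal(loo_auc(shuf, level = 1), a1, tolerance = 1e-12)
})

test_that("k = N folds reduce k-fold CV to leave-one-out exactly", {
  sim <- simulate_resistance_data(n_substitutions = 40, seq_length = 150,
                                  positive_fraction = 0.3,
                                  signal_strength = 0.6, seed = 5)
  ds <- build_dataset(sim$substitutions, sim$protein, "resistance", 3)
  expect_equal(kfold_auc(ds, level = 1, k = nrow(ds), seed = 3),
               loo_auc(ds, level = 1), tolerance = 1e-12)
  # seeded determinism
  expect_identical(kfold_auc(ds, level = 1, k = 5, seed = 11),
                   kfold_auc(ds, level = 1, k = 5, seed = 11))
  expect_error(kfold_auc(ds, level = 1, k = 1), "at least 2")
})

test_that("confusion metrics are the three stated ratios", {
  m <- confusion_metrics(1, 0, 1, 0)
  expect_identical(unlist(m), c(sensitivity = 1, specificity = 1,
                                balanced_accuracy = 1))
  m2 <- confusion_metrics(6, 2, 8, 4)
  expect_equal(m2$sensitivity, 0.6)
  expect_equal(m2$specificity, 0.8)
  expect_equal(m2$balanced_accuracy, 0.7)
  expect_error(confusion_metrics(0, 3, 2, 0), "empty class margin")
})

test_that("threshold scan rows behave monotonically in the cut-off", {
  # model-shaped predictions: Pa and Pi come from the fitted calibration
  sim <- simulate_resistance_data(n_substitutions = 150, seq_length = 400,
                                  positive_fraction = 0.2,
                                  signal_strength = 0.9, seed = 18)
  ds <- build_dataset(sim$substitutions, sim$protein, "resistance", 5)
  model <- spr_fit(ds, level = 1)
  preds <- predict(model, ds)
  scan <- threshold_scan(preds, ds$label)
  expect_identical(scan$rule[1], "Pa > Pi")
  fixed <- scan[-1, ]
  expect_true(all(diff(fixed$FP) <= 0))
  expect_true(all(diff(fixed$TP) <= 0))
  expect_identical(scan$TP + scan$FN,
                   rep(sum(ds$label), nrow(scan)))
  # the permissive default rule dominates sensitivity
  expect_identical(max(scan$sensitivity), scan$sensitivity[1])
})

test_that("an all-positive, all-confident scan puts everything in TP", {
  preds <- tibble::tibble(Pa = rep(1, 4), Pi = rep(0, 4))
  scan <- threshold_scan(preds, rep(1L, 4))
  expect_identical(scan$TP, rep(4L, nrow(scan)))
  expect_identical(scan$FP + scan$TN + scan$FN, rep(0L, nrow(scan)))
  expect_true(all(is.na(scan$specificity)))
})

test_that("a 2x2 grid returns 4 cells and a deterministic best", {
  sim <- simulate_resistance_data(n_substitutions = 60, seq_length = 200,
                                  positive_fraction = 0.3,
                                  signal_strength = 0.6, seed = 6)
  grid <- spr_grid(sim$substitutions, sim$protein, "resistance",
                   lengths = c(3, 5), levels = c(1, 2))
  expect_identical(nrow(tidy(grid)), 4L)
  expect_identical(nrow(grid$summary), 4L)
  expect_identical(nrow(glance(grid)), 1L)
  expect_identical(glance(grid)$avg_auc, max(grid$summary$avg_auc))
  # single endpoint: average equals the endpoint AUC cell by cell
  joined <- dplyr::left_join(grid$summary, tidy(grid),
                             by = c("length", "level"))
  expect_equal(joined$avg_auc, joined$auc)
})

test_that("grid averaging over endpoints is the arithmetic mean", {
  sim <- simulate_resistance_data(n_substitutions = 50, seq_length = 180,
                                  positive_fraction = 0.3,
                                  signal_strength = 0.6, seed = 14)
  subs <- sim$substitutions
  withr::with_seed(15, {
    subs$second <- sample(subs$resistance)
  })
  grid <- spr_grid(subs, sim$protein, c("resistance", "second"),
                   lengths = 3, levels = 1)
  expect_identical(nrow(tidy(grid)), 2L)
  expect_equal(grid$summary$avg_auc, mean(tidy(grid)$auc))
})

test_that("the grid concentrates on short windows when the signal is local", {
  # signal planted within +/-2 residues: the best window should usually
  # be 7 residues or shorter (chance over the scanned lengths is 3/5)
  hits <- 0L
  for (sd in 1:5) {
    sim <- simulate_resistance_data(n_substitutions = 200, seq_length = 500,
                                    positive_fraction = 0.18,
                                    signal_strength = 0.9, motif_radius = 2,
                                    seed = sd)
    grid <- spr_grid(sim$substitutions, sim$protein, "resistance",
                     lengths = c(3, 5, 7, 9, 11), levels = 2)
    if (glance(grid)$length <= 7) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("autoplot methods return ggplot objects", {
  sim <- simulate_resistance_data(n_substitutions = 40, seq_length = 150,
                                  positive_fraction = 0.3,
                                  signal_strength = 0.6, seed = 9)
  ds <- build_dataset(sim$substitutions, sim$protein, "resistance", 3)
  model <- spr_fit(ds, level = 1)
  grid <- spr_grid(sim$substitutions, sim$protein, "resistance",
                   lengths = 3, levels = 1)
  expect_s3_class(autoplot(model), "ggplot")
  expect_s3_class(autoplot(grid), "ggplot")
  preds <- predict(model, ds)
  expect_s3_class(plot_threshold_scan(threshold_scan(preds, ds$label)),
                  "ggplot")
})
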