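test_that("metrics follow their defining formulas", {
  m <- compute_metrics(confusion_counts(true = c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0),
                                        pred = c(1, 1, 1, 0, 0, 0, 0, 0, 0, 1)))
  expect_equal(unname(m), c(0.7, 0.75, 0.6, 2 * (0.75 * 0.6) / 1.35),
               tolerance = 1e-12)
  perfect <- compute_metrics(list(TP = 5, FP = 0, TN = 5, FN = 0))
  expect_equal(unname(perfect), c(1, 1, 1, 1))
  w <- capture_warnings(z <- compute_metrics(list(TP = 0, FP = 0, TN = 5, FN = 5)))
  expect_match(w, "precision", all = FALSE)
  expect_equal(z[["Prec"]], 0)
  expect_error(compute_metrics(list(TP = -1, FP = 0, TN = 0, FN = 0)),
               "non-negative")
})

test_that("count-based and prediction-based metric paths agree", {
  set.seed(71)
  for (i in 1:5) {
    true <- sample(0:1, 40, replace = TRUE)
    pred <- ifelse(runif(40) < 0.3, 1 - true, true)
    cc <- confusion_counts(true, pred)
    expect_equal(cc$TP + cc$FP + cc$TN + cc$FN, 40)
    # naive loop oracle for accuracy
    acc <- sum(vapply(seq_along(true), function(i) true[i] == pred[i], NA)) / 40
    expect_equal(suppressWarnings(compute_metrics(cc))[["Acc"]], acc)
  }
})

test_that("stratified folds partition trials and balance classes", {
  lab <- rep(c(0L, 1L), c(40L, 24L))
  folds <- make_stratified_folds(lab, 4L, seed = 3L)
  expect_setequal(folds, 1:4)
  for (f in 1:4) {
    expect_equal(sum(folds == f & lab == 0L), 10L)
    expect_equal(sum(folds == f & lab == 1L), 6L)
  }
  expect_error(make_stratified_folds(rep(0:1, c(3, 60)), 5L), "at least")
})

test_that("cross-validation reports one row per repeat and fold, reproducibly", {
  g <- generate_mi_eeg(synthetic_config(n_trials_per_class = 15L,
                                        duration_s = 2, seed = 5L))
  cfg <- mi_pipeline_config(epoch_window = c(0.5, 2.5), na = 4L, K = 2L,
                            csp_m = 1L, oof_folds = 3L, hidden_units = 10L)
  r1 <- suppressWarnings(cross_validate(g$epochs, cfg, n_folds = 3L,
                                        n_repeats = 2L, seed = 9L))
  expect_equal(nrow(r1$results), 6L)
  expect_true(all(r1$results$Acc >= 0 & r1$results$Acc <= 1))
  expect_gte(r1$mean[["Acc"]], min(r1$results$Acc))
  expect_lte(r1$mean[["Acc"]], max(r1$results$Acc))
  r2 <- suppressWarnings(cross_validate(g$epochs, cfg, n_folds = 3L,
                                        n_repeats = 2L, seed = 9L))
  expect_identical(r1$results, r2$results)
})

test_that("the feature-count sweep reduces to cross-validation and validates its grid", {
  g <- generate_mi_eeg(synthetic_config(n_trials_per_class = 12L,
                                        duration_s = 2, seed = 6L))
  cfg <- mi_pipeline_config(epoch_window = c(0.5, 2.5), na = 4L, K = 2L,
                            csp_m = 1L, oof_folds = 3L, hidden_units = 10L)
  sw <- suppressWarnings(feature_count_sweep(g$epochs, cfg, na_grid = 4L,
                                             n_folds = 3L, seed = 2L))
  cv <- suppressWarnings(cross_validate(g$epochs, cfg, n_folds = 3L,
                                        n_repeats = 1L, seed = 2L))
  expect_equal(sw$mean_acc, cv$mean[["Acc"]])
  expect_error(feature_count_sweep(g$epochs, cfg, na_grid = integer(0)),
               "non-empty")
})

test_that("pipeline artifacts are written and reproducible from the config snapshot", {
  g <- generate_mi_eeg(synthetic_config(n_trials_per_class = 12L,
                                        duration_s = 2, seed = 7L))
  cfg <- mi_pipeline_config(epoch_window = c(0.5, 2.5), na = 3L, K = 2L,
                            csp_m = 1L, oof_folds = 3L, hidden_units = 10L)
  out <- file.path(tempdir(), "mistack-run")
  rep1 <- suppressWarnings(run_pipeline(g$epochs, cfg, out, n_folds = 3L,
                                        n_repeats = 1L, seed = 4L))
  expect_true(file.exists(file.path(out, "cv_report.json")))
  expect_true(file.exists(file.path(out, "cv_folds.tsv")))
  expect_true(file.exists(file.path(out, "config.json")))
  js <- jsonlite::read_json(file.path(out, "cv_report.json"), simplifyVector = TRUE)
  expect_equal(js$mean$Acc, rep1$mean[["Acc"]])
})
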