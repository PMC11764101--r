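test_that("the meta input is four probability blocks plus one discriminant coordinate", {
  fx <- stacking_fixture(n = 60L, seed = 2L)
  sm <- fit_stacking(fx$comp, fx$sig, fx$labels, seed = 2L)
  expect_equal(sm$meta_model$n[1], 4 * 2 + 1) # |domains| * C + (C - 1) = 9
  expect_s3_class(sm$lda_projector, "lda_projector")
  plain <- fit_stacking(fx$comp, fx$sig, fx$labels, lda_supplement = FALSE,
                        seed = 2L)
  expect_equal(plain$meta_model$n[1], 8)
})

test_that("probability outputs are proper distributions and separable data is learned", {
  fx <- stacking_fixture(n = 80L, seed = 3L)
  sm <- fit_stacking(fx$comp, fx$sig, fx$labels, seed = 3L)
  pr <- predict_stacking(sm, fx$comp, fx$sig)
  expect_equal(unname(rowSums(pr$prob)), rep(1, 80), tolerance = 1e-8)
  expect_true(all(pr$prob >= 0 & pr$prob <= 1))
  expect_equal(mean(pr$labels == fx$labels), 1.0) # training-set accuracy
  pr2 <- predict_stacking(sm, fx$comp, fx$sig)
  expect_identical(pr$prob, pr2$prob) # no randomness at predict time
})

test_that("every base-classifier kind plugs into the same architecture", {
  fx <- stacking_fixture(n = 60L, seed = 4L)
  for (kind in c("random_forest", "svm_rbf", "svm_linear")) {
    sm <- suppressWarnings(fit_stacking(fx$comp, fx$sig, fx$labels,
                                        base_kind = kind, oof_folds = 3L,
                                        hidden_units = 20L, seed = 4L))
    pr <- predict_stacking(sm, fx$comp, fx$sig)
    expect_equal(sm$meta_model$n[1], 9)
    expect_equal(unname(rowSums(pr$prob)), rep(1, 60), tolerance = 1e-8)
    expect_gt(mean(pr$labels == fx$labels), 0.8)
  }
  expect_error(fit_stacking(fx$comp[1:3], fx$sig, fx$labels), "same domains")
  expect_error(fit_stacking(fx$comp, fx$sig, rep(0L, 60)), "single class")
})

test_that("the discriminant direction matches the closed-form oracle", {
  set.seed(61)
  n <- 300
  mu <- c(2.5, 0, 0, 0)
  x <- rbind(matrix(rnorm(n * 4), ncol = 4),
             sweep(matrix(rnorm(n * 4), ncol = 4), 2, mu, "+"))
  lab <- rep(0:1, each = n)
  proj <- lda_features(x, lab)
  expect_equal(ncol(proj$projected), 1L) # C - 1 columns
  # oracle: pooled-covariance closed form
  Sw <- (cov(x[lab == 0, ]) + cov(x[lab == 1, ])) / 2
  w0 <- solve(Sw, colMeans(x[lab == 1, ]) - colMeans(x[lab == 0, ]))
  cosine <- sum(proj$w * w0) / sqrt(sum(proj$w^2) * sum(w0^2))
  expect_gt(cosine, 0.99)
  expect_gt(abs(sum(proj$w * c(1, 0, 0, 0))), 0.99) # parallel to axis 1
  # swapping class labels negates the projection
  proj2 <- lda_features(x, 1L - lab)
  expect_equal(proj2$projected, -proj$projected, tolerance = 1e-10)
})

test_that("singular within-class scatter triggers shrinkage, not failure", {
  set.seed(62)
  x <- matrix(rnorm(20 * 30), 20, 30) # p > n
  lab <- rep(0:1, 10)
  expect_warning(proj <- lda_features(x, lab), "shrinkage")
  expect_true(all(is.finite(proj$projected)))
})

test_that("contribution rates normalize over domains and follow planted signal", {
  fx <- stacking_fixture(n = 60L, seed = 5L)
  sm <- fit_stacking(fx$comp, fx$sig, fx$labels, seed = 5L)
  cr <- contribution_rates(sm)
  expect_equal(sum(cr), 100, tolerance = 1e-6)
  expect_named(cr, c("TD", "FD", "TFD", "SD"))
  expect_true(is.finite(attr(cr, "lda_share")))
  # uniform meta weights give 25% per domain
  sm_flat <- sm
  sm_flat$meta_model$wts <- rep(1, length(sm$meta_model$wts))
  expect_equal(unname(contribution_rates(sm_flat)), rep(25, 4),
               tolerance = 1e-8, ignore_attr = TRUE)
  # signal confined to SD dominates on average over seeds
  crs <- sapply(1:10, function(s) {
    fx1 <- stacking_fixture(n = 60L, effects = c(TD = 0, FD = 0, TFD = 0, SD = 2.5),
                            seed = s)
    sm1 <- fit_stacking(fx1$comp, fx1$sig, fx1$labels, seed = s)
    contribution_rates(sm1)
  })
  avg <- rowMeans(crs)
  expect_equal(names(which.max(avg)), "SD")
  expect_gt(avg[["SD"]], 25)
})

test_that("the fitted ensemble serializes and reproduces predictions bit-for-bit", {
  fx <- stacking_fixture(n = 60L, seed = 6L)
  sm <- fit_stacking(fx$comp, fx$sig, fx$labels, seed = 6L)
  path <- tempfile(fileext = ".rds")
  saveRDS(sm, path)
  back <- readRDS(path)
  expect_identical(predict_stacking(back, fx$comp, fx$sig),
                   predict_stacking(sm, fx$comp, fx$sig))
})
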