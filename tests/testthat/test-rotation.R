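test_that("rotation of a diagonal-covariance block is the identity under the sign convention", {
  set.seed(51)
  n <- 400
  # independent columns with strictly descending variances
  x <- sapply(c(4, 2, 1), function(s) rnorm(n, sd = s))
  tr <- fit_rotation(x, K = 1L, resample_fraction = 1, seed = 1L)
  expect_equal(tr$R, diag(3), tolerance = 0.1)
  expect_equal(abs(diag(tr$R)), rep(1, 3), tolerance = 0.05)
})

test_that("assembled rotation matrices are orthogonal and norm-preserving", {
  set.seed(52)
  x <- matrix(rnorm(60 * 9), 60, 9)
  for (K in c(1L, 2L, 4L, 9L)) {
    tr <- fit_rotation(x, K = K, seed = K)
    expect_equal(t(tr$R) %*% tr$R, diag(9), tolerance = 1e-8)
    rot <- apply_rotation(tr, x)
    expect_equal(sqrt(rowSums(rot^2)), sqrt(rowSums(x^2)), tolerance = 1e-8)
    # rotating the rotated output through a refit transform stays orthogonal
    tr2 <- fit_rotation(rot, K = K, seed = K + 1L)
    expect_equal(t(tr2$R) %*% tr2$R, diag(9), tolerance = 1e-8)
  }
})

test_that("size-1 subspaces reduce the rotation to the identity", {
  set.seed(53)
  x <- matrix(rnorm(50 * 5), 50, 5)
  tr <- fit_rotation(x, K = 5L, seed = 2L)
  expect_equal(tr$R, diag(5), tolerance = 1e-12)
  expect_equal(apply_rotation(tr, x), x, ignore_attr = TRUE)
})

test_that("the partition covers all features with balanced block sizes", {
  set.seed(54)
  x <- matrix(rnorm(40 * 11), 40, 11)
  tr <- fit_rotation(x, K = 4L, seed = 3L)
  blocks <- tr$subspace_assignment
  expect_setequal(unlist(blocks), 1:11)
  expect_setequal(lengths(blocks), c(3L, 3L, 3L, 2L)) # 11 = 3+3+3+2
  expect_error(fit_rotation(x, K = 12L), "must not exceed")
})

test_that("rotation is reproducible from its seed and reused on test data", {
  set.seed(55)
  x <- matrix(rnorm(60 * 6), 60, 6)
  lab <- rep(0:1, 30)
  t1 <- fit_rotation(x, K = 3L, labels = lab, seed = 9L)
  t2 <- fit_rotation(x, K = 3L, labels = lab, seed = 9L)
  expect_identical(t1$subspace_assignment, t2$subspace_assignment)
  expect_identical(t1$R, t2$R)
  xtest <- matrix(rnorm(10 * 6), 10, 6)
  expect_equal(apply_rotation(t1, xtest), xtest %*% t1$R, ignore_attr = TRUE)
  expect_error(apply_rotation(t1, xtest[, 1:4]), "mismatch")
})

test_that("constant subspaces fall back to identity coefficients", {
  x <- cbind(matrix(rnorm(40 * 2), 40, 2), 0, 0)
  expect_warning(tr <- fit_rotation(x, K = 2L, seed = 123L), "zero-variance")
  expect_equal(t(tr$R) %*% tr$R, diag(4), tolerance = 1e-8)
})

test_that("composition concatenates rotated then significant columns", {
  set.seed(56)
  sig <- matrix(rnorm(20 * 5), 20, 5)
  tr <- fit_rotation(sig, K = 2L, seed = 1L)
  rot <- apply_rotation(tr, sig)
  comp <- compose_features(sig, rot)
  expect_equal(ncol(comp), 10L)
  expect_equal(attr(comp, "origin"),
               c(rep("rotated", 5), rep("significant", 5)))
  expect_equal(unclass(comp)[, 1:5], rot, ignore_attr = TRUE)
  expect_equal(unclass(comp)[, 6:10], sig, ignore_attr = TRUE)
  expect_error(compose_features(sig, rot[1:10, ]), "mismatch")
  z <- matrix(0, 4, 2)
  expect_true(all(compose_features(z, z) == 0))
})

test_that("composite features do not hurt a fixed classifier relative to significant features", {
  # buffered-average property over 10 seeds on separable feature data
  diffs <- numeric(10)
  for (s in 1:10) {
    gt <- generate_feature_tables(n = 80L, per_domain_effect = c(TD = 1.2),
                                  n_features = 8L, seed = s)
    x <- unclass(gt$tables$TD)
    lab <- gt$labels
    folds <- make_stratified_folds(lab, 5L, seed = s)
    acc <- function(feats) {
      mean(vapply(1:5, function(f) {
        tr <- folds != f; te <- folds == f
        set.seed(s)
        rf <- randomForest::randomForest(feats[tr, , drop = FALSE],
                                         factor(lab[tr]), ntree = 100)
        mean(predict(rf, feats[te, , drop = FALSE]) == lab[te])
      }, 0))
    }
    rot <- fit_rotation(x, K = 3L, labels = lab, seed = s)
    comp <- compose_features(x, apply_rotation(rot, x))
    diffs[s] <- acc(unclass(comp)) - acc(x)
  }
  expect_gte(mean(diffs), -0.02)
})
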