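test_that("kNN with L1 distance matches hand-computed cases and tie rules", {
  tr <- rbind(c(0, 0), c(3, 0))
  y <- factor(c("A", "B"))
  # distances to (1,0): 1 vs 2 -> A
  expect_equal(as.character(knn_predict(tr, y, rbind(c(1, 0)))$y_pred), "A")
  # a test point identical to a training point takes that point's label
  expect_equal(as.character(knn_predict(tr, y, rbind(c(3, 0)))$y_pred), "B")
  # equidistant neighbors at k = 1 -> the lower training index wins
  expect_equal(as.character(knn_predict(tr, y, rbind(c(1.5, 0)))$y_pred), "A")
  expect_error(knn_predict(tr, y, rbind(c(1, 0, 0))), "dimension")
})

test_that("kNN self-prediction with k = 1 reproduces the training labels", {
  fx <- generate_feature_fixture(n_samples = 30, n_features = 10,
                                 n_informative = 3, effect_size = 0.5, seed = 2)
  ps <- knn_predict(fx$X, fx$y, fx$X, k = 1)
  expect_equal(as.character(ps$y_pred), as.character(fx$y))
})

test_that("kNN is equivariant under class relabeling", {
  fx <- generate_feature_fixture(n_samples = 40, n_features = 8,
                                 n_informative = 4, effect_size = 1, seed = 6)
  te <- matrix(rnorm(10 * 8), 10, 8)
  p1 <- knn_predict(fx$X, fx$y, te, k = 3)$y_pred
  relabel <- factor(ifelse(fx$y == "class01", "Z", "Q"), levels = c("Q", "Z"))
  p2 <- knn_predict(fx$X, relabel, te, k = 3)$y_pred
  expect_equal(as.character(p2), ifelse(as.character(p1) == "class01", "Z", "Q"))
})

test_that("accuracy trend over k is non-increasing on well-separated features", {
  # tight multi-modal classes (XOR layout): the nearest neighbor is always
  # within the right mode, while large k pools votes across modes and blurs
  # the decision boundary -- the mechanism behind the k = 1 optimum
  set.seed(9)
  modes <- list(a = rbind(c(0, 0), c(10, 10)), b = rbind(c(10, 0), c(0, 10)))
  X <- NULL; y <- character(0)
  for (cl in names(modes)) for (m in 1:2) {
    X <- rbind(X, sweep(matrix(rnorm(20, 0, 0.1), 10, 2), 2,
                        modes[[cl]][m, ], "+"))
    y <- c(y, rep(cl, 10))
  }
  y <- factor(y)
  plan <- stratified_folds(y, 10, seed = 5)
  accs <- vapply(c(1, 5, 25), function(k)
    mean(cross_validate(X, y, "knn", plan, k = k)$predictions$y_pred == y), 0)
  expect_gte(accs[1], accs[2])
  expect_gte(accs[2], accs[3])
  expect_gt(accs[1], accs[3])   # the trend is strict over the full sweep
  expect_equal(accs[1], 1)
})

test_that("cubic-kernel SVM separates XOR and counts one-vs-one machines", {
  xor_X <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  xor_y <- factor(c("a", "a", "b", "b"))
  ps <- svm_train_predict(xor_X, xor_y, xor_X)
  expect_equal(as.character(ps$y_pred), as.character(xor_y))

  set.seed(3)
  X <- rbind(matrix(rnorm(40, -2), 20, 2), matrix(rnorm(40, 2), 20, 2))
  y <- factor(rep(c("lo", "hi"), each = 20))
  expect_equal(as.character(svm_train_predict(X, y, X)$y_pred),
               as.character(y))

  X3 <- rbind(X, matrix(c(rnorm(20, -2), rnorm(20, 2)), 20, 2))
  y3 <- factor(rep(c("lo", "hi", "mix"), each = 20))
  fit <- e1071::svm(X3, y3, type = "C-classification", kernel = "polynomial",
                    degree = 3, gamma = 1, coef0 = 1, cost = 1, scale = FALSE)
  expect_length(fit$rho, 3)  # K(K-1)/2 pairwise machines for K = 3

  expect_error(svm_train_predict(X, factor(rep("one", 40)), X), "2 classes")
})

test_that("LDA agrees with an independent reference fit on Gaussian classes", {
  set.seed(7)
  n <- 60
  X <- rbind(matrix(rnorm(2 * n, -1), n, 2), matrix(rnorm(2 * n, 1), n, 2))
  y <- factor(rep(c("a", "b"), each = n))
  te <- matrix(rnorm(60, 0, 2), 30, 2)
  ours <- lda_train_predict(X, y, te)$y_pred
  ref <- predict(MASS::lda(X, y), te)$class
  expect_equal(as.character(ours), as.character(ref))
})

test_that("LDA classifies class means correctly and survives duplicate columns", {
  set.seed(8)
  X <- rbind(matrix(rnorm(80, -2), 40, 2), matrix(rnorm(80, 2), 40, 2))
  y <- factor(rep(c("a", "b"), each = 40))
  mu_a <- colMeans(X[y == "a", , drop = FALSE])
  mu_b <- colMeans(X[y == "b", , drop = FALSE])
  ps <- lda_train_predict(X, y, rbind(mu_a, mu_b))
  expect_equal(as.character(ps$y_pred), c("a", "b"))

  Xdup <- cbind(X, X[, 1])  # singular pooled covariance -> pseudo-inverse path
  ps2 <- lda_train_predict(Xdup, y, cbind(rbind(mu_a, mu_b),
                                          c(mu_a[1], mu_b[1])))
  expect_equal(as.character(ps2$y_pred), c("a", "b"))
})

test_that("stratified folds balance classes and are reproducible", {
  y <- factor(rep(c("a", "b"), each = 50))
  plan <- stratified_folds(y, 10, seed = 3)
  tab <- table(plan$assignments, y)
  expect_true(all(tab == 5))                         # 5 per class per fold
  expect_setequal(seq_along(y)[plan$assignments > 0], seq_along(y))
  expect_identical(stratified_folds(y, 10, seed = 3)$assignments,
                   plan$assignments)
  expect_false(identical(stratified_folds(y, 10, seed = 4)$assignments,
                         plan$assignments))
  expect_error(stratified_folds(factor(c("a", "b")), 10), "exceeds")
  expect_warning(stratified_folds(factor(rep(c("a", "b"), c(30, 4))), 10),
                 "best-effort")
})

test_that("cross-validation predicts every sample exactly once", {
  fx <- generate_feature_fixture(n_samples = 50, n_features = 6,
                                 n_informative = 4, effect_size = 3, seed = 4)
  cv <- cross_validate(fx$X, fx$y, "knn")
  expect_length(cv$predictions$y_pred, 50)
  expect_false(anyNA(cv$predictions$y_pred))
  expect_equal(mean(cv$predictions$y_pred == fx$y), 1)  # perfect separation
  expect_length(cv$fold_acc, 10)
})

test_that("cross-validated accuracy is at chance for pure-noise features", {
  fx <- generate_feature_fixture(n_samples = 200, n_features = 10,
                                 n_informative = 0, effect_size = 0, seed = 12)
  cv <- cross_validate(fx$X, fx$y, "knn", stratified_folds(fx$y, 10, seed = 2))
  acc <- mean(cv$predictions$y_pred == fx$y)
  expect_gt(acc, 0.4)
  expect_lt(acc, 0.6)
})
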