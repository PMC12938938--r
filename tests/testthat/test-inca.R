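test_that("standardization: train stats only, zero-variance handling", {
  set.seed(1)
  X <- cbind(rnorm(30, 5, 2), rnorm(30, -1, 0.5), rep(3, 30))
  std <- standardize_fit(X)
  Xs <- standardize_apply(X, std)
  expect_equal(colMeans(Xs), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(apply(Xs[, 1:2], 2, sd), c(1, 1), tolerance = 1e-12)
  expect_true(all(Xs[, 3] == 0))          # constant column maps to 0
  # a shifted test matrix keeps its shift: transformed with train stats only
  Xt <- X + 10
  Xts <- standardize_apply(Xt, std)
  expect_equal(colMeans(Xts)[1], 10 / std$scale[1], tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("NCA upweights a perfectly separating feature over noise", {
  for (seed in 1:5) {
    set.seed(seed)
    y <- factor(rep(c("a", "b"), each = 20))
    X <- cbind(ifelse(y == "a", -2, 2) + rnorm(40, 0, 0.3), rnorm(40))
    Xs <- standardize_apply(X, standardize_fit(X))
    w <- nca_weights(Xs, y, nca_config(seed = seed))$w
    expect_gt(w[1]^2, w[2]^2)
  }
})

test_that("stochastic ascent improves the NCA objective over the start", {
  set.seed(4)
  y <- factor(rep(c("a", "b"), each = 10))
  X <- cbind(ifelse(y == "a", -1.5, 1.5) + rnorm(20, 0, 0.5),
             matrix(rnorm(20 * 4), 20, 4))
  Xs <- standardize_apply(X, standardize_fit(X))
  fit <- nca_weights(Xs, y, nca_config(seed = 2))
  lam <- fit$config$lambda
  expect_gte(nca_objective(Xs, y, fit$w, lam, fit$sigma),
             nca_objective(Xs, y, rep(1, ncol(Xs)), lam, fit$sigma))
  expect_true(all(is.finite(fit$objective_trace)))
})

test_that("feature ranking matches a naive repeated-argmax sort oracle", {
  set.seed(9)
  w <- rnorm(40)
  w[5] <- w[12]  # force a tie in relevance
  id <- rank_features(w)
  rel <- w^2
  oracle <- integer(0)
  remaining <- seq_along(rel)
  while (length(remaining)) {
    best <- remaining[which.max(rel[remaining])]  # which.max: first = lowest index
    oracle <- c(oracle, best)
    remaining <- setdiff(remaining, best)
  }
  expect_identical(id, oracle)
  expect_identical(rank_features(rep(0.5, 6)), 1:6)  # all ties -> identity
  expect_identical(rank_features(2), 1L)             # d = 1
})

test_that("iterative selection: curve length, nesting, exhaustive minimum", {
  fx <- generate_feature_fixture(n_samples = 60, n_features = 150,
                                 n_informative = 20, effect_size = 1,
                                 seed = 5)
  Xs <- standardize_apply(fx$X, standardize_fit(fx$X))
  id <- rank_features(nca_weights(Xs, fx$y, nca_config(seed = 2)))
  sel <- iterative_selection(Xs, fx$y, id, iv = 10, fv = 60,
                             oracle_config = list(seed = 3))
  expect_length(sel$mcv, 51)
  expect_identical(sel$sfv, id[seq_len(sel$best_size)])  # nested prefix
  expect_equal(min(sel$mcv), sel$mcv[sel$best_size - sel$iv + 1])
  expect_equal(sel$best_size, sel$iv - 1L + which.min(sel$mcv))

  # single-candidate range
  one <- iterative_selection(Xs, fx$y, id, iv = 25, fv = 25,
                             oracle_config = list(seed = 3))
  expect_length(one$mcv, 1)
  expect_identical(one$sfv, id[1:25])

  expect_error(iterative_selection(Xs, fx$y, id, iv = 30, fv = 20), "exceeds")
  expect_error(iterative_selection(Xs, fx$y, id, iv = 10, fv = 151), "exceeds")
})

test_that("sweep errors match an independent fold-by-fold kNN oracle", {
  fx <- generate_feature_fixture(n_samples = 40, n_features = 60,
                                 n_informative = 10, effect_size = 1.2,
                                 seed = 11)
  Xs <- standardize_apply(fx$X, standardize_fit(fx$X))
  id <- rank_features(nca_weights(Xs, fx$y, nca_config(seed = 4)))
  oc <- list(k = 1L, n_folds = 5L, seed = 13L)
  sel <- iterative_selection(Xs, fx$y, id, iv = 5, fv = 40, oracle_config = oc)
  plan <- stratified_folds(fx$y, n_folds = 5L, seed = 13L)
  for (a in c(5, 17, 40)) {
    Xa <- Xs[, id[1:a], drop = FALSE]
    pred <- factor(rep(NA_character_, 40), levels = levels(fx$y))
    for (f in 1:5) {
      te <- plan$assignments == f
      pred[te] <- knn_predict(Xa[!te, , drop = FALSE], fx$y[!te],
                              Xa[te, , drop = FALSE])$y_pred
    }
    expect_equal(sel$mcv[a - 5 + 1], mean(pred != fx$y))
  }
})

test_that("selection artifact round-trips through its plain-text file", {
  fx <- generate_feature_fixture(n_samples = 30, n_features = 40,
                                 n_informative = 8, effect_size = 1.5, seed = 3)
  Xs <- standardize_apply(fx$X, standardize_fit(fx$X))
  id <- rank_features(nca_weights(Xs, fx$y, nca_config(seed = 1)))
  sel <- iterative_selection(Xs, fx$y, id, iv = 5, fv = 20,
                             oracle_config = list(seed = 1))
  path <- tempfile(fileext = ".json")
  save_selection(sel, path)
  sel2 <- load_selection(path)
  expect_equal(sel2$sfv, sel$sfv)
  expect_equal(sel2$mcv, sel$mcv)
  expect_equal(sel2$best_size, sel$best_size)
})

test_that("selection is a pure function of the training rows (no leakage)", {
  fx <- generate_feature_fixture(n_samples = 40, n_features = 60,
                                 n_informative = 10, effect_size = 1.2, seed = 21)
  run_selection <- function() {
    std <- standardize_fit(fx$X)
    Xs <- standardize_apply(fx$X, std)
    id <- rank_features(nca_weights(Xs, fx$y, nca_config(seed = 2)))
    iterative_selection(Xs, fx$y, id, iv = 5, fv = 30,
                        oracle_config = list(seed = 2))
  }
  sel_before <- run_selection()
  # a test matrix of NaNs passes through index transfer untouched and cannot
  # influence any stage of the selection path
  X_test <- matrix(NaN, 7, 60)
  reduced <- apply_selection(X_test, sel_before$sfv)
  expect_equal(dim(reduced), c(7, sel_before$best_size))
  sel_after <- run_selection()
  expect_identical(sel_after$sfv, sel_before$sfv)
  expect_identical(sel_after$mcv, sel_before$mcv)

  # apply_selection contracts
  expect_equal(apply_selection(fx$X, seq_len(ncol(fx$X))), fx$X)
  expect_equal(dim(apply_selection(fx$X[0, , drop = FALSE], 1:5)), c(0, 5))
  expect_error(apply_selection(fx$X, c(1, 61)), "out of range")
})
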