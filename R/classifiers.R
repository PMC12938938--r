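# shallow classifiers on selected deep features: kNN (L1), SVM (cubic
# polynomial kernel, one-vs-one), LDA (gamma = 0), plus stratified
# cross-validation.

prediction_set <- function(y_true, y_pred, source) {
  structure(list(y_true = y_true, y_pred = y_pred, source = source),
            class = "gptnext_predictions")
}

#' @export
print.gptnext_predictions <- function(x, ...) {
  acc <- if (!is.null(x$y_true)) mean(x$y_pred == x$y_true) else NA
  cat("predictions (", x$source, "): n =", length(x$y_pred),
      if (!is.na(acc)) paste0(", accuracy ", round(100 * acc, 2), "%"), "\n")
  invisible(x)
}

#' k-nearest-neighbor classification with L1 distance
#'
#' k = 1 by default ("Voting: none"). Neighbors are ordered by (distance,
#' training index), so equidistant neighbors resolve to the lower training
#' index; vote ties resolve to the tied label with the best-ranked neighbor.
#'
#' @param train_X,train_y training features / labels (factor or coercible).
#' @param test_X test features (same number of columns).
#' @param k number of neighbors.
#' @param test_y optional true test labels, stored in the result.
#' @return a `gptnext_predictions` object.
#' @export
knn_predict <- function(train_X, train_y, test_X, k = 1L, test_y = NULL) {
  train_y <- factor(train_y)
  if (nrow(train_X) == 0L) stop_input("empty training set")
  if (ncol(train_X) != ncol(test_X))
    stop_input("feature dimension mismatch: train has ", ncol(train_X),
               ", test has ", ncol(test_X))
  pred0 <- cpp_knn_l1(as.matrix(train_X), as.integer(train_y) - 1L,
                      as.matrix(test_X), as.integer(k))
  pred <- factor(levels(train_y)[pred0 + 1L], levels = levels(train_y))
  prediction_set(test_y, pred, sprintf("knn(k=%d, L1)", k))
}

#' SVM classification with a cubic polynomial kernel
#'
#' One-vs-one multiclass SVMs with kernel `(u . v + 1)^3` and box constraint
#' `C` (libsvm via e1071; inputs are used as given — standardize beforehand).
#'
#' @inheritParams knn_predict
#' @param C box constraint.
#' @return a `gptnext_predictions` object.
#' @export
svm_train_predict <- function(train_X, train_y, test_X, C = 1, test_y = NULL) {
  train_y <- factor(train_y)
  if (nlevels(droplevels(train_y)) < 2L)
    stop_input("SVM needs at least 2 classes in the training labels")
  fit <- e1071::svm(x = as.matrix(train_X), y = train_y,
                    type = "C-classification", kernel = "polynomial",
                    degree = 3, gamma = 1, coef0 = 1, cost = C,
                    scale = FALSE)
  pred <- stats::predict(fit, as.matrix(test_X))
  prediction_set(test_y, pred, "svm(cubic, one-vs-one)")
}

# pooled-covariance linear discriminant; gamma = 0 (no shrinkage),
# empirical priors, pseudo-inverse fallback for singular covariance
lda_fit <- function(X, y) {
  y <- droplevels(factor(y))
  K <- nlevels(y); d <- ncol(X); n <- nrow(X)
  if (K < 2L) stop_input("LDA needs at least 2 classes")
  M <- matrix(0, K, d)
  Sw <- matrix(0, d, d)
  for (k in seq_len(K)) {
    Xk <- X[y == levels(y)[k], , drop = FALSE]
    M[k, ] <- colMeans(Xk)
    Xc <- sweep(Xk, 2, M[k, ])
    Sw <- Sw + crossprod(Xc)
  }
  Sw <- Sw / max(1, n - K)
  Sinv <- tryCatch({
    if (rcond(Sw) < 1e-12) stop("ill-conditioned")
    solve(Sw)
  }, error = function(e) MASS::ginv(Sw))
  priors <- as.numeric(table(y)) / n
  list(means = M, Sinv = Sinv, priors = priors, levels = levels(y))
}

#' Linear discriminant analysis (gamma = 0)
#'
#' Gaussian linear discriminant with a shared (pooled) within-class
#' covariance, no shrinkage, and empirical class priors. A pseudo-inverse
#' replaces the matrix inverse when the pooled covariance is singular or
#' ill-conditioned (e.g. duplicated feature columns), so predictions are
#' always returned.
#'
#' @inheritParams knn_predict
#' @return a `gptnext_predictions` object.
#' @export
lda_train_predict <- function(train_X, train_y, test_X, test_y = NULL) {
  fit <- lda_fit(as.matrix(train_X), train_y)
  Xt <- as.matrix(test_X)
  # delta_k(x) = x' Sinv mu_k - 0.5 mu_k' Sinv mu_k + log pi_k
  SM <- fit$Sinv %*% t(fit$means)                 # d x K
  lin <- Xt %*% SM
  const <- -0.5 * colSums(t(fit$means) * SM) + log(fit$priors)
  scores <- sweep(lin, 2, const, "+")
  pred <- factor(fit$levels[max.col(scores, ties.method = "first")],
                 levels = fit$levels)
  prediction_set(test_y, pred, "lda(gamma=0)")
}

#' Stratified k-fold plan
#'
#' Seeded stratified partition: within each class the (shuffled) samples are
#' dealt to folds cyclically, so per-class counts across folds differ by at
#' most 1. Classes smaller than `n_folds` are assigned best-effort with a
#' warning.
#'
#' @param y factor of labels.
#' @param n_folds number of folds (default 10).
#' @param seed integer seed.
#' @return an object of class `gptnext_folds`: list with `assignments`
#'   (integer fold per sample), `n_folds`, `seed`.
#' @export
stratified_folds <- function(y, n_folds = 10L, seed = 1L) {
  y <- factor(y)
  n <- length(y)
  n_folds <- as.integer(n_folds)
  if (n_folds > n)
    stop_input("n_folds (", n_folds, ") exceeds the number of samples (", n, ")")
  if (n_folds < 2L) stop_input("n_folds must be at least 2")
  small <- table(y) < n_folds
  if (any(small))
    warning("classes with fewer samples than folds (",
            paste(names(small)[small], collapse = ", "),
            "): stratification is best-effort", call. = FALSE)
  assignments <- integer(n)
  offset <- 0L
  with_seed(derive_seed(seed, 4L), {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      assignments[idx] <- ((offset + seq_along(idx) - 1L) %% n_folds) + 1L
      offset <- (offset + length(idx)) %% n_folds
    }
  })
  structure(list(assignments = assignments, n_folds = n_folds,
                 seed = as.integer(seed), stratified = TRUE),
            class = "gptnext_folds")
}

#' Cross-validated classification
#'
#' Each sample is predicted exactly once by a classifier fitted on the other
#' folds; returns the out-of-fold predictions and per-fold accuracies.
#'
#' @param X feature matrix.
#' @param y factor of labels.
#' @param classifier one of "knn", "svm", "lda".
#' @param plan a [stratified_folds()] plan (default: 10 folds, seed 1).
#' @param k,C classifier settings passed through.
#' @return list with `predictions` (a `gptnext_predictions` with out-of-fold
#'   `y_pred` aligned to `y`) and `fold_acc` (numeric, one per fold).
#' @export
cross_validate <- function(X, y, classifier = c("knn", "svm", "lda"),
                           plan = NULL, k = 1L, C = 1) {
  classifier <- match.arg(classifier)
  y <- factor(y)
  X <- as.matrix(X)
  if (is.null(plan)) plan <- stratified_folds(y, 10L, seed = 1L)
  if (length(plan$assignments) != length(y))
    stop_input("fold plan does not cover the data")
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  fold_acc <- numeric(plan$n_folds)
  for (f in seq_len(plan$n_folds)) {
    te <- which(plan$assignments == f)
    tr <- which(plan$assignments != f)
    if (length(te) == 0L) { fold_acc[f] <- NA_real_; next }
    ps <- tryCatch(switch(classifier,
      knn = knn_predict(X[tr, , drop = FALSE], y[tr], X[te, , drop = FALSE], k = k),
      svm = svm_train_predict(X[tr, , drop = FALSE], y[tr], X[te, , drop = FALSE], C = C),
      lda = lda_train_predict(X[tr, , drop = FALSE], y[tr], X[te, , drop = FALSE])),
      error = function(e) stop_input("fold ", f, ": ", conditionMessage(e)))
    pred[te] <- ps$y_pred
    fold_acc[f] <- mean(ps$y_pred == y[te])
  }
  list(predictions = prediction_set(y, pred, paste0(classifier, " (",
                                                    plan$n_folds, "-fold CV)")),
       fold_acc = fold_acc)
}
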