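# feature standardization and iterative NCA (INCA) feature selection.
# Everything here is fitted on training rows only; test matrices are
# transformed with training statistics and reduced by index transfer.

#' Fit / apply column standardization
#'
#' `standardize_fit` computes per-column means and standard deviations on the
#' training matrix; `standardize_apply` centers and scales any matrix with
#' those training statistics (never its own). Zero-variance training columns
#' are mapped to 0.
#'
#' @param X_train numeric training matrix.
#' @return `standardize_fit`: list with `center`, `scale`, `zero_var`;
#'   `standardize_apply`: the transformed matrix.
#' @export
standardize_fit <- function(X_train) {
  if (!is.matrix(X_train) || nrow(X_train) == 0L)
    stop_input("X_train must be a non-empty matrix")
  center <- colMeans(X_train)
  scale <- apply(X_train, 2, stats::sd)
  zero_var <- !is.finite(scale) | scale < 1e-12
  scale[zero_var] <- 1
  structure(list(center = center, scale = scale, zero_var = zero_var),
            class = "gptnext_standardizer")
}

#' @rdname standardize_fit
#' @param X matrix to transform (training or test).
#' @param stats a `standardize_fit` result.
#' @export
standardize_apply <- function(X, stats) {
  stopifnot(inherits(stats, "gptnext_standardizer"))
  if (ncol(X) != length(stats$center))
    stop_input("matrix has ", ncol(X), " columns; standardizer was fitted on ",
               length(stats$center))
  X <- sweep(sweep(X, 2, stats$center, "-"), 2, stats$scale, "/")
  if (any(stats$zero_var)) X[, stats$zero_var] <- 0
  X
}

#' NCA solver configuration
#'
#' @param steps number of stochastic gradient steps (one sampled anchor
#'   point per step); default `floor(N/2)`, half the number of samples.
#' @param step_size initial step size; step t uses `step_size/sqrt(t)`.
#' @param lambda ridge penalty on the squared weights; default `1/N`.
#' @param seed integer seed for anchor sampling.
#' @export
nca_config <- function(steps = NULL, step_size = 0.1, lambda = NULL, seed = 1L) {
  structure(list(steps = steps, step_size = step_size, lambda = lambda,
                 seed = as.integer(seed)), class = "gptnext_nca_config")
}

#' NCA feature-weighting objective
#'
#' The regularized leave-one-out soft nearest-neighbor objective
#' \deqn{\sum_i \sum_{j \ne i} p_{ij} 1[y_i = y_j] - \lambda \sum_r w_r^2}
#' with \eqn{p_{ij} \propto \exp(-d_w(x_i, x_j))} and the weighted L1 distance
#' \eqn{d_w(x_i, x_j) = \sum_r w_r^2 |x_{ir} - x_{jr}|}. Exposed so the
#' optimizer can be checked against direct evaluation on small problems.
#'
#' @param X numeric matrix (rows = samples).
#' @param y factor of class labels.
#' @param w numeric weight vector (length = ncol(X)).
#' @param lambda ridge penalty.
#' @param sigma kernel length-scale dividing the weighted distances (1 for
#'   the unscaled objective; [nca_weights()] reports the scale it used).
#' @return the scalar objective value.
#' @export
nca_objective <- function(X, y, w, lambda, sigma = 1) {
  n <- nrow(X)
  w2 <- w^2
  total <- 0
  for (i in seq_len(n)) {
    D <- abs(sweep(X[-i, , drop = FALSE], 2, X[i, ], "-"))
    d <- as.numeric(D %*% w2) / sigma
    p <- exp(-(d - min(d)))
    p <- p / sum(p)
    total <- total + sum(p[y[-i] == y[i]])
  }
  total - lambda * sum(w2)
}

#' NCA feature weights
#'
#' Learns a non-negative relevance (`w^2`) per feature by maximizing the
#' regularized soft nearest-neighbor objective (see [nca_objective()]) with
#' seeded stochastic gradient ascent from `w = 1`: each step samples one
#' anchor sample, computes the exact gradient of that anchor's objective term,
#' and updates with a `1/sqrt(t)` decaying step size.
#'
#' @param X_train numeric training matrix (standardized features recommended).
#' @param y_train factor of class labels (>= 2 classes, each with >= 2
#'   samples).
#' @param config an [nca_config()].
#' @return an object of class `gptnext_nca`: list with `w` (weights, length
#'   d), `objective_trace` (per-step anchor objective), `config`.
#' @export
nca_weights <- function(X_train, y_train, config = nca_config()) {
  y_train <- droplevels(factor(y_train))
  n <- nrow(X_train); d <- ncol(X_train)
  if (nlevels(y_train) < 2L)
    stop_input("NCA needs at least 2 classes")
  if (any(table(y_train) < 2L))
    stop_input("NCA needs at least 2 samples per class")
  steps <- config$steps %||% max(1L, floor(n / 2))
  lambda <- config$lambda %||% (1 / n)
  w <- rep(1, d)
  trace <- numeric(steps)
  anchors <- with_seed(derive_seed(config$seed, 3L),
                       sample.int(n, steps, replace = TRUE))
  # kernel length-scale: mean initial (w = 1) distance from the first anchor,
  # so soft neighbor probabilities start spread over many neighbors instead
  # of collapsing onto the single nearest point
  D0 <- abs(sweep(X_train[-anchors[1], , drop = FALSE], 2,
                  X_train[anchors[1], ], "-"))
  sigma <- max(mean(rowSums(D0)), 1e-12)
  for (t in seq_len(steps)) {
    i <- anchors[t]
    D <- abs(sweep(X_train[-i, , drop = FALSE], 2, X_train[i, ], "-"))
    dist <- as.numeric(D %*% (w^2)) / sigma
    p <- exp(-(dist - min(dist)))
    p <- p / sum(p)
    same <- y_train[-i] == y_train[i]
    p_i <- sum(p[same])
    g_all <- as.numeric(crossprod(D, p))
    g_same <- as.numeric(crossprod(D[same, , drop = FALSE], p[same]))
    grad <- (2 * w / sigma) * (p_i * g_all - g_same) - 2 * lambda * w
    w <- w + (config$step_size / sqrt(t)) * grad
    trace[t] <- p_i - lambda * sum(w^2)
  }
  config$steps <- steps
  config$lambda <- lambda
  structure(list(w = w, objective_trace = trace, sigma = sigma,
                 config = config),
            class = "gptnext_nca")
}

#' Rank features by NCA relevance
#'
#' Stable descending sort of the squared weights; ties keep the lower
#' original index first.
#'
#' @param weights a [nca_weights()] result (or a bare numeric weight vector).
#' @return integer permutation of `1..d`, most relevant feature first.
#' @export
rank_features <- function(weights) {
  w <- if (inherits(weights, "gptnext_nca")) weights$w else weights
  if (!all(is.finite(w))) stop_input("non-finite NCA weights")
  order(-(w^2), seq_along(w))
}

#' Iterative NCA feature selection
#'
#' Sweeps nested top-`a` prefixes of the ranked features for
#' `a in [iv, fv]`, scores each subset by the cross-validated
#' misclassification rate of a k-nearest-neighbor classifier (k = 1,
#' L1 distance, stratified folds by default), and returns the best subset
#' (ties in the minimum resolve to the smallest subset).
#'
#' @param X_train numeric training matrix (standardize first; the sweep uses
#'   raw column values as given).
#' @param y_train factor of labels.
#' @param id ranked feature indices from [rank_features()].
#' @param iv,fv smallest / largest subset size (defaults 100 and 1000,
#'   requiring `fv <= ncol(X_train)`).
#' @param oracle_config list with `k` (neighbors, default 1), `n_folds`
#'   (default 10) and `seed` for the fold plan.
#' @return an object of class `gptnext_inca`: `mcv` (misclassification curve,
#'   length `fv - iv + 1`), `best_size`, `sfv` (selected 1-based feature
#'   indices = first `best_size` entries of `id`), plus the inputs.
#' @export
iterative_selection <- function(X_train, y_train, id, iv = 100L, fv = 1000L,
                                oracle_config = list()) {
  y_train <- droplevels(factor(y_train))
  d <- ncol(X_train)
  iv <- as.integer(iv); fv <- as.integer(fv)
  if (iv < 1L) stop_input("iv must be >= 1")
  if (fv > d) stop_input("fv (", fv, ") exceeds the number of features (", d, ")")
  if (iv > fv) stop_input("iv (", iv, ") exceeds fv (", fv, ")")
  if (!setequal(id, seq_len(d)))
    stop_input("id must be a permutation of 1..", d)
  k <- oracle_config$k %||% 1L
  n_folds <- oracle_config$n_folds %||% 10L
  seed <- oracle_config$seed %||% 1L
  plan <- stratified_folds(y_train, n_folds = n_folds, seed = seed)
  mcv <- cpp_inca_sweep(X_train, as.integer(y_train) - 1L,
                        as.integer(id) - 1L, iv, fv,
                        plan$assignments - 1L, as.integer(k))
  ind <- which.min(mcv)          # first minimum = smallest subset
  best_size <- ind + iv - 1L
  structure(list(iv = iv, fv = fv, mcv = mcv, best_size = best_size,
                 sfv = id[seq_len(best_size)], id = id,
                 oracle_config = list(k = k, n_folds = n_folds, seed = seed)),
            class = "gptnext_inca")
}

#' Apply a selected feature index set
#'
#' Column subset in `sfv` order; usable identically on training and test
#' matrices (index transfer — nothing is refitted on test rows).
#'
#' @param X_any numeric matrix.
#' @param sfv 1-based feature indices (e.g. from [iterative_selection()]).
#' @return the reduced matrix with `length(sfv)` columns.
#' @export
apply_selection <- function(X_any, sfv) {
  if (length(sfv) == 0L) stop_input("empty selection")
  if (max(sfv) > ncol(X_any) || min(sfv) < 1L)
    stop_input("selection index out of range: matrix has ", ncol(X_any),
               " columns")
  X_any[, sfv, drop = FALSE]
}

#' Save / load a selection artifact
#'
#' Plain-text JSON recording the selected 1-based indices, the chosen subset
#' size and the misclassification curve as parallel `a` / `mcv` arrays, so a
#' selection is auditable and transferable between runs.
#'
#' @param sel a `gptnext_inca` object.
#' @param path file path.
#' @export
save_selection <- function(sel, path) {
  stopifnot(inherits(sel, "gptnext_inca"))
  jsonlite::write_json(list(
    sfv = sel$sfv, best_size = sel$best_size, iv = sel$iv, fv = sel$fv,
    curve = list(a = seq(sel$iv, sel$fv), mcv = sel$mcv),
    oracle_config = sel$oracle_config, id = sel$id),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_selection
#' @export
load_selection <- function(path) {
  obj <- jsonlite::fromJSON(path)
  structure(list(iv = obj$iv, fv = obj$fv, mcv = obj$curve$mcv,
                 best_size = obj$best_size, sfv = obj$sfv, id = obj$id,
                 oracle_config = as.list(obj$oracle_config)),
            class = "gptnext_inca")
}

#' @export
print.gptnext_inca <- function(x, ...) {
  cat("INCA selection: best subset size", x$best_size, "of range [",
      x$iv, ",", x$fv, "], CV misclassification",
      round(min(x$mcv), 4), "\n")
  invisible(x)
}
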