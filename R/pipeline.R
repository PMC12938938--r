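# end-to-end pipeline orchestration: train -> features -> select -> evaluate,
# with ablation modes and a deterministic artifact layout. These functions
# back the command-line driver in inst/cli/gptnext.R.

#' Pipeline configuration
#'
#' Collects every stage's settings. `ablation` controls evaluation:
#' `"full"` (exemplar features + INCA + shallow classifiers),
#' `"softmax_only"` (score the network head directly),
#' `"full_image_only"` (only the first GAP block, no INCA),
#' `"no_inca"` (all exemplar features, no selection).
#'
#' @param data_dir dataset root containing `train/` and `test/` class folders.
#' @param artifacts_dir where models, features, selections and reports go.
#' @param arch a [gptnext_spec()] (default: a compact schedule suited to
#'   64-px synthetic images).
#' @param train a [train_config()].
#' @param patch_mode `"resize"` or `"native"`.
#' @param iv,fv INCA subset-size range; `NULL` lets [run_select()] pick
#'   `min(100, d/4)` .. `min(1000, d)` for small feature counts.
#' @param knn_k,svm_C classifier settings.
#' @param ablation evaluation mode, see above.
#' @param seed global seed fanned out to every stage.
#' @return an object of class `gptnext_config`.
#' @export
pipeline_config <- function(data_dir, artifacts_dir,
                            arch = gptnext_spec(filters = c(16L, 32L, 64L, 128L, 160L),
                                                input_side = 64L,
                                                num_classes = 3L),
                            train = train_config(max_epochs = 5L),
                            patch_mode = "resize", iv = NULL, fv = NULL,
                            knn_k = 1L, svm_C = 1,
                            ablation = c("full", "softmax_only",
                                         "full_image_only", "no_inca"),
                            seed = 1L) {
  ablation <- match.arg(ablation)
  structure(list(data_dir = data_dir, artifacts_dir = artifacts_dir,
                 arch = arch, train = train, patch_mode = patch_mode,
                 iv = iv, fv = fv, knn_k = as.integer(knn_k), svm_C = svm_C,
                 ablation = ablation, seed = as.integer(seed)),
            class = "gptnext_config")
}

#' Read a pipeline configuration from JSON
#'
#' JSON fields mirror [pipeline_config()] arguments; `arch` and `train` are
#' nested objects passed to [gptnext_spec()] / [train_config()]. Explicit
#' `overrides` (e.g. from CLI flags) replace file values.
#'
#' @param path JSON file.
#' @param overrides named list of overriding values.
#' @return a `gptnext_config`.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  raw <- jsonlite::fromJSON(path)
  raw <- utils::modifyList(raw, overrides)
  arch <- if (!is.null(raw$arch)) do.call(gptnext_spec, as.list(raw$arch))
          else gptnext_spec(filters = c(16L, 32L, 64L, 128L, 160L),
                            input_side = 64L, num_classes = 3L)
  train <- if (!is.null(raw$train)) do.call(train_config, as.list(raw$train))
           else train_config(max_epochs = 5L)
  pipeline_config(data_dir = raw$data_dir, artifacts_dir = raw$artifacts_dir,
                  arch = arch, train = train,
                  patch_mode = raw$patch_mode %||% "resize",
                  iv = raw$iv, fv = raw$fv, knn_k = raw$knn_k %||% 1L,
                  svm_C = raw$svm_C %||% 1,
                  ablation = raw$ablation %||% "full",
                  seed = raw$seed %||% 1L)
}

config_hash <- function(config) {
  s <- as.character(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                     force = TRUE))
  v <- utf8ToInt(s)
  h <- 0
  for (x in v) h <- (h * 31 + x) %% 2147483647
  sprintf("%08x", as.integer(h))
}

log_line <- function(config, stage, ...) {
  line <- sprintf("[%s] config=%s seed=%d %s", stage, config_hash(config),
                  config$seed, paste0(..., collapse = ""))
  message(line)
  dir.create(config$artifacts_dir, recursive = TRUE, showWarnings = FALSE)
  cat(line, "\n", file = file.path(config$artifacts_dir, "pipeline.log"),
      append = TRUE)
}

art_path <- function(config, name) file.path(config$artifacts_dir, name)

#' Pipeline stage: generate synthetic data
#'
#' @param config a [pipeline_config()].
#' @param synth_spec a [synthetic_image_spec()]; defaults derive image side
#'   and class count from the configured architecture.
#' @return invisibly, the dataset manifest.
#' @export
run_synth <- function(config, synth_spec = NULL) {
  if (is.null(synth_spec))
    synth_spec <- synthetic_image_spec(
      n_classes = config$arch$num_classes,
      image_side = config$arch$input_side,
      seed = derive_seed(config$seed, 10L))
  log_line(config, "synth", "writing dataset to ", config$data_dir)
  generate_image_dataset(synth_spec, config$data_dir)
}

#' Pipeline stage: train the network
#'
#' Trains on `data_dir/train` and writes the model archive plus the
#' per-epoch trace.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the path to the model archive.
#' @export
run_train <- function(config) {
  tr_dir <- file.path(config$data_dir, "train")
  if (!dir.exists(tr_dir)) stop_input("missing training folder: ", tr_dir)
  model <- build_model(config$arch, init_seed = derive_seed(config$seed, 11L))
  cfg <- config$train
  cfg$seed <- derive_seed(config$seed, 12L)
  res <- train_model(model, tr_dir, cfg)
  dir.create(config$artifacts_dir, recursive = TRUE, showWarnings = FALSE)
  save_model(res$model, art_path(config, "model.bin"))
  utils::write.csv(res$trace, art_path(config, "training_trace.csv"),
                   row.names = FALSE)
  fin <- if (nrow(res$trace) > 0) utils::tail(res$trace, 1) else
    data.frame(train_acc = NA, val_acc = NA)
  log_line(config, "train", "epochs=", nrow(res$trace),
           " final_train_acc=", round(fin$train_acc, 4),
           " final_val_acc=", round(fin$val_acc, 4),
           " -> ", art_path(config, "model.bin"))
  invisible(art_path(config, "model.bin"))
}

#' Pipeline stage: extract exemplar features for a split
#'
#' @param config a [pipeline_config()].
#' @param split `"train"` or `"test"`.
#' @return invisibly, the path to the feature CSV.
#' @export
run_features <- function(config, split = c("train", "test")) {
  split <- match.arg(split)
  model_path <- art_path(config, "model.bin")
  if (!file.exists(model_path))
    stop_input("model archive not found (run the train stage first): ",
               model_path)
  model <- load_model(model_path)
  fm <- build_feature_matrix(model, file.path(config$data_dir, split),
                             patch_mode = config$patch_mode)
  out <- art_path(config, paste0("features_", split, ".csv"))
  save_features(fm, out, split = split, patch_mode = config$patch_mode)
  log_line(config, "features", split, ": ", nrow(fm$X), " x ", ncol(fm$X),
           " -> ", out)
  invisible(out)
}

#' Pipeline stage: INCA feature selection on the training split
#'
#' Standardizes the training features, fits NCA weights, sweeps the nested
#' ranked subsets and writes the selection artifact. Refuses any feature file
#' not tagged as the training split (leakage guard: selection never sees
#' test rows).
#'
#' @param config a [pipeline_config()].
#' @param features_path feature CSV (default: the train-split artifact).
#' @return invisibly, the path to the selection artifact.
#' @export
run_select <- function(config, features_path = NULL) {
  features_path <- features_path %||% art_path(config, "features_train.csv")
  if (!file.exists(features_path))
    stop_input("feature file not found: ", features_path)
  fm <- load_features(features_path)
  if (!identical(fm$split, "train"))
    stop_input("selection must run on the training split only; '",
               features_path, "' is tagged split=",
               fm$split %||% "<untagged>")
  std <- standardize_fit(fm$X)
  Xs <- standardize_apply(fm$X, std)
  nca <- nca_weights(Xs, fm$y,
                     nca_config(seed = derive_seed(config$seed, 13L)))
  id <- rank_features(nca)
  d <- ncol(Xs)
  iv <- config$iv %||% min(100L, max(1L, d %/% 4L))
  fv <- config$fv %||% min(1000L, d)
  sel <- iterative_selection(Xs, fm$y, id, iv = iv, fv = fv,
                             oracle_config = list(
                               k = config$knn_k, n_folds = 10L,
                               seed = derive_seed(config$seed, 14L)))
  out <- art_path(config, "selection.json")
  save_selection(sel, out)
  log_line(config, "select", "candidates=", fv - iv + 1L,
           " best_size=", sel$best_size, " -> ", out)
  invisible(out)
}

#' Pipeline stage: evaluate on the test split
#'
#' Applies the configured ablation mode, fits the shallow classifiers on the
#' training features, predicts the held-out test split, and writes metric
#' reports (overall, per-class, confusion), per-sample predictions and the
#' pairwise McNemar table.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a named list of `gptnext_report`s (plus `mcnemar` for
#'   feature modes).
#' @export
run_evaluate <- function(config) {
  mode <- config$ablation
  if (mode == "softmax_only") {
    model <- load_model(art_path(config, "model.bin"))
    te <- load_image_folder(file.path(config$data_dir, "test"),
                            model$spec$input_side)
    out <- forward_batch(model, te$x, training = FALSE)
    pred <- factor(levels(te$y)[max.col(out$probs, ties.method = "first")],
                   levels = levels(te$y))
    preds <- prediction_set(te$y, pred, "gptnext softmax head")
    rep_ <- metrics_report(preds)
    write_report_csv(rep_, art_path(config, "report_softmax"))
    write_predictions_csv(list(softmax = preds),
                          art_path(config, "predictions.csv"))
    log_line(config, "evaluate", "mode=softmax_only accuracy=",
             round_half_up(rep_$overall$accuracy, 2))
    return(invisible(list(softmax = rep_)))
  }
  tr <- load_features(art_path(config, "features_train.csv"))
  te <- load_features(art_path(config, "features_test.csv"))
  if (!identical(levels(tr$y), levels(te$y)))
    stop_input("train and test feature files disagree on classes")
  gap_len <- ncol(tr$X) %/% 10L
  if (mode == "full_image_only") {
    keep <- seq_len(gap_len)
    tr$X <- tr$X[, keep, drop = FALSE]; te$X <- te$X[, keep, drop = FALSE]
  }
  std <- standardize_fit(tr$X)
  Xtr <- standardize_apply(tr$X, std)
  Xte <- standardize_apply(te$X, std)
  if (mode == "full") {
    sel_path <- art_path(config, "selection.json")
    if (!file.exists(sel_path))
      stop_input("selection artifact not found (run the select stage first): ",
                 sel_path)
    sel <- load_selection(sel_path)
    Xtr <- apply_selection(Xtr, sel$sfv)
    Xte <- apply_selection(Xte, sel$sfv)   # index transfer, no refitting
  }
  preds <- list(
    knn = knn_predict(Xtr, tr$y, Xte, k = config$knn_k, test_y = te$y),
    svm = svm_train_predict(Xtr, tr$y, Xte, C = config$svm_C, test_y = te$y),
    lda = lda_train_predict(Xtr, tr$y, Xte, test_y = te$y))
  reports <- lapply(preds, metrics_report)
  for (nm in names(reports))
    write_report_csv(reports[[nm]], art_path(config, paste0("report_", nm)))
  write_predictions_csv(preds, art_path(config, "predictions.csv"))
  mc <- list(
    knn_vs_svm = mcnemar(preds$knn, preds$svm),
    knn_vs_lda = mcnemar(preds$knn, preds$lda),
    svm_vs_lda = mcnemar(preds$svm, preds$lda))
  utils::write.csv(data.frame(
    comparison = names(mc),
    b = vapply(mc, `[[`, 0, "b"), c = vapply(mc, `[[`, 0, "c"),
    chi2 = vapply(mc, `[[`, 0, "chi2"), p = vapply(mc, `[[`, 0, "p")),
    art_path(config, "mcnemar.csv"), row.names = FALSE)
  log_line(config, "evaluate", "mode=", mode, " features=", ncol(Xtr),
           " acc(knn/svm/lda)=",
           paste(vapply(reports, function(r)
     format(round_half_up(r$overall$accuracy, 2), nsmall = 2), ""),
     collapse = "/"))
  invisible(c(reports, list(mcnemar = mc)))
}

write_predictions_csv <- function(preds, path) {
  rows <- lapply(names(preds), function(nm) {
    p <- preds[[nm]]
    data.frame(sample = seq_along(p$y_pred),
               true_label = as.character(p$y_true),
               predicted_label = as.character(p$y_pred),
               classifier = nm, mode = p$source)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
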