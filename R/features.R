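# exemplar deep feature extraction: GAP features of the full image and its
# nine overlapping patches, concatenated block-wise.

feature_block_names <- function(gap_len) {
  blocks <- c("image", paste0("patch", 1:9))
  unlist(lapply(blocks, function(b) sprintf("%s_f%04d", b, seq_len(gap_len))))
}

#' Exemplar deep feature vector for one image
#'
#' Extracts the GAP feature of the full image and of each of its nine
#' overlapping patches with the (pretrained) network and concatenates the ten
#' vectors: element `r + gap_len*(t-1)` of the output is element `r` of block
#' `t` (t = 1 the full image, t = k+1 patch k). For the default schedule the
#' result has length 12,800 (= 1280 x 10).
#'
#' @param model a [build_model()] result.
#' @param image a `input_side x input_side x channels` array in \[0, 1\].
#' @param patch_mode `"resize"` (default): each patch is bilinearly upscaled
#'   to `input_side` before the forward pass; `"native"`: patches are passed
#'   through the trunk at their own resolution (fully convolutional; the GAP
#'   length is unchanged).
#' @return numeric vector of length `10 * filters[5]`, with a `block`
#'   attribute naming the source of each element.
#' @export
extract_exemplar_feature <- function(model, image,
                                     patch_mode = c("resize", "native")) {
  patch_mode <- match.arg(patch_mode)
  spec <- model$spec
  side <- spec$input_side
  x_full <- as_input_array(image, spec)
  ps <- divide_patches(x_full[, , , 1])
  gap_len <- spec$filters[5]
  out <- numeric(10L * gap_len)
  if (patch_mode == "resize") {
    batch <- array(0, c(side, side, spec$input_channels, 10L))
    batch[, , , 1] <- x_full[, , , 1]
    for (k in 1:9)
      batch[, , , k + 1L] <- resize_bilinear(ps$patches[[k]], side)
    gap <- forward_batch(model, batch, training = FALSE)$gap
    for (t in 1:10) out[(t - 1L) * gap_len + seq_len(gap_len)] <- gap[t, ]
  } else {
    out[seq_len(gap_len)] <- forward_batch(model, x_full, FALSE)$gap[1, ]
    pside <- ps$patch_side
    pbatch <- array(0, c(pside, pside, spec$input_channels, 9L))
    for (k in 1:9) pbatch[, , , k] <- ps$patches[[k]]
    gap <- forward_batch(model, pbatch, training = FALSE)$gap
    for (k in 1:9) out[k * gap_len + seq_len(gap_len)] <- gap[k, ]
  }
  attr(out, "block") <- rep(c("image", paste0("patch", 1:9)), each = gap_len)
  out
}

#' Build the exemplar feature matrix for a labeled image folder
#'
#' One row per image in deterministic sorted-path order; rows are the
#' concatenated exemplar features, labels are taken from the class
#' sub-directory names. Unreadable images are skipped with a warning.
#'
#' @param model a [build_model()] result.
#' @param dataset a folder with one sub-directory per class, or a list with
#'   elements `x` (array `side x side x 3 x N`), `y` (factor), and optionally
#'   `files`.
#' @param patch_mode see [extract_exemplar_feature()].
#' @return an object of class `gptnext_features`: list with `X`
#'   (N x 10*gap_len numeric matrix with block-named columns), `y` (factor),
#'   `sample_ids` (character).
#' @export
build_feature_matrix <- function(model, dataset, patch_mode = "resize") {
  side <- model$spec$input_side
  if (is.character(dataset)) dataset <- load_image_folder(dataset, side)
  x <- dataset$x; y <- dataset$y
  if (!is.factor(y)) y <- factor(y)
  n <- dim(x)[4]
  if (n == 0L) stop_input("no images to extract features from")
  gap_len <- model$spec$filters[5]
  X <- matrix(NA_real_, n, 10L * gap_len)
  for (i in seq_len(n))
    X[i, ] <- extract_exemplar_feature(model, x[, , , i], patch_mode)
  colnames(X) <- feature_block_names(gap_len)
  ids <- dataset$files %||% sprintf("sample_%04d", seq_len(n))
  structure(list(X = X, y = y, sample_ids = basename(ids)),
            class = "gptnext_features")
}

#' @export
print.gptnext_features <- function(x, ...) {
  cat("feature matrix:", nrow(x$X), "samples x", ncol(x$X), "features,",
      nlevels(x$y), "classes\n")
  invisible(x)
}

#' Save / load a feature matrix
#'
#' Plain CSV: a `sample_id` column, one column per feature named by its block
#' origin (`image_f0001` ... `patch9_f1280`), and a final `label` column with
#' class names. A small JSON side-car (`<path>.meta.json`) records the split
#' tag and patch mode so downstream stages can refuse the wrong split.
#'
#' @param fm a `gptnext_features` object.
#' @param path CSV file path.
#' @param split optional split tag ("train"/"test") stored in the side-car.
#' @param patch_mode patch mode tag stored in the side-car.
#' @return `save_features` returns `path` invisibly; `load_features` a
#'   `gptnext_features` object (with a `split` field if a side-car exists).
#' @export
save_features <- function(fm, path, split = NULL, patch_mode = "resize") {
  stopifnot(inherits(fm, "gptnext_features"))
  df <- data.frame(sample_id = fm$sample_ids, fm$X,
                   label = as.character(fm$y), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(split = split, patch_mode = patch_mode,
               n_samples = nrow(fm$X), n_features = ncol(fm$X),
               classes = levels(fm$y))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_features
#' @export
load_features <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 3L || names(df)[1] != "sample_id" ||
      names(df)[ncol(df)] != "label")
    stop_input("not a gptnext feature file (expected sample_id, features, label): ",
               path)
  feat_names <- names(df)[-c(1L, ncol(df))]
  if (!all(grepl("^(image|patch[1-9])_f[0-9]+$", feat_names)))
    stop_input("feature file header does not name block origins: ", path)
  gap_len <- sum(grepl("^image_", feat_names))
  if (length(feat_names) != 10L * gap_len)
    stop_input("feature file has ", length(feat_names),
               " feature columns; expected 10 x ", gap_len)
  X <- as.matrix(df[, feat_names, drop = FALSE])
  if (!is.numeric(X)) stop_input("non-numeric feature values in ", path)
  fm <- structure(list(X = X, y = factor(df$label),
                       sample_ids = df$sample_id),
                  class = "gptnext_features")
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::fromJSON(meta_path)
    fm$split <- meta$split
    fm$patch_mode <- meta$patch_mode
  }
  fm
}
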