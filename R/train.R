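#' Training configuration
#'
#' Settings for network training: stochastic gradient descent with momentum
#' ("sgdm"), cross-entropy loss, a stratified train/validation split and
#' seeded shuffling. Defaults follow the recommended schedule: learning rate
#' 0.01, momentum 0.9, 100 epochs, mini-batches of 32, 70:30 split.
#'
#' @param solver only `"sgdm"` is supported.
#' @param learning_rate SGD learning rate.
#' @param momentum SGD momentum coefficient.
#' @param max_epochs number of passes over the training split (0 is allowed
#'   and performs no updates).
#' @param batch_size mini-batch size.
#' @param train_val_ratio two positive numbers summing to 100.
#' @param seed integer seed controlling the split, the shuffling and (through
#'   [build_model()]) any weight initialization derived from it.
#' @return an object of class `gptnext_train_config`.
#' @export
train_config <- function(solver = "sgdm", learning_rate = 0.01,
                         momentum = 0.9, max_epochs = 100L, batch_size = 32L,
                         train_val_ratio = c(70, 30), seed = 1L) {
  if (!identical(solver, "sgdm"))
    stop_input("unsupported solver '", solver, "' (only 'sgdm')")
  if (length(train_val_ratio) != 2L || any(train_val_ratio <= 0) ||
      abs(sum(train_val_ratio) - 100) > 1e-8)
    stop_input("train_val_ratio components must be positive and sum to 100")
  if (max_epochs < 0L || batch_size < 1L || learning_rate <= 0)
    stop_input("max_epochs must be >= 0, batch_size >= 1, learning_rate > 0")
  structure(list(solver = solver, learning_rate = learning_rate,
                 momentum = momentum, max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 train_val_ratio = train_val_ratio,
                 seed = as.integer(seed)),
            class = "gptnext_train_config")
}

# stratified index split; ratio like c(70, 30); seeded
stratified_split <- function(y, ratio, seed) {
  idx_tr <- integer(0)
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      if (length(idx) == 0L) stop_input("empty class '", cl, "' in training data")
      idx <- sample(idx)
      n_tr <- max(1L, round(length(idx) * ratio[1] / 100))
      if (n_tr >= length(idx)) n_tr <- length(idx) - 1L
      if (n_tr < 1L)
        stop_input("class '", cl, "' has too few samples (", length(idx),
                   ") for a stratified train/validation split")
      idx_tr <- c(idx_tr, idx[seq_len(n_tr)])
    }
  })
  sort(idx_tr)
}

#' Train a network
#'
#' Cross-entropy training with SGD and momentum on a labeled image set. The
#' data are split 70:30 (stratified, seeded) into a training and a validation
#' part; every epoch records mean training loss/accuracy over the mini-batches
#' and validation loss/accuracy in inference mode. All randomness (split,
#' shuffling) derives from `config$seed`, so identical data, model and seed
#' reproduce identical weights.
#'
#' @param model a [build_model()] result (updated in place and returned).
#' @param dataset either a folder with one sub-directory of images per class,
#'   or a list with elements `x` (a `side x side x 3 x N` array) and `y`
#'   (factor of length N).
#' @param config a [train_config()].
#' @param verbose print per-epoch progress.
#' @return a list with elements `model` (trained) and `trace` (data.frame with
#'   columns epoch, train_loss, train_acc, val_loss, val_acc).
#' @export
train_model <- function(model, dataset, config = train_config(),
                        verbose = FALSE) {
  stopifnot(inherits(model, "gptnext_model"),
            inherits(config, "gptnext_train_config"))
  side <- model$spec$input_side
  if (is.character(dataset)) dataset <- load_image_folder(dataset, side)
  x <- dataset$x; y <- dataset$y
  if (!is.factor(y)) y <- factor(y)
  if (nlevels(y) < 2L) stop_input("training data must contain at least 2 classes")
  if (any(table(y) == 0L)) stop_input("empty class in training data")
  if (nlevels(y) != model$spec$num_classes)
    stop_input("data has ", nlevels(y), " classes but the model head expects ",
               model$spec$num_classes)
  n <- length(y)
  idx_tr <- stratified_split(y, config$train_val_ratio, derive_seed(config$seed, 2L))
  idx_va <- setdiff(seq_len(n), idx_tr)
  if (length(idx_va) == 0L || any(table(y[idx_va]) == 0L))
    stop_input("every class needs at least one validation sample")
  y0 <- as.integer(y) - 1L
  cpp_net_reset_velocity(model$ptr)
  trace <- data.frame(epoch = integer(0), train_loss = numeric(0),
                      train_acc = numeric(0), val_loss = numeric(0),
                      val_acc = numeric(0))
  eval_split <- function(idx) {
    # inference-mode loss/accuracy in small batches
    bs <- min(config$batch_size, 32L)
    tot_l <- 0; tot_c <- 0
    for (b in split(idx, ceiling(seq_along(idx) / bs))) {
      out <- forward_batch(model, x[, , , b, drop = FALSE], training = FALSE)
      p <- out$probs
      tot_l <- tot_l + sum(-log(pmax(p[cbind(seq_along(b), y0[b] + 1L)], 1e-300)))
      tot_c <- tot_c + sum(max.col(p, ties.method = "first") == y0[b] + 1L)
    }
    c(loss = tot_l / length(idx), acc = tot_c / length(idx))
  }
  calib <- idx_tr
  if (length(calib) > 256L)
    calib <- with_seed(derive_seed(config$seed, 99L),
                       unlist(lapply(split(calib, y[calib]), function(ix)
                         sample(ix, max(1L, round(256 * length(ix) / length(calib))))),
                         use.names = FALSE))
  for (epoch in seq_len(config$max_epochs)) {
    ord <- with_seed(derive_seed(config$seed, 100L + epoch), sample(idx_tr))
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_loss <- 0; ep_acc <- 0
    for (b in batches) {
      res <- tryCatch(
        cpp_net_train_batch(model$ptr, x[, , , b, drop = FALSE], y0[b],
                            config$learning_rate, config$momentum),
        error = function(e) stop_input("training diverged at epoch ", epoch,
                                       ": ", conditionMessage(e)))
      ep_loss <- ep_loss + res$loss * length(b)
      ep_acc <- ep_acc + res$acc * length(b)
    }
    # batch-norm calibration: pin running statistics to the training-set
    # statistics under the current weights before any inference-mode use
    cpp_net_calibrate_bn(model$ptr, x[, , , calib, drop = FALSE])
    va <- eval_split(idx_va)
    trace <- rbind(trace, data.frame(
      epoch = epoch, train_loss = ep_loss / length(idx_tr),
      train_acc = ep_acc / length(idx_tr),
      val_loss = unname(va["loss"]), val_acc = unname(va["acc"])))
    if (verbose)
      message(sprintf("epoch %3d  train loss %.4f acc %.3f | val loss %.4f acc %.3f",
                      epoch, trace$train_loss[epoch], trace$train_acc[epoch],
                      trace$val_loss[epoch], trace$val_acc[epoch]))
  }
  model$trained <- TRUE
  list(model = model, trace = trace)
}
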