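#' Build a GPTNeXt network
#'
#' Allocates and initializes all trainable parameters: truncated-normal
#' (sd 0.02, clipped at 2 sd) for convolution and fully-connected weights,
#' ones for normalization scales, zeros for biases and shifts. Initialization
#' is fully determined by `init_seed`.
#'
#' @param spec a [gptnext_spec()].
#' @param init_seed integer seed controlling weight initialization.
#' @return an object of class `gptnext_model`.
#' @examples
#' m <- build_model(gptnext_spec(filters = c(8, 16, 32, 64, 96),
#'                               input_side = 64, num_classes = 3))
#' count_parameters(m)
#' @export
build_model <- function(spec, init_seed = 1L) {
  stopifnot(inherits(spec, "gptnext_spec"))
  ptr <- cpp_net_create(spec)
  lay <- cpp_net_layout(ptr)
  params <- with_seed(derive_seed(init_seed, 1L), {
    unlist(lapply(seq_along(lay$sizes), function(i) {
      n <- lay$sizes[i]
      switch(lay$kinds[i],
             conv  = rtrunc_norm(n, 0.02),
             fc    = rtrunc_norm(n, 0.02),
             scale = rep(1, n),
             rep(0, n))  # bias, shift
    }), use.names = FALSE)
  })
  cpp_net_set_params(ptr, params)
  structure(list(spec = spec, ptr = ptr, mode = "inference",
                 init_seed = as.integer(init_seed), trained = FALSE),
            class = "gptnext_model")
}

#' Count trainable parameters
#'
#' Counts every trainable scalar: convolution kernels and biases,
#' normalization scales and shifts, fully-connected weights and biases.
#' Running batch-norm statistics are not trainable and are excluded.
#'
#' @param model a [build_model()] result.
#' @return the parameter count as a double.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "gptnext_model"))
  cpp_net_nparams(model$ptr)
}

# validate an image and return an (H, W, C, 1) array on the model's grid;
# grayscale inputs are channel-replicated
as_input_array <- function(image, spec, side = spec$input_side) {
  if (is.matrix(image)) image <- array(image, c(dim(image), 1L))
  d <- dim(image)
  if (length(d) != 3L)
    stop_input("image must be a side x side x channels array")
  if (d[3] == 1L && spec$input_channels == 3L)
    image <- array(rep(image, 3L), c(d[1], d[2], 3L))
  d <- dim(image)
  if (d[1] != side || d[2] != side || d[3] != spec$input_channels)
    stop_input("image dimensions ", paste(d, collapse = "x"),
               " do not match expected ", side, "x", side, "x",
               spec$input_channels)
  array(image, c(d, 1L))
}

# internal batched forward; x is an (H, W, C, N) array
forward_batch <- function(model, x, training = FALSE) {
  cpp_net_forward(model$ptr, x, training)
}

#' Class probabilities for one image
#'
#' Runs the network in inference mode (batch-norm uses running statistics, so
#' repeated calls on the same image are identical) and returns the softmax
#' class probabilities.
#'
#' @param model a [build_model()] result.
#' @param image a `input_side x input_side x channels` array with values in
#'   \[0, 1\] (a grayscale matrix is channel-replicated).
#' @return numeric vector of `num_classes` probabilities summing to 1.
#' @export
forward_logits <- function(model, image) {
  x <- as_input_array(image, model$spec)
  drop(forward_batch(model, x, training = FALSE)$probs)
}

#' GAP-layer deep features for one image
#'
#' Extracts the global-average-pooling features: the spatial mean of each
#' channel of the final (post output-block) activation map, a vector of
#' length `filters[5]` (1280 for the default schedule).
#'
#' @inheritParams forward_logits
#' @param side operating side; defaults to the spec's `input_side`. Smaller
#'   sides (e.g. native-resolution patches) run the same trunk fully
#'   convolutionally; the GAP length is unchanged.
#' @return numeric feature vector of length `filters[5]`.
#' @export
gap_features <- function(model, image, side = model$spec$input_side) {
  x <- as_input_array(image, model$spec, side = side)
  drop(forward_batch(model, x, training = FALSE)$gap)
}

#' @export
print.gptnext_model <- function(x, ...) {
  cat("GPTNeXt model:", format(count_parameters(x), big.mark = ","),
      "trainable parameters,", if (isTRUE(x$trained)) "trained" else "untrained", "\n")
  print(x$spec)
  invisible(x)
}

# --------------------------------------------------------- serialization ----

MODEL_MAGIC <- "gptnext-model-v1"

#' Save / load a model
#'
#' The archive is a one-line JSON header (format tag, architecture spec,
#' trained flag, parameter count) followed by the parameters and the running
#' batch-norm statistics as little-endian FP32. The FP32 payload is
#' `4 * count_parameters(model)` bytes (28.2 MiB for the default 4-class
#' model), so saving quantizes double-precision weights to FP32; a second
#' save/load round-trip is bit-exact.
#'
#' @param model a [build_model()] result.
#' @param path file path for the archive.
#' @return `save_model` returns `path` invisibly; `load_model` returns a
#'   `gptnext_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "gptnext_model"))
  params <- cpp_net_get_params(model$ptr)
  state <- cpp_net_get_state(model$ptr)
  header <- jsonlite::toJSON(list(
    magic = MODEL_MAGIC,
    spec = unclass(model$spec),
    trained = isTRUE(model$trained),
    init_seed = model$init_seed,
    n_params = length(params),
    n_state = length(state)), auto_unbox = TRUE)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw(as.character(header)), charToRaw("\n")), con)
  writeBin(params, con, size = 4L, endian = "little")
  writeBin(state, con, size = 4L, endian = "little")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  raw <- readBin(path, what = "raw", n = file.info(path)$size)
  nl <- which(raw == charToRaw("\n"))[1]
  if (is.na(nl))
    stop_input("not a gptnext model archive (no header): ", path)
  header <- tryCatch(
    jsonlite::fromJSON(rawToChar(raw[seq_len(nl - 1L)])),
    error = function(e) stop_input("corrupt model header in ", path, ": ",
                                   conditionMessage(e)))
  if (!identical(header$magic, MODEL_MAGIC))
    stop_input("not a gptnext model archive: ", path)
  spec <- do.call(gptnext_spec, header$spec[c("filters", "repetitions",
                                              "input_side", "input_channels",
                                              "num_classes", "expansion_factor")])
  payload <- raw[-seq_len(nl)]
  expected <- 4L * (header$n_params + header$n_state)
  if (length(payload) != expected)
    stop_input("truncated or corrupt model payload in ", path, ": expected ",
               expected, " bytes for the stored spec (",
               header$n_params, " parameters + ", header$n_state,
               " state values), found ", length(payload))
  vals <- readBin(payload, what = "double", size = 4L,
                  n = header$n_params + header$n_state, endian = "little")
  model <- build_model(spec, init_seed = header$init_seed %||% 1L)
  if (cpp_net_nparams(model$ptr) != header$n_params)
    stop_input("stored parameter count ", header$n_params,
               " does not match the rebuilt spec (",
               cpp_net_nparams(model$ptr), ")")
  cpp_net_set_params(model$ptr, vals[seq_len(header$n_params)])
  cpp_net_set_state(model$ptr, vals[-seq_len(header$n_params)])
  model$trained <- isTRUE(header$trained)
  model
}
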