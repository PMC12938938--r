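#' Architecture specification
#'
#' Defines a GPTNeXt network: a patchify stem (4x4 convolution, stride 4),
#' four stages of dual-shortcut inverted-bottleneck blocks at the first four
#' filter widths, grouped 2x2/stride-2 patchify downsampling between stages,
#' and an output block that widens to the last filter width before global
#' average pooling and the class head. The default schedule
#' `filters = c(96, 192, 384, 768, 1280)` with one block per stage yields
#' roughly 7.4 million trainable parameters for a 4-class head.
#'
#' @param filters five stage widths; consecutive trunk widths must be integer
#'   multiples (the grouped downsampling emits `filters[i+1]/filters[i]`
#'   output maps per input channel).
#' @param repetitions five positive integers; entries 1-4 give the number of
#'   blocks per stage (extra blocks are inserted before the stage's
#'   downsampling and are experimental), entry 5 must be 1.
#' @param input_side input image side in pixels; must be a multiple of 4 with
#'   `input_side/4 >= 8` so all stage sides stay positive (odd intermediate
#'   sides are floor-divided by the 2x2 stride-2 downsampling).
#' @param input_channels number of image channels (3 for RGB).
#' @param num_classes number of output classes, at least 2.
#' @param expansion_factor inverted-bottleneck widening of the depth-wise
#'   3x3 convolution inside each block sub-unit (default 4, e.g. 96 -> 384).
#' @return an object of class `gptnext_spec`.
#' @seealso [build_model()], [stage_shapes()]
#' @export
gptnext_spec <- function(filters = c(96L, 192L, 384L, 768L, 1280L),
                         repetitions = rep(1L, 5),
                         input_side = 224L,
                         input_channels = 3L,
                         num_classes = 2L,
                         expansion_factor = 4L) {
  filters <- as.integer(filters)
  repetitions <- as.integer(repetitions)
  if (length(filters) != 5L || any(filters <= 0L))
    stop_input("invalid spec: 'filters' must be 5 positive integers")
  if (length(repetitions) != 5L || any(repetitions <= 0L))
    stop_input("invalid spec: 'repetitions' must be 5 positive integers")
  if (repetitions[5] != 1L)
    stop_input("invalid spec: 'repetitions[5]' (output block) must be 1")
  for (i in 1:3)
    if (filters[i + 1] %% filters[i] != 0L)
      stop_input("invalid spec: filters[", i + 1, "] must be a multiple of filters[",
                 i, "] (grouped downsampling doubles or multiplies channels per group)")
  input_side <- as.integer(input_side)
  if (length(input_side) != 1L || input_side %% 4L != 0L || input_side < 32L)
    stop_input("invalid spec: 'input_side' must be a multiple of 4 and at least 32")
  num_classes <- as.integer(num_classes)
  if (num_classes < 2L)
    stop_input("invalid spec: 'num_classes' must be at least 2")
  expansion_factor <- as.integer(expansion_factor)
  if (expansion_factor < 1L)
    stop_input("invalid spec: 'expansion_factor' must be a positive integer")
  input_channels <- as.integer(input_channels)
  if (input_channels < 1L)
    stop_input("invalid spec: 'input_channels' must be a positive integer")
  structure(list(filters = filters, repetitions = repetitions,
                 input_side = input_side, input_channels = input_channels,
                 num_classes = num_classes,
                 expansion_factor = expansion_factor),
            class = "gptnext_spec")
}

#' Analytic stage shape trace
#'
#' Computes the spatial side and channel width after each stage of the trunk
#' without allocating any weights: stem (side/4), the three downsampled stages
#' (floor division by 2), and the output block (same side, widened channels).
#' Matches the shapes an actual forward pass produces.
#'
#' @param spec a [gptnext_spec()].
#' @return a data.frame with columns `stage`, `side`, `channels`; five rows
#'   (stage 1 block resolution through the post-output-convolution map).
#' @export
stage_shapes <- function(spec) {
  stopifnot(inherits(spec, "gptnext_spec"))
  side <- spec$input_side / 4L
  if (side != floor(side))
    stop_input("non-integer side after stem: input_side must be a multiple of 4")
  sides <- integer(5)
  sides[1] <- side
  for (i in 2:4) {
    side <- floor((side - 2) / 2) + 1  # 2x2 conv, stride 2
    if (side < 1)
      stop_input("non-positive side at stage ", i, "; increase input_side")
    sides[i] <- side
  }
  sides[5] <- sides[4]  # output block is 1x1, side unchanged
  data.frame(stage = c(paste0("stage", 1:4), "output"),
             side = sides, channels = spec$filters)
}

#' @export
print.gptnext_spec <- function(x, ...) {
  cat("GPTNeXt architecture spec\n")
  cat("  filters:         ", paste(x$filters, collapse = ", "), "\n")
  cat("  repetitions:     ", paste(x$repetitions, collapse = ", "), "\n")
  cat("  input:           ", x$input_side, "x", x$input_side, "x",
      x$input_channels, "\n")
  cat("  classes:         ", x$num_classes, "\n")
  cat("  expansion factor:", x$expansion_factor, "\n")
  invisible(x)
}
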