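#' Divide an image into nine overlapping fixed-size patches
#'
#' Slices a square image into a 3 x 3 grid of overlapping patches whose
#' top-left corners lie at offsets \{0, stride, 2*stride\} in both rows and
#' columns (0-based), ordered row-major (row offset varies slowest). With the
#' default geometry (side 224, patch 112, stride 56) this gives 9 patches with
#' 50% overlap: corner pixels are covered once, the central
#' `stride x stride` square four times.
#'
#' @param image a `side x side x C` array (or `side x side` matrix).
#' @param patch_side patch side in pixels; default `side/2`.
#' @param stride patch stride in pixels; default `side/4`. The geometry must
#'   satisfy `side == patch_side + 2*stride`.
#' @return an object of class `gptnext_patchset`: list with `patches` (list of
#'   9 arrays), `offsets` (9 x 2 matrix of 0-based (row, col) corners),
#'   `patch_side`, `stride`, `source_side`.
#' @export
divide_patches <- function(image, patch_side = NULL, stride = NULL) {
  if (is.matrix(image)) image <- array(image, c(dim(image), 1L))
  d <- dim(image)
  if (length(d) != 3L || d[1] != d[2])
    stop_input("image must be a square side x side x C array")
  side <- d[1]
  if (is.null(patch_side)) patch_side <- side %/% 2L
  if (is.null(stride)) stride <- side %/% 4L
  if (side != patch_side + 2L * stride)
    stop_input("patch geometry mismatch: expected image side ",
               patch_side + 2L * stride, " (= patch_side + 2*stride), got ", side)
  offs <- as.matrix(expand.grid(col = c(0L, stride, 2L * stride),
                                row = c(0L, stride, 2L * stride)))[, c("row", "col")]
  patches <- lapply(seq_len(nrow(offs)), function(k) {
    r <- offs[k, 1]; c0 <- offs[k, 2]
    image[r + seq_len(patch_side), c0 + seq_len(patch_side), , drop = FALSE]
  })
  structure(list(patches = patches, offsets = unname(offs),
                 patch_side = patch_side, stride = stride,
                 source_side = side),
            class = "gptnext_patchset")
}

#' @export
print.gptnext_patchset <- function(x, ...) {
  cat("patch set:", length(x$patches), "patches of", x$patch_side, "x",
      x$patch_side, "from a", x$source_side, "px image (stride", x$stride, ")\n")
  invisible(x)
}
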