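# image I/O: reading, bilinear resizing, labeled-folder loading.
# Images are handled internally as (height, width, channel) arrays in [0, 1].

#' Read an image file
#'
#' Reads PNG/JPEG/TIFF via EBImage, drops an alpha channel if present,
#' channel-replicates grayscale to RGB, and clamps to \[0, 1\].
#'
#' @param path image file.
#' @return an H x W x 3 numeric array in \[0, 1\].
#' @export
read_image <- function(path) {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)      # (x = column, y = row[, channel]) order
  if (length(dim(a)) == 2L) a <- array(a, c(dim(a), 1L))
  if (dim(a)[3] >= 4L) a <- a[, , 1:3, drop = FALSE]   # drop alpha
  if (dim(a)[3] == 1L) a <- array(rep(a, 3L), c(dim(a)[1:2], 3L))
  if (dim(a)[3] == 2L) a <- array(rep(a[, , 1], 3L), c(dim(a)[1:2], 3L))
  a <- aperm(a, c(2, 1, 3))         # to (row, column, channel)
  pmin(pmax(a, 0), 1)
}

#' Bilinear resize
#'
#' @param image an H x W x C array in \[0, 1\].
#' @param side target side in pixels (square output).
#' @return a side x side x C array.
#' @export
resize_bilinear <- function(image, side) {
  d <- dim(image)
  if (d[1] == side && d[2] == side) return(image)
  eb <- EBImage::Image(aperm(image, c(2, 1, 3)), colormode = "Color")
  out <- EBImage::resize(eb, w = side, h = side)  # bilinear filter
  a <- aperm(EBImage::imageData(out), c(2, 1, 3))
  pmin(pmax(a, 0), 1)
}

# list a labeled image folder: split_dir/<class>/*.{png,jpg,jpeg,tif,tiff}
# classes are directory names sorted lexicographically (C locale)
list_image_folder <- function(folder) {
  if (!dir.exists(folder))
    stop_input("image folder does not exist: ", folder)
  classes <- sort(list.dirs(folder, recursive = FALSE, full.names = FALSE),
                  method = "radix")
  if (length(classes) == 0L)
    stop_input("no class sub-directories under ", folder)
  files <- character(0); labels <- character(0)
  for (cl in classes) {
    f <- sort(list.files(file.path(folder, cl),
                         pattern = "\\.(png|jpg|jpeg|tif|tiff)$",
                         ignore.case = TRUE, full.names = TRUE),
              method = "radix")
    files <- c(files, f)
    labels <- c(labels, rep(cl, length(f)))
  }
  if (length(files) == 0L)
    stop_input("no image files under ", folder)
  list(files = files, labels = factor(labels, levels = classes))
}

# load a whole labeled folder into an (side, side, 3, N) array + labels;
# unreadable files are skipped with a warning
load_image_folder <- function(folder, side) {
  lst <- list_image_folder(folder)
  n <- length(lst$files)
  x <- array(0, c(side, side, 3L, n))
  keep <- logical(n)
  for (i in seq_len(n)) {
    img <- tryCatch(resize_bilinear(read_image(lst$files[i]), side),
                    error = function(e) {
                      warning("skipping unreadable image ", lst$files[i], ": ",
                              conditionMessage(e), call. = FALSE)
                      NULL
                    })
    if (!is.null(img)) { x[, , , i] <- img; keep[i] <- TRUE }
  }
  if (!any(keep))
    stop_input("all ", n, " images under ", folder, " were unreadable")
  if (!all(keep)) x <- x[, , , keep, drop = FALSE]
  list(x = x, y = droplevels(lst$labels[keep]), files = lst$files[keep],
       n_skipped = sum(!keep))
}
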