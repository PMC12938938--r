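# seeded synthetic data with the statistical structure the pipeline assumes:
# a smooth class-specific global pattern plus a class-specific high-frequency
# motif confined to one patch region, so patch-level features carry
# information beyond full-image features.

#' Synthetic image dataset specification
#'
#' Each image is `0.5 + global template + local motif + noise`, clipped to
#' \[0, 1\] and replicated over three channels (with independent per-channel
#' noise). The global template is a smooth two-dimensional cosine surface
#' whose frequency and phase are class-specific (low-frequency, whole-image
#' signal). The motif is a class-specific high-frequency checkerboard placed
#' at the center of one class-specific patch region of the 3 x 3 overlapping
#' patch grid (local signal confined to one patch).
#'
#' @param n_classes number of classes.
#' @param train_per_class,test_per_class images per class and split.
#' @param image_side image side in pixels (multiple of 4, >= 32).
#' @param global_amplitude amplitude of the global cosine template (0 turns
#'   the whole-image signal off).
#' @param motif_amplitude amplitude of the local checkerboard motif.
#' @param noise_sigma standard deviation of the i.i.d. pixel noise.
#' @param seed integer seed; generation is pure given (spec, seed).
#' @return an object of class `gptnext_synth_spec`.
#' @export
synthetic_image_spec <- function(n_classes = 3L, train_per_class = 20L,
                                 test_per_class = 10L, image_side = 64L,
                                 global_amplitude = 0.25,
                                 motif_amplitude = 0.5, noise_sigma = 0.1,
                                 seed = 1L) {
  if (n_classes < 2L) stop_input("n_classes must be at least 2")
  if (global_amplitude < 0 || motif_amplitude < 0 || noise_sigma < 0)
    stop_input("amplitudes and noise_sigma must be non-negative")
  if (image_side %% 4L != 0L || image_side < 32L)
    stop_input("image_side must be a multiple of 4 and at least 32")
  structure(list(n_classes = as.integer(n_classes),
                 train_per_class = as.integer(train_per_class),
                 test_per_class = as.integer(test_per_class),
                 image_side = as.integer(image_side),
                 global_amplitude = global_amplitude,
                 motif_amplitude = motif_amplitude,
                 noise_sigma = noise_sigma,
                 motif_region = ((seq_len(n_classes) - 1L) %% 9L) + 1L,
                 seed = as.integer(seed)),
            class = "gptnext_synth_spec")
}

# deterministic class pattern (global template + motif), side x side
synth_class_pattern <- function(spec, cl) {
  side <- spec$image_side
  u <- (seq_len(side) - 0.5) / side
  g <- matrix(0, side, side)
  if (spec$global_amplitude > 0) {
    fx <- 1 + (cl - 1) %% 3
    fy <- 1 + ((cl - 1) %/% 3) %% 3
    ph <- 2 * pi * (cl - 1) / spec$n_classes
    g <- spec$global_amplitude *
      outer(cos(2 * pi * fx * u + ph), cos(2 * pi * fy * u - ph))
  }
  if (spec$motif_amplitude > 0) {
    k <- spec$motif_region[cl]
    stride <- side %/% 4L
    off_r <- ((k - 1L) %/% 3L) * stride
    off_c <- ((k - 1L) %% 3L) * stride
    pside <- side %/% 2L
    mside <- pside %/% 2L
    r0 <- off_r + pside %/% 4L
    c0 <- off_c + pside %/% 4L
    period <- 2L + (cl - 1L) %% 3L
    idx_r <- r0 + seq_len(mside); idx_c <- c0 + seq_len(mside)
    checker <- outer(idx_r %/% period, idx_c %/% period,
                     function(a, b) ifelse((a + b) %% 2 == 0, 1, -1))
    g[idx_r, idx_c] <- g[idx_r, idx_c] + spec$motif_amplitude * 0.5 * checker
  }
  g
}

synth_image <- function(spec, cl) {
  side <- spec$image_side
  base <- 0.5 + synth_class_pattern(spec, cl)
  img <- array(rep(base, 3L), c(side, side, 3L))
  if (spec$noise_sigma > 0)
    img <- img + array(stats::rnorm(side * side * 3L, 0, spec$noise_sigma),
                       c(side, side, 3L))
  pmin(pmax(img, 0), 1)
}

#' Generate a synthetic labeled image dataset on disk
#'
#' Writes `train/<class>/*.png` and `test/<class>/*.png` under `out_dir`,
#' plus a `manifest.csv` recording file, split, class, motif region and seed.
#' Generation is deterministic: the same spec and seed produce byte-identical
#' files.
#'
#' @param spec a [synthetic_image_spec()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the manifest data.frame.
#' @export
generate_image_dataset <- function(spec, out_dir) {
  stopifnot(inherits(spec, "gptnext_synth_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  classes <- sprintf("class%02d", seq_len(spec$n_classes))
  manifest <- list()
  with_seed(derive_seed(spec$seed, 5L), {
    for (split in c("train", "test")) {
      n_img <- if (split == "train") spec$train_per_class else spec$test_per_class
      for (cl in seq_len(spec$n_classes)) {
        dir.create(file.path(out_dir, split, classes[cl]), recursive = TRUE,
                   showWarnings = FALSE)
        for (i in seq_len(n_img)) {
          img <- synth_image(spec, cl)
          fn <- file.path(out_dir, split, classes[cl],
                          sprintf("%s_%03d.png", classes[cl], i))
          png::writePNG(img, fn)
          manifest[[length(manifest) + 1L]] <- data.frame(
            file = fn, split = split, class = classes[cl],
            motif_region = spec$motif_region[cl], seed = spec$seed)
        }
      }
    }
  })
  manifest <- do.call(rbind, manifest)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Generate a synthetic image dataset in memory
#'
#' Same generator as [generate_image_dataset()] without the PNG round-trip;
#' returns the two splits as arrays. Values are identical to what the on-disk
#' generator encodes up to 8-bit quantization.
#'
#' @param spec a [synthetic_image_spec()].
#' @return list with `train` and `test`, each a list of `x`
#'   (side x side x 3 x N array), `y` (factor), `files` (synthetic ids).
#' @export
generate_image_arrays <- function(spec) {
  stopifnot(inherits(spec, "gptnext_synth_spec"))
  classes <- sprintf("class%02d", seq_len(spec$n_classes))
  out <- list()
  with_seed(derive_seed(spec$seed, 5L), {
    for (split in c("train", "test")) {
      n_img <- if (split == "train") spec$train_per_class else spec$test_per_class
      n <- n_img * spec$n_classes
      x <- array(0, c(spec$image_side, spec$image_side, 3L, n))
      y <- character(n); files <- character(n)
      j <- 0L
      for (cl in seq_len(spec$n_classes)) {
        for (i in seq_len(n_img)) {
          j <- j + 1L
          x[, , , j] <- synth_image(spec, cl)
          y[j] <- classes[cl]
          files[j] <- sprintf("%s_%03d.png", classes[cl], i)
        }
      }
      out[[split]] <- list(x = x, y = factor(y, levels = classes),
                           files = files)
    }
  })
  out
}

#' Feature fixture specification / generator
#'
#' Draws a labeled feature matrix with `n_informative` informative columns
#' (class-dependent means, adjacent classes separated by `effect_size` in
#' noise-SD units) at seeded random positions among `n_features` columns;
#' all remaining columns are standard-normal noise. Classes are balanced.
#'
#' @param n_samples total samples (multiple of `n_classes` recommended).
#' @param n_features total feature count d.
#' @param n_informative number of informative columns (<= d).
#' @param effect_size class-mean separation in noise-SD units (>= 0).
#' @param n_classes number of balanced classes.
#' @param seed integer seed.
#' @return a `gptnext_features` object with an extra `informative` field
#'   (the 1-based informative column indices).
#' @export
generate_feature_fixture <- function(n_samples = 200L, n_features = 500L,
                                     n_informative = 50L, effect_size = 1,
                                     n_classes = 2L, seed = 1L) {
  if (n_informative > n_features)
    stop_input("n_informative must not exceed n_features")
  if (effect_size < 0) stop_input("effect_size must be >= 0")
  classes <- sprintf("class%02d", seq_len(n_classes))
  y <- factor(rep(classes, length.out = n_samples), levels = classes)
  with_seed(derive_seed(seed, 6L), {
    X <- matrix(stats::rnorm(n_samples * n_features), n_samples, n_features)
    informative <- sort(sample.int(n_features, n_informative))
    # class c mean on every informative column: effect_size * (c - (K+1)/2)
    shift <- effect_size * (as.integer(y) - (n_classes + 1) / 2)
    X[, informative] <- X[, informative] + shift
  })
  colnames(X) <- sprintf("f%05d", seq_len(n_features))
  structure(list(X = X, y = y,
                 sample_ids = sprintf("synth_%04d", seq_len(n_samples)),
                 informative = informative),
            class = "gptnext_features")
}
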