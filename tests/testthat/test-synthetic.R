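test_that("image dataset generator writes the documented layout", {
  root <- tempfile("synth")
  spec <- synthetic_image_spec(n_classes = 3, train_per_class = 4,
                               test_per_class = 2, image_side = 32, seed = 5)
  manifest <- generate_image_dataset(spec, root)
  expect_equal(nrow(manifest), 3 * (4 + 2))
  expect_length(list.files(file.path(root, "train"), recursive = TRUE), 12)
  expect_length(list.files(file.path(root, "test"), recursive = TRUE), 6)
  expect_true(file.exists(file.path(root, "manifest.csv")))
  expect_setequal(unique(manifest$class), c("class01", "class02", "class03"))
  img <- read_image(file.path(root, "train", "class01", "class01_001.png"))
  expect_equal(dim(img), c(32, 32, 3))
  expect_true(all(img >= 0 & img <= 1))
})

test_that("generation is pure given (spec, seed): byte-identical files", {
  spec <- synthetic_image_spec(n_classes = 2, train_per_class = 3,
                               test_per_class = 1, image_side = 32, seed = 9)
  r1 <- tempfile(); r2 <- tempfile()
  generate_image_dataset(spec, r1)
  generate_image_dataset(spec, r2)
  f1 <- list.files(r1, recursive = TRUE, pattern = "png$", full.names = TRUE)
  f2 <- list.files(r2, recursive = TRUE, pattern = "png$", full.names = TRUE)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  spec2 <- synthetic_image_spec(n_classes = 2, train_per_class = 3,
                                test_per_class = 1, image_side = 32, seed = 10)
  r3 <- tempfile()
  generate_image_dataset(spec2, r3)
  f3 <- list.files(r3, recursive = TRUE, pattern = "png$", full.names = TRUE)
  expect_false(identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f3))))
})

test_that("noise-free classes are separable by raw-pixel nearest neighbor", {
  spec <- synthetic_image_spec(n_classes = 3, train_per_class = 2,
                               test_per_class = 2, image_side = 32,
                               noise_sigma = 0, seed = 4)
  ds <- generate_image_arrays(spec)
  flat <- function(x) t(apply(x, 4, as.vector))
  ps <- knn_predict(flat(ds$train$x), ds$train$y, flat(ds$test$x))
  expect_equal(as.character(ps$y_pred), as.character(ds$test$y))
})

test_that("in-memory arrays match the PNG files up to 8-bit quantization", {
  spec <- synthetic_image_spec(n_classes = 2, train_per_class = 2,
                               test_per_class = 1, image_side = 32, seed = 6)
  root <- tempfile()
  generate_image_dataset(spec, root)
  ds <- generate_image_arrays(spec)
  on_disk <- read_image(file.path(root, "train", "class01", "class01_001.png"))
  expect_equal(on_disk, ds$train$x[, , , 1], tolerance = 1 / 255)
})

test_that("feature fixture: shape, separation calibration, null behavior", {
  fx <- generate_feature_fixture(n_samples = 500, n_features = 40,
                                 n_informative = 10, effect_size = 1, seed = 8)
  expect_equal(dim(fx$X), c(500, 40))
  expect_equal(as.vector(table(fx$y)), c(250, 250))
  # empirical class-mean separation of informative columns near effect_size
  sep <- colMeans(fx$X[fx$y == "class02", fx$informative]) -
         colMeans(fx$X[fx$y == "class01", fx$informative])
  expect_lt(abs(mean(sep) - 1), 0.2)
  # non-informative columns carry no signal
  noise_cols <- setdiff(seq_len(40), fx$informative)
  sep0 <- colMeans(fx$X[fx$y == "class02", noise_cols]) -
          colMeans(fx$X[fx$y == "class01", noise_cols])
  expect_lt(abs(mean(sep0)), 0.2)
  expect_error(generate_feature_fixture(n_features = 5, n_informative = 6),
               "exceed")
})

test_that("zero effect size yields chance-level cross-validated accuracy", {
  fx <- generate_feature_fixture(n_samples = 200, n_features = 30,
                                 n_informative = 10, effect_size = 0, seed = 3)
  cv <- cross_validate(fx$X, fx$y, "knn", stratified_folds(fx$y, 10, seed = 7))
  acc <- mean(cv$predictions$y_pred == fx$y)
  expect_lt(abs(acc - 0.5), 0.1)
})
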