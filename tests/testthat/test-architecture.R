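test_that("stage shape trace matches the transition schedule", {
  sh <- stage_shapes(gptnext_spec(num_classes = 4))
  expect_equal(sh$side, c(56, 28, 14, 7, 7))
  expect_equal(sh$channels, c(96, 192, 384, 768, 1280))

  sh112 <- stage_shapes(gptnext_spec(input_side = 112))
  expect_equal(sh112$side, c(28, 14, 7, 3, 3))   # floor division on odd sides

  expect_equal(stage_shapes(gptnext_spec(input_side = 32))$side[5], 1)
})

test_that("spec invariants are enforced with informative errors", {
  expect_error(gptnext_spec(filters = c(96, 192, 384)), "filters")
  expect_error(gptnext_spec(num_classes = 1), "num_classes")
  expect_error(gptnext_spec(input_side = 30), "input_side")
  expect_error(gptnext_spec(filters = c(96, 100, 384, 768, 1280)), "multiple")
})

test_that("parameter counting: stem enumeration, head size, monotonicity", {
  m <- tiny_model()
  lay <- gptnext:::cpp_net_layout(m$ptr)
  # stem = conv W + bias + BN scale + shift, hand-enumerated
  f1 <- tiny_arch()$filters[1]
  expect_equal(sum(lay$sizes[1:4]), 4 * 4 * 3 * f1 + f1 + 2 * f1)

  # class head adds (gap_len + 1) parameters per class
  m2 <- build_model(tiny_arch(num_classes = 3L))
  expect_equal(count_parameters(m2) - count_parameters(m),
               tiny_arch()$filters[5] + 1)

  # widening the inverted bottleneck strictly increases the count
  wide <- gptnext_spec(filters = c(4, 8, 16, 32, 24), input_side = 32,
                       num_classes = 2, expansion_factor = 4)
  expect_gt(count_parameters(build_model(wide)), count_parameters(m))
})

test_that("forward pass: softmax output, determinism, input validation", {
  m <- tiny_model()
  img <- rand_image(32)
  p <- forward_logits(m, img)
  expect_length(p, 2)
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_identical(p, forward_logits(m, img))
  expect_error(forward_logits(m, rand_image(64)), "dimensions")
})

test_that("compiled forward matches the naive R reference implementation", {
  m <- tiny_model()
  img <- rand_image(32, seed = 4)
  ref <- ref_forward(m, img)
  expect_equal(gap_features(m, img), ref$gap, tolerance = 1e-10)
  expect_equal(forward_logits(m, img), ref$probs, tolerance = 1e-10)
})

test_that("GAP features equal the explicit spatial mean of the final map", {
  m <- tiny_model()
  img <- rand_image(32, seed = 9)
  out <- gptnext:::forward_batch(m, gptnext:::as_input_array(img, m$spec))
  hw <- out$hw
  expect_equal(dim(out$pregap), c(hw, m$spec$filters[5]))
  expect_equal(drop(out$gap), colMeans(out$pregap), tolerance = 1e-12)
  expect_length(drop(out$gap), m$spec$filters[5])
})

test_that("residual identity: zeroed sub-units make each block the identity", {
  m <- build_model(tiny_arch(), init_seed = 7L)
  params <- gptnext:::cpp_net_get_params(m$ptr)
  lay <- gptnext:::cpp_net_layout(m$ptr)
  # walk the layout and zero every block point-wise convolution (weights and
  # biases); with BN shifts at their zero init each sub-unit output vanishes
  ends <- cumsum(lay$sizes)
  starts <- ends - lay$sizes + 1L
  # layout order: stem(4), then per sub-unit: ln g, ln b, dw W, dw b, pw W,
  # pw b, bn g, bn b (8 tensors), with 4 downsample tensors after stages 1-3
  pos <- 5L
  spec <- tiny_arch()
  for (i in 1:4) {
    for (r in seq_len(spec$repetitions[i])) for (s in 1:2) {
      for (tens in c(5L, 6L))  # pw W, pw b within the 8-tensor sub-unit
        params[starts[pos + tens - 1L]:ends[pos + tens - 1L]] <- 0
      pos <- pos + 8L
    }
    if (i < 4) pos <- pos + 4L  # downsample: conv W, conv b, ln g, ln b
  }
  gptnext:::cpp_net_set_params(m$ptr, params)
  img <- rand_image(32, seed = 12)
  ref <- ref_forward(m, img, skip_blocks = TRUE)
  expect_equal(gap_features(m, img), ref$gap, tolerance = 1e-10)
})

test_that("analytic gradients match central finite differences", {
  m <- build_model(tiny_arch(), init_seed = 17L)
  set.seed(3)
  x <- array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  y0 <- c(0L, 1L)
  params <- gptnext:::cpp_net_get_params(m$ptr)
  ana <- gptnext:::cpp_net_loss_grad(m$ptr, x, y0, TRUE)$grad
  idx <- sort(sample(length(params), 40))
  eps <- 1e-5
  num <- vapply(idx, function(i) {
    p <- params
    p[i] <- params[i] + eps
    gptnext:::cpp_net_set_params(m$ptr, p)
    l1 <- gptnext:::cpp_net_loss_grad(m$ptr, x, y0, TRUE)$loss
    p[i] <- params[i] - eps
    gptnext:::cpp_net_set_params(m$ptr, p)
    l2 <- gptnext:::cpp_net_loss_grad(m$ptr, x, y0, TRUE)$loss
    (l1 - l2) / (2 * eps)
  }, 0)
  gptnext:::cpp_net_set_params(m$ptr, params)
  rel <- abs(num - ana[idx]) / pmax(1e-6, abs(num) + abs(ana[idx]))
  expect_lt(max(rel), 1e-4)
})

test_that("twenty SGD steps on one batch decrease the training loss", {
  m <- build_model(tiny_arch(), init_seed = 23L)
  set.seed(5)
  x <- array(runif(32 * 32 * 3 * 8), c(32, 32, 3, 8))
  y0 <- rep(0:1, 4)
  losses <- vapply(1:20, function(i)
    gptnext:::cpp_net_train_batch(m$ptr, x, y0, 0.01, 0.9)$loss, 0)
  expect_lt(losses[20], losses[1])
  expect_lt(min(losses), 0.5 * losses[1])
})
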