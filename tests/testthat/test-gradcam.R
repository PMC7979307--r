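test_that("global average pooling is the spatial mean per feature map", {
  expect_identical(global_average_pool(array(5, c(3, 3, 3, 1))), 5)
  expect_identical(global_average_pool(array(0:7, c(2, 2, 2, 1))), 3.5)
  expect_identical(global_average_pool(array(0, c(2, 2, 2, 2))), c(0, 0))
  # multiple maps pool independently
  a <- array(0, c(2, 2, 2, 2)); a[, , , 2] <- 1:8
  expect_identical(global_average_pool(a), c(0, 4.5))
  expect_error(global_average_pool(numeric(0)), "empty")
})

test_that("class weights are the per-map gradient sums", {
  expect_identical(class_weights(array(0, c(2, 2, 3))), c(0, 0, 0))
  paired <- array(rep(c(1, -1), 4), c(2, 2, 2, 1))
  expect_identical(class_weights(paired), 0)
  expect_identical(class_weights(array(c(1, 2, 3, 4), c(2, 2, 1))), 10)
  expect_identical(class_weights(array(c(1, 2, 3, 4), c(2, 2, 1)), mode = "mean"), 2.5)
})

test_that("Grad-CAM equals the closed-form CAM on GAP+linear networks", {
  for (seed in 1:4) {
    m <- build_model(gap_toy_description(edge = 6L, maps = 5L), seed = seed)
    set.seed(seed + 100)
    v <- array(rnorm(6^3), c(6, 6, 6))
    for (cls in 0:1) {
      hm <- grad_cam(m, v, class_index = cls)
      cam <- cam_reference(m, v, class_index = cls)
      expect_lt(max(abs(hm$values / max(hm$values, 1e-30) - cam$normalized)), 1e-5)
      # raw maps agree up to a single positive scale (the GAP 1/z factor)
      pos <- cam$values > 1e-6
      if (any(pos)) {
        ratio <- hm$values[pos] / cam$values[pos]
        expect_lt(diff(range(ratio)) / max(ratio), 1e-4)
        expect_gt(min(ratio), 0)
      }
    }
  }
})

test_that("heatmaps are everywhere non-negative and reproducible", {
  m <- build_model(tiny_description(), seed = 4)
  set.seed(8)
  v <- array(rnorm(7^3), c(7, 7, 7))
  h1 <- grad_cam(m, v, class_index = 1)
  expect_true(all(h1$values >= 0))
  expect_true(all(h1$upsampled >= 0))
  h2 <- grad_cam(m, v, class_index = 1)
  expect_identical(h1$values, h2$values)       # bit-identical recomputation
  expect_identical(h1$upsampled, h2$upsampled)
})

test_that("a class score constant in the input yields a zero heatmap", {
  m <- build_model(gap_toy_description(edge = 5L, maps = 3L, kernel = 2L), seed = 2)
  # zero the dense layer: class scores become constants, all gradients vanish
  di <- length(m$description$layers)
  to <- m$compiled$desc[di, 19] + 1L
  m$theta[to:(to + m$compiled$desc[di, 20] - 1L)] <- 0
  v <- array(rnorm(5^3), c(5, 5, 5))
  hm <- grad_cam(m, v, class_index = 1)
  expect_identical(max(abs(hm$weights)), 0)
  expect_true(all(hm$values == 0))
  expect_true(all(hm$upsampled == 0))
})

test_that("one positive map with positive weight reproduces the activation map", {
  m <- build_model(gap_toy_description(edge = 5L, maps = 1L, kernel = 2L,
                                       conv_act = "relu"), seed = 3)
  # force a positive dense weight for class 1 on the single map
  di <- length(m$description$layers)
  to <- m$compiled$desc[di, 19] + 1L
  m$theta[to:(to + 1L)] <- c(-0.5, 0.7)   # class0, class1 weights
  v <- array(abs(rnorm(5^3)) + 0.5, c(5, 5, 5))
  hm <- grad_cam(m, v, class_index = 1)
  A <- hm$activations[, , , 1]
  expect_gt(max(A), 0)
  expect_equal(hm$values / max(hm$values), A / max(A), tolerance = 1e-5)
})

test_that("normalized heatmaps are identical under sum and mean weighting", {
  m <- build_model(tiny_description(), seed = 6)
  set.seed(12)
  v <- array(rnorm(7^3), c(7, 7, 7))
  hs <- grad_cam(m, v, class_index = 1, weight_mode = "sum")
  hmn <- grad_cam(m, v, class_index = 1, weight_mode = "mean")
  # raw values differ exactly by the constant spatial size z
  z <- prod(dim(hs$values))
  expect_equal(hs$values, hmn$values * z, tolerance = 1e-6)
  expect_equal(hs$upsampled, hmn$upsampled, tolerance = 1e-6)
})

test_that("rescaling activations with compensated head leaves the map unchanged", {
  d <- gap_toy_description(edge = 5L, maps = 4L, kernel = 2L, conv_act = "relu")
  m <- build_model(d, seed = 9)
  v <- array(rnorm(5^3), c(5, 5, 5))
  h1 <- grad_cam(m, v, class_index = 1)
  # scale conv weights and biases by c, dense weights by 1/c: scores unchanged
  cfac <- 3.7
  m2 <- m
  conv_to <- m$compiled$desc[1, 19] + 1L
  conv_len <- m$compiled$desc[1, 20]
  m2$theta[conv_to:(conv_to + conv_len - 1L)] <-
    m2$theta[conv_to:(conv_to + conv_len - 1L)] * cfac
  di <- length(d$layers)
  dto <- m$compiled$desc[di, 19] + 1L
  dnw <- m$compiled$desc[di, 3] * m$compiled$desc[di, 2]
  m2$theta[dto:(dto + dnw - 1L)] <- m2$theta[dto:(dto + dnw - 1L)] / cfac
  h2 <- grad_cam(m2, v, class_index = 1)
  expect_equal(predict(m, v, type = "score"), predict(m2, v, type = "score"),
               tolerance = 1e-4)
  expect_lt(max(abs(h1$upsampled - h2$upsampled)), 1e-5)
})

test_that("invalid targets are rejected", {
  m <- build_model(tiny_description(), seed = 1)
  v <- array(rnorm(7^3), c(7, 7, 7))
  expect_error(grad_cam(m, v, class_index = 2), "class index")
  expect_error(grad_cam(m, v, target_layer = 2), "not a convolution")
})

test_that("upsampled heatmaps live on the input grid with max exactly 1", {
  m <- build_model(tiny_description(), seed = 5)
  set.seed(3)
  v <- array(rnorm(7^3), c(7, 7, 7))
  hm <- grad_cam(m, v, class_index = 0)
  expect_identical(dim(hm$upsampled), c(7L, 7L, 7L))
  if (max(hm$values) > 0) expect_identical(max(hm$upsampled), 1)
  expect_true(all(hm$upsampled >= 0 & hm$upsampled <= 1))
})

test_that("upsampled heatmaps are aligned through the receptive-field map", {
  # single valid k=3 conv: cell c (0-based) is centred at input voxel c+1.
  # With a centre-peaked kernel the conv output has its unique maximum at
  # the cell centred on a bright spike, so the upsampled argmax must recover
  # the spike's voxel position exactly.
  d <- network_description("align", c(9L, 9L, 9L, 1L), list(
    layer_spec("conv3d", 1, 1, kernel = 3, padding = "valid", activation = "relu"),
    layer_spec("avgpool_global"), layer_spec("flatten"),
    layer_spec("dense", 1, 2)))
  m <- build_model(d, seed = 1)
  m$theta[1:27] <- 0.1; m$theta[14] <- 1; m$theta[28] <- 0  # centre-peaked kernel
  m$theta[29:30] <- c(-1, 1); m$theta[31:32] <- 0   # dense: class 1 follows the map
  for (spike in list(c(3L, 5L, 7L), c(3L, 3L, 3L), c(7L, 7L, 7L))) {
    v <- array(0, c(9, 9, 9))
    v[spike[1], spike[2], spike[3]] <- 1
    hm <- grad_cam(m, v, class_index = 1)
    am <- arrayInd(which.max(hm$upsampled), dim(hm$upsampled))
    expect_identical(as.integer(am), spike)
  }
})

test_that("linear upsampling preserves constants and endpoints", {
  const <- upsample_linear(array(2.5, c(3, 3, 3)), c(9, 9, 9))
  expect_true(all(abs(const - 2.5) < 1e-12))
  ident <- upsample_linear(array(1:27, c(3, 3, 3)), c(3, 3, 3))
  expect_identical(ident, array(as.numeric(1:27), c(3, 3, 3)))
})

test_that("overlay blending obeys its limit cases", {
  set.seed(4)
  v <- array(runif(5^3), c(5, 5, 5))
  zero <- array(0, c(5, 5, 5))
  img <- overlay(v, zero, slice_axis = 3, slice_index = 3, alpha = 0.8)
  sl <- v[, , 3]
  sl <- (sl - min(sl)) / diff(range(sl))
  for (ch in 1:3) expect_equal(img[, , ch], sl, tolerance = 1e-12)

  sat <- array(1, c(5, 5, 5))
  img2 <- overlay(v, sat, slice_axis = 1, slice_index = 2, alpha = 1)
  top <- grDevices::col2rgb(grDevices::hcl.colors(256, "Inferno")[256]) / 255
  for (ch in 1:3) expect_true(all(abs(img2[, , ch] - top[ch]) < 1e-12))

  expect_error(overlay(v, zero, slice_axis = 3, slice_index = 9), "out of bounds")
  expect_error(overlay(v, array(0, c(4, 4, 4))), "resolution")
})
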