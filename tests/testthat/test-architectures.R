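test_that("canonical descriptions reproduce every consistent printed count", {
  printed_ok <- list(
    proposed3d = c(3472, 2064, 16400, 4128, 8224, 16448, 16640, 1024, 514),
    alexnet3d = c(8208, 13856, 55360, 110656, 409800, 15075, 152),
    alexnet2d = c(272, 4640, 18496, 36928, 102600, 15075, 152))
  for (arch in names(printed_ok)) {
    d <- canonical_description(arch)
    a <- audit(d)
    matched <- a$realized[a$status == "match"]
    expect_true(all(printed_ok[[arch]] %in% matched),
                info = paste(arch, "missing printed cells"))
    expect_true(attr(a, "pass"))
  }
})

test_that("exactly the two inconsistent printed cells carry the typo flag", {
  a3 <- audit(canonical_description("alexnet3d"))
  expect_identical(sum(a3$status == "known-typo"), 1L)
  expect_identical(a3$printed[a3$status == "known-typo"], 53328L)
  expect_identical(a3$realized[a3$status == "known-typo"], 55328L)

  a2 <- audit(canonical_description("alexnet2d"))
  expect_identical(sum(a2$status == "known-typo"), 1L)
  expect_identical(a2$printed[a2$status == "known-typo"], 18454L)
  expect_identical(a2$realized[a2$status == "known-typo"], 18464L)

  ap <- audit(canonical_description("proposed3d"))
  expect_identical(sum(ap$status == "known-typo"), 0L)
})

test_that("a wrong realized count surfaces as a mismatch and fails the audit", {
  d <- canonical_description("proposed3d")
  d$layers[[1]] <- layer_spec("conv3d", 1, 16, kernel = 5, padding = "same",
                              activation = "relu")
  a <- audit(d)
  expect_false(attr(a, "pass"))
  expect_identical(a$status[1], "mismatch")
})

test_that("audit of a built model uses realized counts off the parameter vectors", {
  for (arch in c("proposed3d", "alexnet3d", "alexnet2d")) {
    m <- build_model(canonical_description(arch), seed = 1)
    a <- audit(m)
    expect_true(attr(a, "pass"))
    expect_identical(sum(a$realized), sum(m$realized_counts))
    # theta + batchnorm running stats account for every counted parameter
    expect_identical(sum(a$realized),
                     as.integer(length(m$theta) + length(m$state)))
  }
})

test_that("parameter counts are invariant to the padding resolution", {
  d <- canonical_description("proposed3d")
  flipped <- d
  flipped$layers <- lapply(d$layers, function(l) {
    if (l$kind == "conv3d")
      l$padding <- "same"  # rebuild the all-same variant
    l
  })
  # channel flow unchanged -> identical realized counts even though shapes move
  f <- network_description("proposed3d_same", c(27L, 27L, 27L, 1L),
                           flipped$layers, d$expected_counts)
  a1 <- audit(canonical_description("proposed3d"))
  a2 <- audit(f)
  expect_identical(a1$realized, a2$realized)
  expect_true(attr(a2, "pass"))
})

test_that("builds are deterministic and forward maps to a softmax pair", {
  m1 <- build_model(canonical_description("proposed3d"), seed = 11)
  m2 <- build_model(canonical_description("proposed3d"), seed = 11)
  expect_identical(m1$theta, m2$theta)     # bit-identical initial weights
  m3 <- build_model(canonical_description("proposed3d"), seed = 12)
  expect_false(identical(m1$theta, m3$theta))

  v <- array(rnorm(27^3), c(27, 27, 27))
  s <- predict(m1, v, type = "score")
  expect_identical(dim(s), c(1L, 2L))
  p <- predict(m1, v)
  expect_true(p >= 0 && p <= 1)
  # softmax of the two scores sums to one
  sm <- exp(s - max(s)); sm <- sm / sum(sm)
  expect_equal(sum(sm), 1, tolerance = 1e-6)
})

test_that("initial weights respect the stated maximum magnitude", {
  m <- build_model(canonical_description("proposed3d"), seed = 5)
  expect_true(max(abs(m$theta)) <= 1)
})

test_that("shape errors name the offending layer", {
  bad <- network_description("bad", c(5L, 5L, 5L, 1L), list(
    layer_spec("conv3d", 1, 2, kernel = 3, padding = "valid"),
    layer_spec("maxpool3d", kernel = 4)))
  expect_error(build_model(bad), "layer 2.*below 1")
  badc <- network_description("badc", c(3L, 3L, 3L, 1L), list(
    layer_spec("conv3d", 1, 2, kernel = 5, padding = "valid")))
  expect_error(build_model(badc), "layer 1.*below 1")
})

test_that("channel-incompatible layer lists are rejected", {
  expect_error(
    network_description("x", c(5L, 5L, 5L, 1L), list(
      layer_spec("conv3d", 1, 4, kernel = 2),
      layer_spec("conv3d", 8, 4, kernel = 2))),
    "channel mismatch")
})

test_that("descriptions round-trip through YAML and JSON", {
  for (arch in c("proposed3d", "alexnet2d")) {
    d <- canonical_description(arch)
    for (ext in c("yaml", "json")) {
      path <- file.path(tempdir(), paste0(arch, ".", ext))
      write_description(d, path)
      d2 <- read_description(path)
      expect_identical(d2$name, d$name)
      expect_identical(d2$input_shape, d$input_shape)
      expect_identical(length(d2$layers), length(d$layers))
      a <- audit(d2)
      expect_true(attr(a, "pass"))
      expect_identical(a$realized, audit(d)$realized)
      unlink(path)
    }
  }
})

test_that("the canonical YAML files shipped with the package audit clean", {
  for (arch in c("proposed3d", "alexnet3d", "alexnet2d")) {
    path <- system.file("extdata", paste0(arch, ".yaml"), package = "nodulecam")
    expect_true(nzchar(path))
    expect_true(attr(audit(read_description(path)), "pass"))
  }
})
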