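test_that("cross-entropy matches hand-computed values and is overflow-safe", {
  expect_equal(cross_entropy_loss(c(0, 0), 0), log(2), tolerance = 1e-12)
  expect_equal(cross_entropy_loss(c(0, 0), 1), log(2), tolerance = 1e-12)
  # extreme scores: exact zero loss, no overflow
  expect_identical(cross_entropy_loss(c(1000, -1000), 0), 0)
  expect_identical(cross_entropy_loss(c(-1000, 1000), 1), 0)
  # -log(e^2 / (e^1 + e^2)) = log(1 + e^-1)
  expect_equal(cross_entropy_loss(c(1, 2), 1), log(1 + exp(-1)), tolerance = 1e-12)
  expect_equal(cross_entropy_loss(c(1, 2), 1), 0.31326, tolerance = 1e-5)
  # batch mean
  expect_equal(cross_entropy_loss(rbind(c(0, 0), c(1, 2)), c(0, 1)),
               (log(2) + log(1 + exp(-1))) / 2, tolerance = 1e-12)
  expect_error(cross_entropy_loss(c(0, 0), 2), "labels")
})

test_that("analytic loss gradient matches finite differences within 1e-4", {
  set.seed(41)
  for (rep in 1:5) {
    s <- matrix(rnorm(12, sd = 2), ncol = 2)
    y <- sample(0:1, 6, replace = TRUE)
    g <- nodulecam:::cross_entropy_grad(s, y)
    h <- 1e-5
    num <- s * 0
    for (i in seq_len(nrow(s))) for (j in 1:2) {
      sp <- s; sp[i, j] <- sp[i, j] + h
      sm <- s; sm[i, j] <- sm[i, j] - h
      num[i, j] <- (cross_entropy_loss(sp, y) - cross_entropy_loss(sm, y)) / (2 * h)
    }
    expect_lt(max(abs(num - g)), 1e-4)
    # softmax-minus-onehot structure: rows sum to zero
    expect_true(all(abs(rowSums(g)) < 1e-12))
  }
})

test_that("training runs the requested epochs and logs one entry per epoch", {
  ds <- generate_dataset(tiny_phantom_config(), 4, 4, seed = 2)
  sp <- make_splits(ds$labels, 0.75, 0.34, seed = 3)
  m <- build_model(tiny_description(), seed = 1)
  fit <- train(m, ds, sp, train_config(epochs = 1, batch_size = 2, seed = 5))
  expect_identical(nrow(fit$history), 1L)
  expect_true(fit$model$trained)
  fit3 <- train(m, ds, sp, train_config(epochs = 3, batch_size = 2, seed = 5,
                                        early_stop_patience = NULL))
  expect_identical(nrow(fit3$history), 3L)
  expect_identical(fit3$history$epoch, 1:3)
  # best epoch is the validation-loss minimum, earliest on ties
  expect_identical(attr(fit3$history, "best_epoch"),
                   which.min(fit3$history$val_loss))
})

test_that("a zero-rate optimizer path leaves trainable weights unchanged", {
  ds <- generate_dataset(tiny_phantom_config(), 3, 3, seed = 4)
  sp <- make_splits(ds$labels, 0.67, 0.5, seed = 3)
  m <- build_model(tiny_description(), seed = 9)
  fit <- train(m, ds, sp, train_config(learning_rate = 1e-30, epochs = 2,
                                       batch_size = 2, seed = 5))
  expect_equal(fit$model$theta, m$theta, tolerance = 1e-12)
})

test_that("training histories replay exactly under a fixed seed", {
  ds <- generate_dataset(tiny_phantom_config(), 4, 4, seed = 6)
  sp <- make_splits(ds$labels, 0.75, 0.34, seed = 3)
  cfg <- train_config(epochs = 2, batch_size = 2, seed = 11)
  f1 <- train(build_model(tiny_description(), seed = 1), ds, sp, cfg)
  f2 <- train(build_model(tiny_description(), seed = 1), ds, sp, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$theta, f2$model$theta)
})

test_that("an untrained model with a zeroed head predicts exactly 1/2", {
  m <- build_model(tiny_description(), seed = 2)
  di <- length(m$description$layers)
  to <- m$compiled$desc[di, 19] + 1L
  m$theta[to:(to + m$compiled$desc[di, 20] - 1L)] <- 0
  vols <- lapply(1:3, function(i) array(rnorm(7^3), c(7, 7, 7)))
  p <- predict(m, vols)
  expect_identical(p, rep(0.5, 3))
})

test_that("class probabilities complement each other", {
  m <- build_model(tiny_description(), seed = 3)
  vols <- lapply(1:4, function(i) array(rnorm(7^3), c(7, 7, 7)))
  s <- predict(m, vols, type = "score")
  p <- exp(s) / rowSums(exp(s))
  expect_true(all(abs(rowSums(p) - 1) < 1e-6))
  expect_equal(predict(m, vols), p[, 2], tolerance = 1e-12)
})

test_that("loss decreases over the first epochs on easy phantoms", {
  # median over three seeds of the drop from epoch 1 to the best of 4
  drops <- vapply(1:3, function(sd0) {
    ds <- generate_dataset(tiny_phantom_config(), 10, 10, seed = 20 + sd0)
    sp <- make_splits(ds$labels, 0.8, 0.25, seed = 3)
    m <- build_model(tiny_description(), seed = sd0)
    fit <- train(m, ds, sp, train_config(epochs = 4, batch_size = 4,
                                         learning_rate = 1e-3, seed = sd0,
                                         early_stop_patience = NULL))
    fit$history$train_loss[1] - min(fit$history$train_loss)
  }, numeric(1))
  expect_gt(stats::median(drops), 0)
})

test_that("shape mismatches abort before the first step", {
  ds <- generate_dataset(tiny_phantom_config(), 3, 3, seed = 4)
  sp <- make_splits(ds$labels, 0.67, 0.5, seed = 3)
  m27 <- build_model(canonical_description("proposed3d"), seed = 1)
  expect_error(train(m27, ds, sp, train_config(epochs = 1)), "does not match")
})

test_that("the held-out test split warns when scored a second time", {
  ds <- generate_dataset(tiny_phantom_config(), 4, 4, seed = 31)
  sp <- make_splits(ds$labels, 0.5, 0.34, seed = 77)
  m <- build_model(tiny_description(), seed = 1)
  fit <- train(m, ds, sp, train_config(epochs = 1, batch_size = 2, seed = 5))
  # validation may be scored repeatedly
  expect_silent(validate(fit$model, ds, sp))
  expect_silent(validate(fit$model, ds, sp))
  expect_warning(r1 <- evaluate_test(fit$model, ds, sp), NA)
  expect_warning(evaluate_test(fit$model, ds, sp), "only once")
  expect_s3_class(r1, "metrics_report")
})
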