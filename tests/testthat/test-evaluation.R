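test_that("confusion counts partition the samples with ties counted positive", {
  cc <- confusion(c(1, 0), c(0.9, 0.1))
  expect_identical(unlist(cc[c("tp", "fp", "fn", "tn")]),
                   c(tp = 1L, fp = 0L, fn = 0L, tn = 1L))
  # probability exactly at the threshold is a positive prediction
  tie <- confusion(c(1, 0), c(0.5, 0.5), threshold = 0.5)
  expect_identical(tie$tp, 1L)
  expect_identical(tie$fp, 1L)
  expect_error(confusion(numeric(0), numeric(0)), "empty")
  expect_error(confusion(c(0, 2), c(0.1, 0.2)), "labels")
  expect_error(confusion(c(0, 1), c(0.1, 0.2), threshold = 2), "threshold")
})

test_that("confusion counts equal a per-sample loop oracle on random inputs", {
  set.seed(31)
  y <- sample(0:1, 200, replace = TRUE)
  p <- runif(200)
  for (thr in c(0.25, 0.5, 0.75)) {
    cc <- confusion(y, p, thr)
    tp <- fp <- fn <- tn <- 0L
    for (i in seq_along(y)) {
      pred <- p[i] >= thr
      if (pred && y[i] == 1) tp <- tp + 1L
      else if (pred && y[i] == 0) fp <- fp + 1L
      else if (!pred && y[i] == 1) fn <- fn + 1L
      else tn <- tn + 1L
    }
    expect_identical(unlist(cc[c("tp", "fp", "fn", "tn")]),
                     c(tp = tp, fp = fp, fn = fn, tn = tn))
    expect_identical(tp + fp + fn + tn, 200L)
  }
})

test_that("statistics follow their contingency-table formulas", {
  perfect <- metrics(confusion(c(1, 0), c(0.9, 0.1)))
  expect_identical(perfect$accuracy, 1)
  expect_identical(perfect$f1, 1)

  m <- metrics(structure(list(tp = 3L, fp = 1L, fn = 2L, tn = 4L, threshold = 0.5),
                         class = "confusion_counts"))
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  expect_equal(m$f1, 2 / (1 / 0.6 + 1 / 0.75), tolerance = 1e-12)
  expect_equal(m$f1, 0.6667, tolerance = 1e-4)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$fpr, 1 - m$specificity, tolerance = 1e-12)
})

test_that("zero denominators surface as flagged NaN, never silent zero", {
  m <- metrics(structure(list(tp = 0L, fp = 0L, fn = 2L, tn = 4L, threshold = 0.5),
                         class = "confusion_counts"))
  expect_true(is.nan(m$precision))
  expect_true("precision" %in% m$undefined)
  expect_false("recall" %in% m$undefined)
  all_neg <- metrics(structure(list(tp = 0L, fp = 0L, fn = 0L, tn = 4L,
                                    threshold = 0.5), class = "confusion_counts"))
  expect_true(all(c("precision", "recall", "f1") %in% all_neg$undefined))
})

test_that("table identities hold on 1,000 random confusion tables", {
  set.seed(7)
  tabs <- random_confusion(1000)
  tabs <- tabs[rowSums(tabs) > 0, ]
  for (i in seq_len(nrow(tabs))) {
    r <- tabs[i, ]
    cc <- structure(list(tp = r$tp, fp = r$fp, fn = r$fn, tn = r$tn,
                         threshold = 0.5), class = "confusion_counts")
    m <- metrics(cc)
    expect_equal(m$accuracy, (r$tp + r$tn) / sum(r))
    if (r$tp + r$fn > 0) expect_equal(m$recall, r$tp / (r$tp + r$fn))
    if (r$tp + r$fp > 0) expect_equal(m$precision, r$tp / (r$tp + r$fp))
    if (r$tn + r$fp > 0) {
      expect_equal(m$specificity, r$tn / (r$tn + r$fp))
      expect_equal(m$fpr, 1 - m$specificity, tolerance = 1e-12)
    }
    if (!is.nan(m$precision) && !is.nan(m$recall) && m$precision + m$recall > 0)
      expect_equal(m$f1, 1 / ((1 / m$recall + 1 / m$precision) / 2),
                   tolerance = 1e-12)
  }
})

test_that("AUC endpoints: perfect separation gives 1, constant scores give 1/2", {
  expect_identical(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))$auc, 1)
  expect_identical(roc_auc(c(0, 1, 0, 1), rep(0.4, 4))$auc, 0.5)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.4)), "both classes")
})

test_that("trapezoidal AUC equals the exhaustive pairwise oracle", {
  set.seed(13)
  for (rep in 1:5) {
    y <- c(rep(1, 20), rep(0, 30))
    p <- round(runif(50), 2)   # coarse grid forces ties
    expect_equal(roc_auc(y, p)$auc, auc_pairwise_oracle(y, p),
                 tolerance = 1e-10)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(19)
  y <- sample(0:1, 80, replace = TRUE, prob = c(0.4, 0.6))
  p <- runif(80) + 0.3 * y
  ref <- as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE, direction = "<")))
  expect_equal(roc_auc(y, p)$auc, ref, tolerance = 1e-10)
})

test_that("label swap with score negation maps AUC to its complement", {
  set.seed(23)
  y <- sample(0:1, 60, replace = TRUE)
  p <- runif(60) + 0.4 * y
  a <- roc_auc(y, p)$auc
  b <- roc_auc(1 - y, -p)$auc
  expect_equal(a, b, tolerance = 1e-12)
  expect_equal(roc_auc(1 - y, p)$auc, 1 - a, tolerance = 1e-12)
})

test_that("best-threshold accuracy is at least the majority-class rate", {
  set.seed(29)
  for (rep in 1:10) {
    y <- sample(0:1, 50, replace = TRUE)
    if (length(unique(y)) < 2) next
    p <- runif(50)
    accs <- vapply(c(0, sort(unique(p))),
                   function(t) metrics(confusion(y, p, t))$accuracy, numeric(1))
    prev <- mean(y == 1)
    expect_gte(max(accs), max(prev, 1 - prev) - 1e-12)
  }
})

test_that("the ROC point list runs from (0,0) to (1,1) monotonically", {
  set.seed(37)
  y <- sample(0:1, 40, replace = TRUE)
  p <- runif(40)
  roc <- roc_auc(y, p)$roc
  expect_identical(c(roc$fpr[1], roc$tpr[1]), c(0, 0))
  expect_identical(c(roc$fpr[nrow(roc)], roc$tpr[nrow(roc)]), c(1, 1))
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))
})
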