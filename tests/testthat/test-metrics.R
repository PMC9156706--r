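test_that("accuracy matches hand-evaluated confusion counts", {
  expect_equal(accuracy(binary_confusion(tp = 10, tn = 10, fp = 0, fn = 0)), 1)
  expect_equal(accuracy(binary_confusion(1, 1, 1, 1)), 0.5)
  expect_equal(accuracy(binary_confusion(tp = 45, tn = 40, fp = 5, fn = 10)), 0.85)

  truth <- c("a", "a", "b", "c", "c")
  est <- c("a", "b", "b", "c", "a")
  expect_equal(accuracy(truth, est), 3 / 5)
  expect_error(binary_confusion(-1, 0, 0, 0), "nonnegative")
  expect_error(confusion_matrix(character(0), character(0)), "0 frames")
})

test_that("MAPE and MAE match their definitions and error on bad input", {
  expect_equal(mape(c(5, 7, 9), c(5, 7, 9)), 0)
  expect_equal(mape(100, 90), 10)
  expect_equal(mape(c(200, 400), c(220, 380)), 7.5)
  expect_equal(mae(c(3, 3), c(3, 3)), 0)
  expect_equal(mae(100, 90), 10)
  expect_equal(mae(c(200, 400), c(220, 380)), 20)
  expect_error(mape(c(100, 0), c(90, 10)), "undefined")
  expect_error(mape(c(100, 200), 90), "equal length")
})

test_that("MAPE is scale-free and MAE scales; both are permutation-invariant", {
  withr::with_seed(11, {
    for (i in 1:5) {
      y <- runif(30, 100, 2500)
      x <- y + rnorm(30, 0, 50)
      perm <- sample.int(30)
      expect_equal(mape(y[perm], x[perm]), mape(y, x))
      expect_equal(mae(y[perm], x[perm]), mae(y, x))
      c0 <- runif(1, 0.1, 10)
      expect_equal(mape(c0 * y, c0 * x), mape(y, x))
      expect_equal(mae(c0 * y, c0 * x), c0 * mae(y, x))
    }
  })
})

test_that("ROC AUC equals brute-force pairwise enumeration", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)
  expect_equal(roc_auc(c(0.9, 0.4, 0.6, 0.2), c(1, 0, 1, 0))$auc, 1)

  withr::with_seed(23, {
    for (i in 1:10) {
      n <- sample(10:200, 1)
      truth <- rbinom(n, 1, 0.5)
      if (length(unique(truth)) < 2) truth[1:2] <- c(0, 1)
      scores <- round(runif(n), 2)  # coarse grid to exercise ties
      r <- roc_auc(scores, truth)
      expect_equal(r$auc, auc_brute(scores, truth), tolerance = 1e-12)
      expect_true(all(c("threshold", "sensitivity", "specificity") %in%
                        names(r$roc)))
    }
  })
  expect_error(roc_auc(c(0.1, 0.9), c(1, 1)), "both classes")
})

test_that("fold aggregation is mean with sample-SD standard error", {
  a <- aggregate_mean_se(c(90, 94))
  expect_equal(a$mean, 92)
  expect_equal(a$se, 2)
  b <- aggregate_mean_se(rep(7, 5))
  expect_equal(b$mean, 7)
  expect_equal(b$se, 0)
  expect_false(b$se_degenerate)
  d <- aggregate_mean_se(1:4)
  expect_equal(d$mean, 2.5)
  expect_equal(d$se, sd(1:4) / 2)
  expect_equal(d$se, 0.6455, tolerance = 1e-4)
  single <- aggregate_mean_se(3.14)
  expect_equal(single$se, 0)
  expect_true(single$se_degenerate)
  expect_error(aggregate_mean_se(numeric(0)), "empty")
})
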