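test_that("centring uses the training mean only", {
  ctr <- center_images(list(matrix(100, 3, 3), matrix(100, 3, 3)))
  expect_true(all(ctr$train[[1]] == 0))
  expect_equal(ctr$train_mean, 100)

  ctr2 <- center_images(list(matrix(100, 3, 3)), list(matrix(120, 3, 3)))
  expect_true(all(ctr2$other[[1]] == 20))
  # the stored constant is provenance of the training set, not the other set
  expect_equal(ctr2$train_mean, 100)
  expect_error(center_images(list()), "nonempty")
})

test_that("a stage-3 classifier separates flavum from epidural space", {
  m <- tiny_stage3_model()
  expect_s3_class(m, "oct_cnn")
  expect_equal(m$classes, c("ligamentum_flavum", "epidural_space"))
  expect_gte(glance(m)$val_metric, 0.95)
  # probabilities are a simplex per frame
  d <- tiny_study()
  te <- d[d$subject_id == 3 & as.character(d$label) %in% m$classes, ]
  p <- predict(m, te)
  probs <- as.matrix(p[, paste0(".pred_", m$classes)])
  expect_equal(rowSums(probs), rep(1, nrow(probs)), tolerance = 1e-6)
  expect_true(all(probs >= 0))
})

test_that("predictions are independent of batching and geometry-checked", {
  m <- tiny_stage3_model()
  d <- tiny_study()
  te <- d[d$subject_id == 3 & as.character(d$label) %in% m$classes, ][1:5, ]
  batched <- predict(m, te)
  single <- dplyr::bind_rows(lapply(te$frame, function(f) predict(m, f)))
  expect_equal(batched, single, tolerance = 1e-10)
  wrong <- simulate_frame("epidural_space", geometry = "regress",
                          distance_um = 500)
  expect_error(predict(m, wrong), "geometry mismatch")
})

test_that("training is deterministic under a fixed seed", {
  d <- tiny_study()
  cfg <- training_config(max_epochs = 3L, patience = 2L)
  m1 <- train_classifier(d, "stage4", config = cfg,
                         train_subjects = 1:2, val_subjects = 3, seed = 12)
  m2 <- train_classifier(d, "stage4", config = cfg,
                         train_subjects = 1:2, val_subjects = 3, seed = 12)
  expect_identical(tidy(m1), tidy(m2))
  expect_identical(m1$net, m2$net)
})

test_that("shuffled labels give chance-level validation accuracy", {
  d <- tiny_study()
  d2 <- d[as.character(d$label) %in%
            c("ligamentum_flavum", "epidural_space"), ]
  withr::with_seed(5, {
    d2$label <- sample(d2$label)
    d2$distance_um <- NA_real_  # labels no longer meaningful
  })
  # distance rule ties distances to the label column; drop to plain frames
  d2$frame <- lapply(d2$frame, function(f) .subset2(f, "pixels"))
  m <- train_classifier(d2, "stage3",
                        config = training_config(max_epochs = 6L, patience = 3L),
                        train_subjects = 1:2, val_subjects = 3, seed = 31)
  n_val <- sum(d2$subject_id == 3)
  acc <- glance(m)$val_metric
  expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / n_val) + 1e-9)
})

test_that("label and subject preconditions are enforced", {
  d <- tiny_study()
  expect_error(
    train_classifier(d, "stage3", train_subjects = 1:2, val_subjects = 2),
    "leakage")
  one_class <- d[as.character(d$label) == "fat", ]
  expect_error(
    train_classifier(one_class, "stage1",
                     train_subjects = 1:2, val_subjects = 3),
    "every class")
  no_epi <- d[as.character(d$label) == "fat", ]
  expect_error(
    train_regressor(no_epi, train_subjects = 1:2, val_subjects = 3),
    "no epidural-space frames")
  expect_error(train_classifier(d, "stage9", train_subjects = 1:2,
                                val_subjects = 3),
               "task")
})

test_that("degenerate equal-distance training is fitted almost exactly", {
  d <- simulate_study(n_subjects = 2, frames_per_layer = 80, task = "regress",
                      distance_range_um = c(1000, 1000),
                      layers = "epidural_space", seed = 55)
  m <- train_regressor(d, architecture = "small-cnn",
                       train_subjects = 1, val_subjects = 2, seed = 3)
  p <- predict(m, d[d$subject_id == 2, ])$.pred_distance_um
  expect_lte(mape(d$distance_um[d$subject_id == 2], p), 1)
})

test_that("the surface detector inverts the generator within one pixel", {
  withr::with_seed(77, {
    dists <- runif(100, 200, 2500)
    errs <- vapply(dists, function(d0) {
      fr <- simulate_frame("epidural_space", geometry = "regress",
                           distance_um = d0)
      abs(detect_surface_distance(fr) - d0)
    }, numeric(1))
    expect_gte(mean(errs <= 6.25), 0.99)
  })
})

test_that("detected distance increases with the simulated gap", {
  app <- default_appearances()
  app$speckle_variance <- 0
  app$heterogeneity_scale <- 0
  withr::with_seed(3, {
    dists <- seq(200, 2400, by = 200)
    det <- vapply(dists, function(d0) {
      detect_surface_distance(
        simulate_frame("epidural_space", app, "regress", distance_um = d0))
    }, numeric(1))
    expect_true(all(diff(det) > 0))
  })
})

test_that("a frame with no tissue yields a 'no surface' error", {
  withr::with_seed(4, {
    noise <- matrix(as.integer(pmax(pmin(rnorm(241 * 181, 18, 5), 255), 0)),
                    241, 181)
    expect_error(detect_surface_distance(noise), "no surface")
  })
})
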