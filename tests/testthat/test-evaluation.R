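test_that("nested folds partition subjects with zero leakage", {
  plans <- make_nested_folds(1:8)
  expect_equal(nrow(plans), 56)  # 8 outer x 7 inner rotations
  expect_equal(sort(unique(plans$test_subject)), 1:8)
  for (f in 1:8) {
    p <- plans[plans$outer_fold == f, ]
    expect_equal(nrow(p), 7)
    # each CV subject validates exactly once
    expect_setequal(p$val_subject, setdiff(1:8, p$test_subject[1]))
    for (r in seq_len(nrow(p))) {
      tr <- p$train_subjects[[r]]
      expect_length(tr, 6)
      expect_setequal(c(tr, p$val_subject[r], p$test_subject[r]), 1:8)
      expect_equal(anyDuplicated(c(tr, p$val_subject[r], p$test_subject[r])), 0)
    }
  }
  small <- make_nested_folds(c("a", "b", "c"))
  expect_equal(nrow(small), 6)  # 3 outer x 2 inner
  expect_error(make_nested_folds(c(1, 1, 2)), "distinct")
  expect_error(make_nested_folds(1:2), "at least 3")
})

test_that("architecture selection uses the mean inner metric with stable ties", {
  expect_equal(
    select_best_architecture(list(A = c(0.90, 0.92), B = c(0.95, 0.93))), "B")
  expect_equal(
    select_best_architecture(list(A = 3.7, B = 3.2, C = 4.1), "minimize"), "B")
  expect_message(
    tie <- select_best_architecture(list(X = c(1, 2), Y = c(2, 1))), "tie")
  expect_equal(tie, "X")
  expect_error(select_best_architecture(list()), "no architectures")
  expect_error(select_best_architecture(list(A = 1:2, B = 1:3)),
               "same number")
  # tibble input as produced by the nested loop
  tb <- tibble::tibble(architecture = rep(c("m1", "m2"), each = 2),
                       metric = c(0.8, 0.9, 0.7, 0.75))
  expect_equal(select_best_architecture(tb), "m1")
})

test_that("the sequential report mirrors the folds-by-stages layout", {
  withr::with_seed(2, {
    res <- tidyr::expand_grid(fold = paste0("S", 1:8),
                              stage = paste0("stage", 1:4))
    res$value <- round(runif(32, 90, 100), 1)
  })
  rep_ <- build_sequential_report(res)
  expect_equal(nrow(rep_), 10)  # 8 folds + Average + SE rows
  expect_equal(names(rep_), c("fold", paste0("stage", 1:4), "average", "se"))
  r1 <- res$value[res$fold == "S1"]
  expect_equal(rep_$average[1], mean(r1))
  expect_equal(rep_$se[1], sd(r1) / 2)
  avg <- rep_[rep_$fold == "Average", ]
  expect_equal(avg$stage2, mean(res$value[res$stage == "stage2"]))

  gap <- res[-1, ]
  expect_warning(rep2 <- build_sequential_report(gap), "gap")
  expect_true(is.na(rep2$stage1[rep2$fold == "S1"]))

  single <- build_sequential_report(res[res$fold == "S1", ])
  expect_equal(single$se[nrow(single) - 1], 0)
})

test_that("the nested protocol selects, retrains and tests without leakage", {
  d <- fixture("nested_study", function() {
    simulate_study(n_subjects = 3, frames_per_layer = 60, seed = 202)
  })
  cfg <- training_config(max_epochs = 25L, patience = 10L)
  res <- run_nested_evaluation(d, "stage3",
                               architectures = c("small-cnn", "xception-like"),
                               config = cfg, seed = 5)
  # bookkeeping: 3 outer folds x 2 architectures x 2 rotations
  expect_equal(nrow(res$inner), 12)
  expect_equal(nrow(res$selection), 3)
  expect_equal(nrow(res$test), 3)
  expect_setequal(res$test$test_subject, 1:3)
  # no inner run ever sees its outer test subject
  for (i in seq_len(nrow(res$inner))) {
    expect_false(res$inner$test_subject[i] == res$inner$val_subject[i])
  }
  # selection is reproducible from the stored inner table
  for (f in 1:3) {
    inn <- res$inner[res$inner$outer_fold == f, c("architecture", "metric")]
    expect_equal(select_best_architecture(inn, "maximize"),
                 res$selection$architecture[res$selection$outer_fold == f])
  }
  # aggregate is recomputable from the per-fold outputs
  expect_equal(res$summary, aggregate_mean_se(res$test$metric))
  expect_equal(glance(res)$mean, mean(res$test$metric))
  # the near-separable stage-3 task is solved on every held-out subject
  expect_true(all(res$test$metric >= 0.95))
  # a single candidate is selected trivially
  res1 <- run_nested_evaluation(d[d$subject_id %in% 1:3, ], "stage3",
                                architectures = "small-cnn",
                                config = training_config(max_epochs = 2L,
                                                         patience = 2L),
                                seed = 6)
  expect_true(all(res1$selection$architecture == "small-cnn"))
})
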