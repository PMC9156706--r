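#' Subject-grouped nested fold plans
#'
#' Builds the nested cross-validation/cross-testing partition: an outer
#' loop rotates every subject through the test role; within each outer
#' fold, an inner loop rotates every remaining (cross-validation) subject
#' through the validation role, the others training. With 8 subjects this
#' yields 8 outer folds x 7 inner rotations = 56 train/validation/test
#' triples; each subject tests exactly once and, within an outer fold,
#' validates exactly once.
#'
#' @param subject_ids Vector of at least 3 distinct subject identifiers.
#' @return A tibble with columns `outer_fold`, `test_subject`, `rotation`,
#'   `val_subject` and list-column `train_subjects`.
#' @export
#' @examples
#' nrow(make_nested_folds(1:8))  # 56
make_nested_folds <- function(subject_ids) {
  if (anyDuplicated(subject_ids)) abort("subject IDs must be distinct")
  n <- length(subject_ids)
  if (n < 3) abort("need at least 3 subjects for nested folds")
  plans <- purrr::map(seq_len(n), function(f) {
    test <- subject_ids[f]
    cv <- subject_ids[subject_ids != test]
    tibble(
      outer_fold = f,
      test_subject = test,
      rotation = seq_len(n - 1L),
      val_subject = cv,
      train_subjects = purrr::map(cv, function(v) cv[cv != v])
    )
  })
  dplyr::bind_rows(plans)
}

#' Select the architecture with the best mean inner-fold metric
#'
#' The selection statistic is the mean of the inner-fold validation metrics
#' per architecture; exact ties are broken by input order (and reported via
#' a message).
#'
#' @param inner_metrics Named list of per-fold metric vectors (one element
#'   per architecture, equal lengths), or a tibble with columns
#'   `architecture` and `metric`.
#' @param direction `"maximize"` (accuracy) or `"minimize"` (MAPE).
#' @return The selected architecture name.
#' @export
#' @examples
#' select_best_architecture(list(A = c(0.90, 0.92), B = c(0.95, 0.93)))
select_best_architecture <- function(inner_metrics,
                                     direction = c("maximize", "minimize")) {
  direction <- match.arg(direction)
  if (is.data.frame(inner_metrics)) {
    inner_metrics <- split(inner_metrics$metric,
                           factor(inner_metrics$architecture,
                                  levels = unique(inner_metrics$architecture)))
  }
  if (length(inner_metrics) == 0) abort("no architectures to select from")
  lens <- lengths(inner_metrics)
  if (length(unique(lens)) != 1) {
    abort("all architectures must have the same number of inner folds")
  }
  means <- vapply(inner_metrics, mean, numeric(1))
  score <- if (direction == "maximize") means else -means
  best <- which(score == max(score))
  if (length(best) > 1) {
    message("architecture selection tie; keeping first in input order: ",
            names(means)[best[1]])
  }
  names(means)[best[1]]
}

# per-run reproducible seed, spread across fold/architecture/rotation
.run_seed <- function(base, fold, arch_idx, rotation) {
  as.integer((base + 9973 * fold + 733 * arch_idx + 101 * rotation) %% .Machine$integer.max)
}

#' Run the nested cross-validation / cross-testing protocol
#'
#' For every outer fold (test subject held out entirely), trains each
#' candidate architecture on all inner rotations (6 training subjects, 1
#' validation subject with the 8-subject default), selects the architecture
#' with the best mean inner validation metric (accuracy for
#' classification, MAPE for regression), retrains it on all cross-validation
#' subjects, and evaluates once on the unseen test subject. Test metrics
#' are aggregated as mean and standard error across outer folds. A
#' subject-disjointness audit guards every training run; any leakage
#' aborts.
#'
#' Classification retraining runs a fixed epoch budget equal to the rounded
#' mean best epoch of the selected architecture's inner runs (there is no
#' validation subject left to stop on); regression retraining uses the
#' standard fixed 20 epochs.
#'
#' @param data Dataset tibble covering every subject.
#' @param task `"stage1"`..`"stage4"`, `"multiclass"` or `"regress"`.
#' @param architectures Character vector of candidate architectures.
#' @param config A [training_config()].
#' @param seed Base seed; each training run derives its own seed from
#'   (fold, architecture, rotation).
#' @return A `nested_result` object with tibbles `inner`, `selection`,
#'   `test` and the aggregate `summary`; see [tidy.nested_result()].
#' @export
run_nested_evaluation <- function(data, task, architectures = "small-cnn",
                                  config = training_config(), seed = 1L) {
  subjects <- sort(unique(data$subject_id))
  folds <- make_nested_folds(subjects)
  is_reg <- identical(task, "regress")
  direction <- if (is_reg) "minimize" else "maximize"
  metric_name <- if (is_reg) "mape" else "accuracy"

  train_one <- function(train_s, val_s, arch, run_seed, epochs = NULL) {
    .assert_no_leakage(train_s, val_s)
    if (is_reg) {
      train_regressor(data, architecture = arch, config = config,
                      train_subjects = train_s, val_subjects = val_s,
                      seed = run_seed)
    } else {
      train_classifier(data, task, architecture = arch, config = config,
                       train_subjects = train_s, val_subjects = val_s,
                       epochs = epochs, seed = run_seed)
    }
  }

  eval_model <- function(model, eval_subjects) {
    rows <- data[data$subject_id %in% eval_subjects, , drop = FALSE]
    if (!is_reg && !identical(task, "multiclass")) {
      sp <- .stage_spec(task)
      rows <- rows[as.character(rows$label) %in%
                     c(as.character(sp$class0), as.character(sp$class1)), ,
                   drop = FALSE]
    }
    if (is_reg) {
      rows <- rows[as.character(rows$label) == "epidural_space", , drop = FALSE]
      pred <- predict(model, rows)$.pred_distance_um
      c(metric = mape(rows$distance_um, pred),
        mae = mae(rows$distance_um, pred))
    } else {
      pred <- predict(model, rows)$.pred_class
      c(metric = accuracy(confusion_matrix(
          factor(as.character(rows$label), levels = model$classes),
          pred)),
        mae = NA_real_)
    }
  }

  inner <- list()
  selection <- list()
  test <- list()
  for (f in unique(folds$outer_fold)) {
    plan <- folds[folds$outer_fold == f, ]
    test_subject <- plan$test_subject[1]
    cv_subjects <- subjects[subjects != test_subject]

    for (a in seq_along(architectures)) {
      arch <- architectures[a]
      for (r in plan$rotation) {
        row <- plan[plan$rotation == r, ]
        train_s <- row$train_subjects[[1]]
        val_s <- row$val_subject
        if (test_subject %in% c(train_s, val_s)) {
          abort("leakage: test subject found in a cross-validation split")
        }
        rs <- .run_seed(seed, f, a, r)
        m <- train_one(train_s, val_s, arch, rs)
        g <- glance(m)
        inner[[length(inner) + 1L]] <- tibble(
          outer_fold = f, test_subject = test_subject, architecture = arch,
          rotation = r, val_subject = val_s,
          metric = g$val_metric, best_epoch = g$best_epoch, seed = rs)
      }
    }

    inner_f <- dplyr::bind_rows(inner)
    inner_f <- inner_f[inner_f$outer_fold == f, ]
    chosen <- select_best_architecture(
      inner_f[, c("architecture", "metric")], direction)
    selection[[length(selection) + 1L]] <- tibble(
      outer_fold = f, architecture = chosen,
      mean_metric = mean(inner_f$metric[inner_f$architecture == chosen]))

    retrain_epochs <- if (is_reg) NULL else {
      max(1L, as.integer(round(mean(
        inner_f$best_epoch[inner_f$architecture == chosen]))))
    }
    rs <- .run_seed(seed, f, match(chosen, architectures), 0L)
    final <- train_one(cv_subjects, NULL, chosen, rs, epochs = retrain_epochs)
    ev <- eval_model(final, test_subject)
    test[[length(test) + 1L]] <- tibble(
      outer_fold = f, test_subject = test_subject, architecture = chosen,
      metric = ev[["metric"]], mae = ev[["mae"]])
  }

  inner <- dplyr::bind_rows(inner)
  selection <- dplyr::bind_rows(selection)
  test <- dplyr::bind_rows(test)
  structure(
    list(task = task, metric_name = metric_name, direction = direction,
         inner = inner, selection = selection, test = test,
         summary = aggregate_mean_se(test$metric)),
    class = "nested_result"
  )
}

#' @export
print.nested_result <- function(x, ...) {
  cat(sprintf("<nested_result> task %s, %d outer folds, metric %s\n",
              x$task, nrow(x$test), x$metric_name))
  cat(sprintf("  test %s: %.4g +/- %.4g (mean +/- SE)\n",
              x$metric_name, x$summary$mean, x$summary$se))
  invisible(x)
}

#' Tidy and summarise nested evaluation results
#'
#' `tidy()` returns the per-outer-fold test table (selected architecture
#' and test metric); `glance()` the aggregate mean and standard error.
#'
#' @param x A `nested_result`.
#' @param ... Unused.
#' @name tidy-nested_result
#' @method tidy nested_result
#' @export
tidy.nested_result <- function(x, ...) x$test

#' @rdname tidy-nested_result
#' @method glance nested_result
#' @export
glance.nested_result <- function(x, ...) {
  dplyr::bind_cols(tibble(task = x$task, metric = x$metric_name), x$summary)
}

#' Assemble the sequential-cascade report table
#'
#' Cross-testing results for the four stage tasks laid out as testing folds
#' in rows and stage tasks in columns, with a per-fold mean and standard
#' error and a final marginal row. Missing cells are reported as `NA` (an
#' explicit gap, with a warning), never dropped.
#'
#' @param stage_results Tibble with columns `fold` (testing-fold label),
#'   `stage` (task label) and `value` (the metric, e.g. accuracy).
#' @return A wide tibble: one row per fold plus an `"Average"` row; one
#'   column per stage plus `average` and `se` columns.
#' @export
build_sequential_report <- function(stage_results) {
  stopifnot(all(c("fold", "stage", "value") %in% names(stage_results)))
  wide <- tidyr::pivot_wider(stage_results, id_cols = "fold",
                             names_from = "stage", values_from = "value")
  stage_cols <- setdiff(names(wide), "fold")
  if (anyNA(wide[stage_cols])) {
    warn("missing fold x stage cells; reported as NA gap markers")
  }
  vals <- as.matrix(wide[stage_cols])
  row_n <- rowSums(!is.na(vals))
  row_mean <- rowMeans(vals, na.rm = TRUE)
  row_se <- apply(vals, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) <= 1) 0 else sd(v) / sqrt(length(v))
  })
  out <- dplyr::bind_cols(wide, tibble(average = row_mean, se = row_se))
  col_stat <- function(f0) purrr::map_dbl(stage_cols, function(s) {
    v <- vals[, s]
    f0(v[!is.na(v)])
  })
  col_se <- function(v) if (length(v) <= 1) 0 else sd(v) / sqrt(length(v))
  avg_row <- tibble(fold = "Average")
  se_row <- tibble(fold = "SE")
  means <- col_stat(mean)
  ses <- col_stat(col_se)
  for (i in seq_along(stage_cols)) {
    avg_row[[stage_cols[i]]] <- means[i]
    se_row[[stage_cols[i]]] <- ses[i]
  }
  avg_row$average <- mean(row_mean)
  avg_row$se <- col_se(row_mean)
  se_row$average <- NA_real_
  se_row$se <- NA_real_
  out$fold <- as.character(out$fold)
  dplyr::bind_rows(out, avg_row, se_row)
}
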