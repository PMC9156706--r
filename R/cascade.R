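#' Traffic-light zone for a sliding-window class-1 count
#'
#' GREEN while the class-1 count is below `yellow` (26), YELLOW from
#' `yellow` up to but excluding `red` (35), RED at `red` and above.
#'
#' @param count Class-1 prediction count(s) in the window.
#' @param yellow,red Zone thresholds.
#' @return Character vector of `"GREEN"`, `"YELLOW"`, `"RED"`.
#' @export
#' @examples
#' cascade_zone(c(0, 25, 26, 34, 35, 50))
cascade_zone <- function(count, yellow = 26L, red = 35L) {
  ifelse(count >= red, "RED", ifelse(count >= yellow, "YELLOW", "GREEN"))
}

#' Initialise the sequential cascade state
#'
#' The cascade starts at stage 1 (fat vs interspinous ligament) with an
#' empty sliding window. Each stage buffers its most recent `window_size`
#' (50) binary predictions; while fewer frames have been seen in the stage,
#' the displayed denominator is that count. When the class-1 count reaches
#' `red` (35) the needle is considered to have entered the deeper layer:
#' the next classifier is activated and (by default) the window is cleared.
#' Stage 4 never switches and displays no fraction or zone.
#'
#' @param window_size Sliding-window length (frames).
#' @param yellow,red Zone/switch thresholds on the class-1 count.
#' @param reset_on_switch Clear the window when a switch fires; the new
#'   classifier's predictions are not commensurable with the old window.
#' @return A `cascade_state` object.
#' @export
#' @examples
#' st <- init_cascade()
#' st <- cascade_update(st, 1L)
#' st$fraction  # 1/1
init_cascade <- function(window_size = 50L, yellow = 26L, red = 35L,
                         reset_on_switch = TRUE) {
  structure(
    list(stage = 1L, buf = integer(window_size), wpos = 1L, len = 0L,
         class1_count = 0L, denominator = 0L, fraction = NA_real_,
         zone = "GREEN", frames_processed = 0L, frames_in_stage = 0L,
         switch_log = tibble(stage = integer(0), frame = integer(0)),
         closed = FALSE,
         config = list(window_size = as.integer(window_size),
                       yellow = as.integer(yellow), red = as.integer(red),
                       reset_on_switch = reset_on_switch)),
    class = "cascade_state"
  )
}

#' Close a cascade stream
#'
#' A closed state rejects further updates.
#'
#' @param state A `cascade_state`.
#' @return The closed state.
#' @export
close_cascade <- function(state) {
  if (!inherits(state, "cascade_state")) abort("state must be a cascade_state")
  state$closed <- TRUE
  state
}

#' The sliding window of a cascade state, oldest first
#'
#' @param state A `cascade_state`.
#' @return Integer vector of at most `window_size` recent predictions.
#' @export
cascade_window <- function(state) {
  W <- state$config$window_size
  if (state$len < W) return(state$buf[seq_len(state$len)])
  state$buf[((state$wpos - 1L + 0:(W - 1L)) %% W) + 1L]
}

#' Advance the cascade by one binary prediction
#'
#' Appends the active stage's prediction to the window (evicting the oldest
#' at capacity), recomputes the class-1 count and zone, and switches to the
#' next stage when the count reaches the red threshold (allowed even before
#' the window is full: reaching 35 of fewer than 50 is stricter). At stage 4
#' the frame is counted but no window, fraction or zone is maintained.
#'
#' @param state A `cascade_state`.
#' @param prediction 0 or 1, the active stage classifier's output.
#' @return The updated `cascade_state`.
#' @export
cascade_update <- function(state, prediction) {
  if (!inherits(state, "cascade_state")) abort("state must be a cascade_state")
  if (state$closed) abort("cascade stream is closed; no further updates")
  if (!prediction %in% c(0L, 1L)) abort("prediction must be 0 or 1")
  prediction <- as.integer(prediction)
  cfg <- state$config
  state$frames_processed <- state$frames_processed + 1L

  if (state$stage == 4L) {
    state$denominator <- NA_integer_
    state$fraction <- NA_real_
    state$zone <- NA_character_
    return(state)
  }

  W <- cfg$window_size
  if (state$len == W) {
    state$class1_count <- state$class1_count - state$buf[state$wpos]
  } else {
    state$len <- state$len + 1L
  }
  state$buf[state$wpos] <- prediction
  state$class1_count <- state$class1_count + prediction
  state$wpos <- (state$wpos %% W) + 1L
  state$frames_in_stage <- state$frames_in_stage + 1L
  state$denominator <- state$len
  state$fraction <- state$class1_count / state$len
  state$zone <- cascade_zone(state$class1_count, cfg$yellow, cfg$red)

  if (state$class1_count >= cfg$red) {
    state$switch_log <- dplyr::bind_rows(
      state$switch_log,
      tibble(stage = state$stage, frame = state$frames_processed))
    state$stage <- state$stage + 1L
    state$frames_in_stage <- 0L
    if (cfg$reset_on_switch) {
      state$buf <- integer(W)
      state$wpos <- 1L
      state$len <- 0L
      state$class1_count <- 0L
    }
  }
  state
}

#' @export
print.cascade_state <- function(x, ...) {
  frac <- if (is.na(x$fraction)) "-" else {
    sprintf("%d/%d (%s)", x$class1_count, x$denominator, x$zone)
  }
  cat(sprintf("<cascade_state> stage %d, frame %d, fraction %s, %d switch(es)\n",
              x$stage, x$frames_processed, frac, nrow(x$switch_log)))
  invisible(x)
}

# fast ring-buffer core shared by run_stream and run_prediction_stream;
# preds: list of 4 integer vectors (per-stage predictions for every frame)
.stream_core <- function(preds, config) {
  n <- length(preds[[1]])
  W <- config$window_size
  red <- config$red
  yellow <- config$yellow
  reset <- config$reset_on_switch

  stage_v <- integer(n)
  pred_v <- integer(n)
  count_v <- rep(NA_integer_, n)
  denom_v <- rep(NA_integer_, n)
  zone_v <- rep(NA_character_, n)
  sw_stage <- integer(0)
  sw_frame <- integer(0)

  stage <- 1L
  buf <- integer(W)
  wpos <- 1L
  len <- 0L
  count <- 0L
  for (t in seq_len(n)) {
    p <- preds[[stage]][t]
    stage_v[t] <- stage
    pred_v[t] <- p
    if (stage < 4L) {
      if (len == W) count <- count - buf[wpos] else len <- len + 1L
      buf[wpos] <- p
      count <- count + p
      wpos <- (wpos %% W) + 1L
      count_v[t] <- count
      denom_v[t] <- len
      zone_v[t] <- if (count >= red) "RED" else if (count >= yellow) "YELLOW" else "GREEN"
      if (count >= red) {
        sw_stage <- c(sw_stage, stage)
        sw_frame <- c(sw_frame, t)
        stage <- stage + 1L
        if (reset) {
          buf <- integer(W)
          wpos <- 1L
          len <- 0L
          count <- 0L
        }
      }
    }
  }
  list(stage = stage_v, prediction = pred_v, class1_count = count_v,
       denominator = denom_v, zone = zone_v,
       switches = tibble(stage = sw_stage, frame = sw_frame))
}

#' Run the cascade over a raw binary prediction stream
#'
#' Applies the sliding-window switching rule to a single stream of binary
#' predictions, each consumed by whichever stage is active when it arrives.
#' Useful for analysing the switching logic independently of any frames.
#'
#' @param predictions Integer vector of 0/1 predictions.
#' @param state A fresh [init_cascade()] state carrying the configuration.
#' @return A `cascade_run` object; see [run_stream()].
#' @export
#' @examples
#' r <- run_prediction_stream(c(rep(0, 100), rep(1, 100)))
#' r$switches  # first switch at frame 135
run_prediction_stream <- function(predictions, state = init_cascade()) {
  if (!all(predictions %in% c(0L, 1L))) abort("predictions must be 0/1")
  preds <- as.integer(predictions)
  core <- .stream_core(rep(list(preds), 4L), state$config)
  ann <- tibble(t = seq_along(preds), stage = core$stage,
                prediction = core$prediction,
                class1_count = core$class1_count,
                denominator = core$denominator,
                fraction = core$class1_count / core$denominator,
                zone = core$zone)
  structure(list(annotations = ann, switches = core$switches,
                 config = state$config),
            class = "cascade_run")
}

#' Run the sequential cascade over an insertion image stream
#'
#' Each frame is classified by the active stage's predictor only; the
#' sliding-window rule (see [init_cascade()]) switches stages. Annotations
#' carry the displayed fraction and traffic-light zone (absent once stage 4
#' is active), the active classifier, and the truth and predicted labels.
#'
#' @param frames An insertion-sequence tibble from
#'   [simulate_insertion_sequence()] (columns `label`, `frame`).
#' @param predictors `"oracle"` (predict from the truth labels), a list of
#'   four trained stage models (`oct_cnn`), or a function
#'   `f(stage, frames)` returning 0/1 predictions.
#' @param state A fresh [init_cascade()] state.
#' @return A `cascade_run` with `annotations` (tibble, one row per frame),
#'   `switches` (tibble of stage/frame switch events) and `accuracy`
#'   (end-to-end labelling accuracy of the displayed label vs truth).
#' @export
run_stream <- function(frames, predictors = "oracle", state = init_cascade()) {
  truth <- as_tissue_label(frames$label)
  n <- length(truth)
  stg <- cascade_stages()

  preds <- vector("list", 4L)
  if (identical(predictors, "oracle")) {
    code <- as.integer(truth)
    for (k in 1:4) preds[[k]] <- as.integer(code >= k + 1L)
  } else if (is.function(predictors)) {
    for (k in 1:4) preds[[k]] <- as.integer(predictors(k, frames))
  } else {
    if (!is.list(predictors) || length(predictors) != 4L ||
        !all(vapply(predictors, inherits, logical(1), "oct_cnn"))) {
      abort("predictors must be 'oracle', a function, or a list of 4 oct_cnn stage models")
    }
    for (k in 1:4) {
      cls <- predict(predictors[[k]], frames)$.pred_class
      preds[[k]] <- as.integer(cls == predictors[[k]]$classes[2])
    }
  }

  core <- .stream_core(preds, state$config)
  lv <- tissue_labels()
  pred_label <- factor(
    ifelse(core$prediction == 1L, lv[core$stage + 1L], lv[core$stage]),
    levels = lv)
  ann <- tibble(
    t = seq_len(n), stage = core$stage,
    classifier = paste0(as.character(stg$class0[core$stage]), "_vs_",
                        as.character(stg$class1[core$stage])),
    truth = truth, prediction = core$prediction, pred_label = pred_label,
    class1_count = core$class1_count, denominator = core$denominator,
    fraction = core$class1_count / core$denominator, zone = core$zone)
  structure(list(annotations = ann, switches = core$switches,
                 accuracy = mean(pred_label == truth),
                 config = state$config),
            class = "cascade_run")
}

#' @export
print.cascade_run <- function(x, ...) {
  cat(sprintf("<cascade_run> %d frames, %d switch(es)",
              nrow(x$annotations), nrow(x$switches)))
  if (nrow(x$switches) > 0) {
    cat(" at frame(s) ", paste(x$switches$frame, collapse = ", "), sep = "")
  }
  if (!is.null(x$accuracy)) cat(sprintf("; stream accuracy %.3f", x$accuracy))
  cat("\n")
  invisible(x)
}

#' @describeIn run_stream Per-frame annotations of a cascade run.
#' @method tidy cascade_run
#' @export
tidy.cascade_run <- function(x, ...) x$annotations

#' @describeIn run_stream One-row summary of a cascade run.
#' @method glance cascade_run
#' @export
glance.cascade_run <- function(x, ...) {
  tibble(n_frames = nrow(x$annotations), n_switches = nrow(x$switches),
         final_stage = max(x$annotations$stage),
         accuracy = if (is.null(x$accuracy)) NA_real_ else x$accuracy)
}
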