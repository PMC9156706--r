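# shared fixtures, built once per test run and cached
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# free a heavy fixture once every consumer has run
drop_fixture <- function(name) {
  if (!is.null(.fixtures[[name]])) {
    rm(list = name, envir = .fixtures)
    invisible(gc(verbose = FALSE))
  }
}

# a small multi-subject classification study
tiny_study <- function() {
  fixture("tiny_study", function() {
    simulate_study(n_subjects = 3, frames_per_layer = 12, seed = 101)
  })
}

# a quick, deterministic stage-3 classifier for prediction/explanation tests
tiny_stage3_model <- function() {
  fixture("tiny_stage3_model", function() {
    train_classifier(tiny_study(), "stage3",
                     config = training_config(max_epochs = 15L, patience = 8L),
                     train_subjects = 1:2, val_subjects = 3, seed = 7)
  })
}

# brute-force AUC: fraction of positive-negative pairs ranked correctly,
# ties counted one half
auc_brute <- function(scores, truth) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# naive reference for the cascade switch rule: recount the last 50
# predictions of the active stage at every frame
naive_switch_frames <- function(preds, window = 50L, red = 35L, reset = TRUE) {
  n <- length(preds)
  switches <- integer(0)
  stage <- 1L
  hist <- integer(n)
  hlen <- 0L
  for (t in seq_len(n)) {
    if (stage == 4L) break
    hlen <- hlen + 1L
    hist[hlen] <- preds[t]
    from <- max(1L, hlen - window + 1L)
    if (sum(hist[from:hlen]) >= red) {
      switches <- c(switches, t)
      stage <- stage + 1L
      if (reset) hlen <- 0L
    }
  }
  switches
}

# per-frame appearance features used by signature-separation checks:
# surface depth/brightness from the smoothed lateral-mean profile, an
# e-folding attenuation length fitted below the surface, and the lateral
# coefficient of variation of the tissue band
frame_features <- function(fr) {
  r <- rowMeans(fr$pixels)
  bg <- as.numeric(quantile(r, 0.05))
  thr <- bg + 0.4 * (max(r) - bg)
  z0 <- which(r >= thr)[1]
  span <- z0:min(z0 + 80L, length(r))
  y <- pmax(r[span] - bg, 1)
  fit <- stats::lm(log(y) ~ seq_along(span))
  atten <- -1 / coef(fit)[2]
  band <- fr$pixels[z0:min(z0 + 30L, nrow(fr$pixels)), , drop = FALSE]
  cmeans <- colMeans(band)
  c(surface_row = z0, brightness = max(r), attenuation = unname(atten),
    lateral_cv = sd(cmeans) / mean(cmeans))
}
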