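#' Training configuration
#'
#' Optimisation constants for all learned models: stochastic gradient
#' descent with Nesterov momentum, learning rate 0.01, momentum 0.9, decay
#' 0.01 (applied as a per-epoch schedule `lr / (1 + decay * epoch)`), batch
#' size 32. Classification uses sparse categorical cross-entropy with early
#' stopping at patience 10 (epoch cap 100); regression trains for a fixed 20
#' epochs with the mean absolute percentage error as the objective. Any
#' value can be overridden explicitly.
#'
#' @param learning_rate,momentum,decay,batch_size Optimiser constants.
#' @param patience Early-stopping patience (classification), in epochs
#'   without validation-loss improvement of at least `min_delta`.
#' @param min_delta Minimum validation-loss decrease that counts as an
#'   improvement for the patience counter (the best-epoch weights are
#'   tracked regardless).
#' @param max_epochs Epoch cap for classification.
#' @param epochs_regression Fixed epoch count for regression.
#' @return A `training_config` list.
#' @export
#' @examples
#' training_config()
training_config <- function(learning_rate = 0.01, momentum = 0.9,
                            decay = 0.01, batch_size = 32L,
                            patience = 10L, min_delta = 1e-4,
                            max_epochs = 100L,
                            epochs_regression = 20L) {
  structure(
    list(learning_rate = learning_rate, momentum = momentum, decay = decay,
         batch_size = as.integer(batch_size), patience = as.integer(patience),
         min_delta = min_delta, max_epochs = as.integer(max_epochs),
         epochs_regression = as.integer(epochs_regression)),
    class = "training_config"
  )
}

#' @export
print.training_config <- function(x, ...) {
  cat("<training_config> SGD + Nesterov momentum\n")
  cat(sprintf("  lr %.3g, momentum %.3g, decay %.3g, batch %d\n",
              x$learning_rate, x$momentum, x$decay, x$batch_size))
  cat(sprintf("  classification: patience %d, cap %d epochs; regression: %d epochs\n",
              x$patience, x$max_epochs, x$epochs_regression))
  invisible(x)
}

# compact conv-block variants; the suffixed names denote width/depth
# variants of the same family, not full-size reimplementations
.arch_filters <- list(
  "small-cnn"      = c(8L, 16L),
  "resnet50-like"  = c(12L, 24L),
  "inception-like" = c(12L, 24L, 48L),
  "xception-like"  = c(6L, 12L)
)

#' Available classifier/regressor architectures
#'
#' All architectures are compact convolutional networks of stacked
#' 3x3-conv / ReLU / 2x2-maxpool blocks followed by a dense output layer,
#' differing in width and depth; `"small-cnn"` is the classifier default
#' and the deeper `"inception-like"` the regression default. The suffixed
#' names are desk-scale stand-ins keyed by relative capacity.
#'
#' @return Tibble with columns `name` and `filters` (list of per-block
#'   filter counts).
#' @export
list_architectures <- function() {
  tibble(name = names(.arch_filters), filters = unname(.arch_filters))
}

# depth/width block-mean downsampling factors feeding the networks
.downsample_for_task <- function(geometry_task) {
  if (geometry_task == "regress") c(4L, 8L) else c(8L, 8L)
}

# block-mean downsampling of a depth x width matrix by integer factors
.downsample_mean <- function(m, fz, fx) {
  d2 <- (nrow(m) %/% fz) * fz
  w2 <- (ncol(m) %/% fx) * fx
  m <- m[seq_len(d2), seq_len(w2), drop = FALSE]
  dim(m) <- c(fz, (d2 %/% fz) * w2)
  m <- colMeans(m)
  dim(m) <- c(d2 %/% fz, w2)
  m <- t(m)
  dim(m) <- c(fx, (w2 %/% fx) * (d2 %/% fz))
  m <- colMeans(m)
  dim(m) <- c(w2 %/% fx, d2 %/% fz)
  t(m)
}

# extract the pixel matrix from an oct_frame or bare matrix
.frame_pixels <- function(x) {
  if (inherits(x, "oct_frame")) x$pixels else x
}

# frames (list-column or list) -> (Hd*Wd) x N tensor of downsampled pixels
.frames_tensor <- function(frames, downsample) {
  fz <- downsample[1]
  fx <- downsample[2]
  first <- .downsample_mean(.frame_pixels(frames[[1]]), fz, fx)
  out <- matrix(0, length(first), length(frames))
  out[, 1] <- as.vector(first)
  if (length(frames) > 1) {
    for (i in 2:length(frames)) {
      out[, i] <- as.vector(.downsample_mean(.frame_pixels(frames[[i]]), fz, fx))
    }
  }
  attr(out, "map_dim") <- dim(first)
  out
}

#' Centre image sets by the training-set mean pixel value
#'
#' The scalar mean is computed from the training frames only and subtracted
#' from every frame of both sets; the constant is returned so it can be
#' stored on a model and reapplied at prediction time.
#'
#' @param train List of frames (matrices or [oct_frame()]s) or a dataset
#'   tibble with a `frame` column; must be nonempty.
#' @param other Optional second set centred with the same constant.
#' @return List with `train`, `other` (centred numeric matrices) and
#'   `train_mean`.
#' @export
#' @examples
#' ctr <- center_images(list(matrix(100, 2, 2)), list(matrix(120, 2, 2)))
#' ctr$other[[1]][1, 1]  # 20
center_images <- function(train, other = NULL) {
  as_mats <- function(x) {
    if (is.data.frame(x)) x <- x$frame
    lapply(x, .frame_pixels)
  }
  train <- as_mats(train)
  if (length(train) == 0) abort("training set must be nonempty")
  m <- mean(vapply(train, mean, numeric(1)))
  center <- function(lst) lapply(lst, function(p) p - m)
  list(train = center(train),
       other = if (!is.null(other)) center(as_mats(other)),
       train_mean = m)
}

# subject-disjointness audit; any overlap is a hard failure
.assert_no_leakage <- function(train_subjects, val_subjects, test_subjects = NULL) {
  sets <- list(train = train_subjects, validation = val_subjects,
               test = test_subjects)
  sets <- sets[!vapply(sets, is.null, logical(1))]
  nm <- names(sets)
  for (i in seq_along(sets)) for (j in seq_along(sets)) {
    if (i < j) {
      ov <- intersect(sets[[i]], sets[[j]])
      if (length(ov) > 0) {
        abort(sprintf("subject leakage: subject(s) %s appear in both %s and %s sets",
                      paste(ov, collapse = ", "), nm[i], nm[j]))
      }
    }
  }
  invisible(TRUE)
}

# shared preprocessing: filter rows, tensorise, centre, scale to ~[0,1]
.prep_split <- function(data, subjects, downsample, train_mean = NULL) {
  rows <- data[data$subject_id %in% subjects, , drop = FALSE]
  if (nrow(rows) == 0) abort("no frames for the requested subjects")
  X <- .frames_tensor(rows$frame, downsample)
  list(rows = rows, X = X, map_dim = attr(X, "map_dim"))
}

.finish_tensor <- function(X, train_mean) (X - train_mean) / 255

# per-frame standardisation (zero mean, unit SD per image): cancels the
# residual per-frame gain left by the acquisition's own 0-255 scaling,
# which otherwise leaks subject-level speckle/attenuation shifts into the
# distance readout
.standardize_frames <- function(X) {
  X <- sweep(X, 2, colMeans(X))
  sweep(X, 2, pmax(sqrt(colMeans(X^2)), 1e-6), "/")
}

# append a normalised depth-coordinate channel (CoordConv style): the
# padless convolutions are otherwise position-blind, and absolute depth is
# part of the signal (the epidural gap sits at the top of the frame)
.with_coord_channel <- function(X, map_dim) {
  coord <- as.vector(matrix((seq_len(map_dim[1]) - 0.5) / map_dim[1],
                            map_dim[1], map_dim[2]))
  rbind(X, matrix(coord, length(coord), ncol(X)))
}

#' Train a stage or multi-class tissue classifier
#'
#' Trains a convolutional classifier with sparse categorical cross-entropy
#' under SGD with Nesterov momentum (see [training_config()]), early
#' stopping on validation loss, best-validation-epoch weights retained.
#' Training and validation subjects must be disjoint. Images are block-mean
#' downsampled, centred by the training-set mean pixel value and scaled by
#' 1/255 before entering the network; the centring constant is stored on
#' the model.
#'
#' @param data Dataset tibble from [simulate_study()] (or [read_manifest()]
#'   + [load_frames()]) with columns `subject_id`, `label`, `frame`.
#' @param task `"stage1"`..`"stage4"` for the four binary cascade stages
#'   (class 1 is the deeper tissue) or `"multiclass"` for all five layers.
#' @param architecture One of [list_architectures()]`$name`.
#' @param config A [training_config()].
#' @param train_subjects,val_subjects Disjoint subject-id sets. With
#'   `val_subjects = NULL` there is no held-out validation: training is
#'   monitored on the training set itself and runs for a fixed number of
#'   `epochs` (the retraining mode of the nested protocol).
#' @param epochs Optional fixed epoch count, disabling early stopping.
#' @param seed Optional seed making initialisation and batch shuffling
#'   reproducible.
#' @return An `oct_cnn` model object; see also [predict.oct_cnn()],
#'   [tidy.oct_cnn()], [glance.oct_cnn()].
#' @export
train_classifier <- function(data, task, architecture = "small-cnn",
                             config = training_config(),
                             train_subjects, val_subjects = NULL,
                             epochs = NULL, seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, train_classifier(
      data, task, architecture, config, train_subjects, val_subjects,
      epochs, seed = NULL)))
  }
  .assert_no_leakage(train_subjects, val_subjects)
  filters <- .arch_filters[[architecture]]
  if (is.null(filters)) abort(paste0("unknown architecture: ", architecture))

  if (identical(task, "multiclass")) {
    classes <- tissue_labels()
  } else {
    sp <- .stage_spec(task)
    classes <- c(as.character(sp$class0), as.character(sp$class1))
  }
  data <- data[as.character(data$label) %in% classes, , drop = FALSE]
  geometry_task <- .infer_geometry_task(data)
  downsample <- .downsample_for_task(geometry_task)

  tr <- .prep_split(data, train_subjects, downsample)
  y_tr <- match(as.character(tr$rows$label), classes)
  if (length(unique(y_tr)) < length(classes)) {
    abort("training set does not contain every class of the task")
  }
  train_mean <- mean(tr$X)
  X_tr <- .finish_tensor(tr$X, train_mean)
  if (is.null(val_subjects)) {
    X_va <- X_tr
    y_va <- y_tr
    max_epochs <- if (is.null(epochs)) config$max_epochs else as.integer(epochs)
    patience <- Inf
  } else {
    va <- .prep_split(data, val_subjects, downsample)
    y_va <- match(as.character(va$rows$label), classes)
    X_va <- .finish_tensor(va$X, train_mean)
    max_epochs <- if (is.null(epochs)) config$max_epochs else as.integer(epochs)
    patience <- if (is.null(epochs)) config$patience else Inf
  }

  net <- .init_net(tr$map_dim[1], tr$map_dim[2], filters, length(classes),
                   head = "gap")
  fit <- .train_net(net, X_tr, y_tr, X_va, y_va, "class", config,
                    max_epochs = max_epochs, patience = patience)

  structure(
    list(net = fit$net, type = "class", task = task,
         architecture = architecture, classes = classes,
         train_mean = train_mean, downsample = downsample,
         map_dim = tr$map_dim,
         raw_dim = dim(.frame_pixels(tr$rows$frame[[1]])),
         geometry_task = geometry_task, config = config,
         history = fit$history, best_epoch = fit$best_epoch,
         train_subjects = train_subjects, val_subjects = val_subjects),
    class = "oct_cnn"
  )
}

# a dataset's geometry task, from its attribute or the first frame's shape
.infer_geometry_task <- function(data) {
  g <- attr(data, "geometry")
  if (!is.null(g)) return(g$task)
  d <- nrow(.frame_pixels(data$frame[[1]]))
  if (d >= 600) "regress" else "classify"
}

#' Train the needle-to-dura distance regressor
#'
#' Trains a convolutional regressor whose output layer is a single unit
#' with an identity activation, optimising the mean absolute percentage
#' error over a fixed 20 epochs (batch 32, SGD with Nesterov momentum).
#' The regression family uses average pooling (the denoising choice for
#' speckle imagery, and it preserves sub-cell surface-position
#' interpolation) and per-frame input standardisation, which cancels the
#' per-frame gain left by the acquisition's own 0-255 image scaling.
#' Internally the target is expressed in millimetres so that SGD at the
#' standard learning rate is well-scaled; predictions are reported in um.
#' The best-validation-epoch weights are retained.
#'
#' @param data Dataset tibble of epidural-space frames with positive
#'   `distance_um` labels.
#' @inheritParams train_classifier
#' @return An `oct_cnn` model with `type = "regress"`.
#' @export
train_regressor <- function(data, architecture = "inception-like",
                            config = training_config(),
                            train_subjects, val_subjects = NULL,
                            seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, train_regressor(
      data, architecture, config, train_subjects, val_subjects, seed = NULL)))
  }
  .assert_no_leakage(train_subjects, val_subjects)
  filters <- .arch_filters[[architecture]]
  if (is.null(filters)) abort(paste0("unknown architecture: ", architecture))
  data <- data[as.character(data$label) == "epidural_space", , drop = FALSE]
  if (nrow(data) == 0) abort("no epidural-space frames in data")
  if (any(is.na(data$distance_um)) || any(data$distance_um <= 0)) {
    abort("all epidural frames must carry positive distance_um labels")
  }
  geometry_task <- .infer_geometry_task(data)
  downsample <- .downsample_for_task(geometry_task)

  tr <- .prep_split(data, train_subjects, downsample)
  y_tr <- tr$rows$distance_um / 1000
  X_tr <- .standardize_frames(tr$X)
  if (is.null(val_subjects)) {
    X_va <- X_tr
    y_va <- y_tr
  } else {
    va <- .prep_split(data, val_subjects, downsample)
    y_va <- va$rows$distance_um / 1000
    X_va <- .standardize_frames(va$X)
  }

  net <- .init_net(tr$map_dim[1], tr$map_dim[2], filters, 1L,
                   head = "flatten", pool = "avg")
  # identity-output bias starts at the training-mean distance so epochs are
  # spent on the image-dependent signal, not on locating the target scale
  net$layers[[length(net$layers)]]$b <- mean(y_tr)
  fit <- .train_net(net, X_tr, y_tr, X_va, y_va, "reg", config,
                    max_epochs = config$epochs_regression, patience = Inf)

  structure(
    list(net = fit$net, type = "regress", task = "regress",
         architecture = architecture, classes = NULL,
         preproc = "frame_standardize",
         train_mean = NA_real_, downsample = downsample,
         map_dim = tr$map_dim,
         raw_dim = dim(.frame_pixels(tr$rows$frame[[1]])),
         geometry_task = geometry_task, config = config,
         history = fit$history, best_epoch = fit$best_epoch,
         train_subjects = train_subjects, val_subjects = val_subjects),
    class = "oct_cnn"
  )
}

# frames argument of predict/gradcam -> list of pixel matrices
.as_frame_list <- function(data) {
  if (inherits(data, "oct_frame")) return(list(data))
  if (is.data.frame(data)) return(data$frame)
  if (is.matrix(data)) return(list(data))
  data
}

# preprocess arbitrary frames with a model's stored constants
.model_tensor <- function(object, frames) {
  dims <- vapply(frames, function(f) dim(.frame_pixels(f)), integer(2))
  if (any(dims[1, ] != object$raw_dim[1]) || any(dims[2, ] != object$raw_dim[2])) {
    abort(sprintf("frame geometry mismatch: model expects %d x %d px frames",
                  object$raw_dim[1], object$raw_dim[2]))
  }
  X <- .frames_tensor(frames, object$downsample)
  if (identical(object$preproc, "frame_standardize")) {
    .standardize_frames(X)
  } else {
    .finish_tensor(X, object$train_mean)
  }
}

#' Predict from a trained model
#'
#' Classification models return per-class softmax probabilities (rows sum
#' to 1) and the argmax class; regression models return the predicted
#' needle-to-dura distance in um. Frames are preprocessed with the model's
#' stored training mean; outputs are independent of how frames are batched.
#'
#' @param object An `oct_cnn` model.
#' @param data A dataset tibble, list of frames, or single [oct_frame()].
#' @param type `"prob"`, `"class"` or `"distance"` (regression only);
#'   defaults to the model's natural output.
#' @param ... Unused.
#' @return A tibble with `.pred_<class>` probability columns and
#'   `.pred_class` (classification) or `.pred_distance_um` (regression).
#' @export
predict.oct_cnn <- function(object, data, type = NULL, ...) {
  frames <- .as_frame_list(data)
  X <- .model_tensor(object, frames)
  n <- ncol(X)
  outs <- vector("list", ceiling(n / 256))
  for (b in seq_along(outs)) {
    s <- (b - 1L) * 256L + 1L
    e <- min(b * 256L, n)
    outs[[b]] <- .net_forward(object$net, X[, s:e, drop = FALSE])$out
  }
  Z <- do.call(cbind, outs)
  if (object$type == "regress") {
    return(tibble(.pred_distance_um = as.vector(Z) * 1000))
  }
  P <- t(.softmax_cols(Z))
  colnames(P) <- paste0(".pred_", object$classes)
  out <- as_tibble(P)
  out$.pred_class <- factor(object$classes[max.col(P)],
                            levels = object$classes)
  if (identical(type, "class")) return(out[".pred_class"])
  out
}

#' @export
print.oct_cnn <- function(x, ...) {
  cat(sprintf("<oct_cnn> %s %s model (%s)\n",
              x$architecture, x$type, x$task))
  cat(sprintf("  input %d x %d px -> %d x %d maps; best epoch %d of %d run\n",
              x$raw_dim[1], x$raw_dim[2], x$map_dim[1], x$map_dim[2],
              x$best_epoch, nrow(x$history)))
  cat(sprintf("  train subjects: %s | val subjects: %s\n",
              paste(x$train_subjects, collapse = ","),
              paste(x$val_subjects, collapse = ",")))
  invisible(x)
}

#' @describeIn tidy-oct_cnn Per-epoch training log (epoch, learning rate,
#'   train loss, validation loss and metric).
#' @name tidy-oct_cnn
#' @param x An `oct_cnn` model.
#' @param ... Unused.
#' @method tidy oct_cnn
#' @export
tidy.oct_cnn <- function(x, ...) x$history

#' Model-level summary of a trained network
#'
#' @rdname tidy-oct_cnn
#' @method glance oct_cnn
#' @export
glance.oct_cnn <- function(x, ...) {
  best <- x$history[x$best_epoch, ]
  tibble(architecture = x$architecture, task = x$task, type = x$type,
         epochs_run = nrow(x$history), best_epoch = x$best_epoch,
         val_loss = best$val_loss, val_metric = best$val_metric)
}

#' Analytic needle-to-dura distance from the A-scan intensity profile
#'
#' A non-learned baseline and labelling oracle: the lateral mean intensity
#' is computed per depth row, the background level estimated from the
#' darkest rows, and the surface placed at the first row whose mean exceeds
#' the background by a fixed fraction of the background-to-peak contrast.
#' The distance is `pixel_size_um * (surface row index - 1)`.
#'
#' @param frame An [oct_frame()] (or a dataset tibble, giving one distance
#'   per row).
#' @param rel_threshold Fraction of the background-to-peak contrast used as
#'   the detection margin.
#' @param min_contrast Minimum background-to-peak contrast (intensity
#'   units); below this no surface is present and an error is raised.
#' @return Distance(s) in um.
#' @export
#' @examples
#' fr <- withr::with_seed(1,
#'   simulate_frame("epidural_space", distance_um = 625))
#' detect_surface_distance(fr)
detect_surface_distance <- function(frame, rel_threshold = 0.4,
                                    min_contrast = 25) {
  if (is.data.frame(frame)) {
    return(vapply(frame$frame, detect_surface_distance, numeric(1),
                  rel_threshold = rel_threshold, min_contrast = min_contrast))
  }
  px <- if (inherits(frame, "oct_frame")) frame$pixel_size_um else 6.25
  r <- rowMeans(.frame_pixels(frame))
  bg <- as.numeric(quantile(r, 0.05))
  peak <- max(r)
  if (peak - bg < min_contrast) {
    abort("no surface found: frame has no tissue contrast")
  }
  thr <- bg + rel_threshold * (peak - bg)
  i <- which(r >= thr)[1]
  (i - 1) * px
}
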