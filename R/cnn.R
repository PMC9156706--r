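# Internal convolutional-network engine.
#
# Activations between layers use a flat "feature format": a C x (npos * B)
# matrix, where C is the channel count and columns run over spatial
# positions (depth-fastest, column-major over the H x W grid) within each
# sample, samples consecutive. Convolutions are evaluated as im2col patch
# extraction followed by a single BLAS matrix multiply per layer per batch;
# every sample in a batch is independent, so outputs are invariant to batch
# composition.

# column-index vector selecting patch offset (dz, dx) for all output
# positions of all samples in a batch
.conv_cols <- function(hin, hout, wout, dz, dx, npos_in, B) {
  base <- as.vector(outer(seq_len(hout) + dz, (seq_len(wout) - 1L + dx) * hin, "+"))
  rep(base, B) + rep((seq_len(B) - 1L) * npos_in, each = hout * wout)
}

.pool_cols <- function(hin, ho, wo, dz, dx, npos_in, B) {
  base <- as.vector(outer(2L * seq_len(ho) - 1L + dz,
                          (2L * (seq_len(wo) - 1L) + dx) * hin, "+"))
  rep(base, B) + rep((seq_len(B) - 1L) * npos_in, each = ho * wo)
}

# build a conv-block network: [conv 3x3 -> relu -> maxpool 2x2] per filter
# count, then either global average pooling (classification, as in the
# full-size image backbones) or a flatten (regression, which needs spatial
# position) feeding a dense output layer. Weights He-initialised from the
# current RNG state; biases zero.
.init_net <- function(h, w, filters, n_out, head = c("gap", "flatten"),
                      in_channels = 1L, pool = c("max", "avg")) {
  head <- match.arg(head)
  pool <- match.arg(pool)
  layers <- list()
  cin <- as.integer(in_channels)
  for (f in filters) {
    if (h < 3L || w < 3L) abort("input too small for another conv block")
    hout <- h - 2L
    wout <- w - 2L
    Wc <- matrix(rnorm(f * 9L * cin, 0, sqrt(2 / (9 * cin))), f, 9L * cin)
    layers[[length(layers) + 1L]] <-
      list(type = "conv", cin = cin, cout = f, hin = h, win = w,
           hout = hout, wout = wout, W = Wc, b = numeric(f))
    layers[[length(layers) + 1L]] <- list(type = "relu")
    ho <- hout %/% 2L
    wo <- wout %/% 2L
    if (ho < 1L || wo < 1L) abort("feature map too small to pool")
    layers[[length(layers) + 1L]] <-
      list(type = if (pool == "avg") "apool" else "pool",
           c = f, hin = hout, win = wout, hout = ho, wout = wo)
    h <- ho
    w <- wo
    cin <- f
  }
  if (head == "gap") {
    layers[[length(layers) + 1L]] <- list(type = "gap", c = cin, npos = h * w)
    din <- cin
  } else {
    din <- cin * h * w
  }
  Wd <- matrix(rnorm(n_out * din, 0, sqrt(2 / din)), n_out, din)
  layers[[length(layers) + 1L]] <-
    list(type = "dense", c = cin, h = h, w = w, din = din, dout = n_out,
         head = head, W = Wd, b = numeric(n_out))
  list(input = c(h = NA, w = NA), layers = layers)
}

# X: (H*W) x B matrix of preprocessed pixels. Returns head output
# (n_out x B) and, if keep, per-layer caches for backprop.
.net_forward <- function(net, X, keep = FALSE, idx_cache = NULL) {
  if (identical(getOption("octguide.engine", "cpp"), "cpp")) {
    return(cpp_net_forward(net$layers, X, keep))
  }
  .net_forward_r(net, X, keep, idx_cache)
}

.net_backward <- function(net, caches, dZ, stop_at = 0L) {
  if (identical(getOption("octguide.engine", "cpp"), "cpp")) {
    return(cpp_net_backward(net$layers, caches, dZ, as.integer(stop_at)))
  }
  .net_backward_r(net, caches, dZ, stop_at)
}

.net_forward_r <- function(net, X, keep = FALSE, idx_cache = NULL) {
  B <- ncol(X)
  cin1 <- net$layers[[1L]]$cin
  if (cin1 == 1L) {
    A <- matrix(as.vector(X), nrow = 1L)
  } else {
    hw <- nrow(X) %/% cin1
    A <- aperm(array(X, c(hw, cin1, B)), c(2L, 1L, 3L))
    dim(A) <- c(cin1, hw * B)
  }
  caches <- if (keep) vector("list", length(net$layers)) else NULL
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    if (ly$type == "conv") {
      npos_in <- ly$hin * ly$win
      npos_out <- ly$hout * ly$wout
      key <- paste0("c", i, "_", B)
      ic <- if (!is.null(idx_cache)) idx_cache[[key]]
      if (is.null(ic)) {
        cols <- vector("list", 9L)
        k <- 0L
        for (dx in 0:2) for (dz in 0:2) {
          k <- k + 1L
          cols[[k]] <- .conv_cols(ly$hin, ly$hout, ly$wout, dz, dx, npos_in, B)
        }
        # one linear-index matrix gathers all nine patch offsets at once
        idx <- do.call(rbind, lapply(cols, function(cl) {
          if (ly$cin == 1L) matrix(cl, 1L) else
            outer(seq_len(ly$cin), (cl - 1L) * ly$cin, "+")
        }))
        ic <- list(cols = cols, idx = idx)
        if (!is.null(idx_cache)) idx_cache[[key]] <- ic
      }
      P <- A[ic$idx]
      dim(P) <- dim(ic$idx)
      Z <- ly$W %*% P + ly$b
      if (keep) caches[[i]] <- list(P = P, cols = ic$cols,
                                    npos_in = npos_in, B = B)
      A <- Z
    } else if (ly$type == "relu") {
      mask <- A > 0
      A <- A * mask
      if (keep) caches[[i]] <- list(mask = mask, A = A)
    } else if (ly$type == "apool") {
      npos_in <- ly$hin * ly$win
      key <- paste0("a", i, "_", B)
      cols <- if (!is.null(idx_cache)) idx_cache[[key]]
      if (is.null(cols)) {
        cols <- vector("list", 4L)
        k <- 0L
        for (dx in 0:1) for (dz in 0:1) {
          k <- k + 1L
          cols[[k]] <- .pool_cols(ly$hin, ly$hout, ly$wout, dz, dx, npos_in, B)
        }
        if (!is.null(idx_cache)) idx_cache[[key]] <- cols
      }
      out <- (A[, cols[[1]], drop = FALSE] + A[, cols[[2]], drop = FALSE] +
              A[, cols[[3]], drop = FALSE] + A[, cols[[4]], drop = FALSE]) / 4
      if (keep) caches[[i]] <- list(cols = cols, npos_in = npos_in, B = B)
      A <- out
    } else if (ly$type == "pool") {
      npos_in <- ly$hin * ly$win
      key <- paste0("p", i, "_", B)
      cols <- if (!is.null(idx_cache)) idx_cache[[key]]
      if (is.null(cols)) {
        cols <- vector("list", 4L)
        k <- 0L
        for (dx in 0:1) for (dz in 0:1) {
          k <- k + 1L
          cols[[k]] <- .pool_cols(ly$hin, ly$hout, ly$wout, dz, dx, npos_in, B)
        }
        if (!is.null(idx_cache)) idx_cache[[key]] <- cols
      }
      cur <- NULL
      ch <- NULL
      for (k in 1:4) {
        M <- A[, cols[[k]], drop = FALSE]
        if (k == 1L) {
          cur <- M
          ch <- matrix(1L, nrow(M), ncol(M))
        } else {
          upd <- M > cur
          cur[upd] <- M[upd]
          ch[upd] <- k
        }
      }
      if (keep) caches[[i]] <- list(cols = cols, ch = ch, npos_in = npos_in, B = B)
      A <- cur
    } else if (ly$type == "gap") {
      key <- paste0("g", i, "_", B)
      Mh <- if (!is.null(idx_cache)) idx_cache[[key]]
      if (is.null(Mh)) {
        Mh <- matrix(0, ly$npos * B, B)
        for (b2 in seq_len(B)) {
          Mh[((b2 - 1L) * ly$npos + 1L):(b2 * ly$npos), b2] <- 1 / ly$npos
        }
        if (!is.null(idx_cache)) idx_cache[[key]] <- Mh
      }
      if (keep) caches[[i]] <- list(Mh = Mh, B = B)
      A <- A %*% Mh
    } else if (ly$type == "dense") {
      Xf <- A
      if (is.null(ly$head) || ly$head == "flatten") dim(Xf) <- c(ly$din, B)
      if (keep) caches[[i]] <- list(Xf = Xf, B = B)
      A <- ly$W %*% Xf + ly$b
    }
  }
  list(out = A, caches = caches)
}

# Backpropagate dZ (gradient at head output). Returns per-layer parameter
# gradients; if stop_at is given, also the gradient at the *output* of layer
# stop_at (and does not descend further).
.net_backward_r <- function(net, caches, dZ, stop_at = 0L) {
  n <- length(net$layers)
  grads <- vector("list", n)
  G <- dZ
  for (i in rev(seq_len(n))) {
    ly <- net$layers[[i]]
    cc <- caches[[i]]
    if (ly$type == "dense") {
      grads[[i]] <- list(W = tcrossprod(G, cc$Xf), b = rowSums(G))
      G <- crossprod(ly$W, G)
      if (is.null(ly$head) || ly$head == "flatten") {
        dim(G) <- c(ly$c, ly$h * ly$w * cc$B)
      }
    } else if (ly$type == "gap") {
      G <- G %*% t(cc$Mh)
    } else if (ly$type == "apool") {
      Gin <- matrix(0, ly$c, cc$npos_in * cc$B)
      Gq <- G / 4
      for (k in 1:4) {
        Gin[, cc$cols[[k]]] <- Gq
      }
      G <- Gin
    } else if (ly$type == "pool") {
      Gin <- matrix(0, ly$c, cc$npos_in * cc$B)
      for (k in 1:4) {
        Gin[, cc$cols[[k]]] <- G * (cc$ch == k)
      }
      G <- Gin
    } else if (ly$type == "relu") {
      G <- G * cc$mask
    } else if (ly$type == "conv") {
      grads[[i]] <- list(W = tcrossprod(G, cc$P), b = rowSums(G))
      if (i > stop_at + 1L && i > 1L) {
        dP <- crossprod(ly$W, G)
        Gin <- matrix(0, ly$cin, cc$npos_in * cc$B)
        for (k in 1:9) {
          cl <- cc$cols[[k]]
          Gin[, cl] <- Gin[, cl, drop = FALSE] +
            dP[((k - 1L) * ly$cin + 1L):(k * ly$cin), , drop = FALSE]
        }
        G <- Gin
      } else {
        G <- NULL
      }
    }
    if (i == stop_at + 1L) {
      return(list(grads = grads, G_stop = G))
    }
    if (is.null(G) && i > 1L) {
      return(list(grads = grads, G_stop = NULL))
    }
  }
  list(grads = grads, G_stop = G)
}

.softmax_cols <- function(Z) {
  Z <- sweep(Z, 2, apply(Z, 2, max), "-")
  E <- exp(Z)
  sweep(E, 2, colSums(E), "/")
}

# loss and head gradient for one batch; y: integer class (1-based) or
# numeric regression target
.head_loss <- function(Z, y, task) {
  B <- ncol(Z)
  if (task == "class") {
    P <- .softmax_cols(Z)
    picked <- P[cbind(y, seq_len(B))]
    loss <- -mean(log(pmax(picked, 1e-12)))
    dZ <- P
    dZ[cbind(y, seq_len(B))] <- dZ[cbind(y, seq_len(B))] - 1
    dZ <- dZ / B
  } else {
    # mean relative absolute error: the MAPE objective on fraction scale,
    # same minimiser, gradients well-sized for SGD at the standard lr
    x <- as.vector(Z)
    loss <- mean(abs(y - x) / y)
    dZ <- matrix(sign(x - y) / y / B, 1L, B)
  }
  list(loss = loss, dZ = dZ)
}

.zero_velocity <- function(net) {
  lapply(net$layers, function(ly) {
    if (!is.null(ly$W)) list(W = ly$W * 0, b = ly$b * 0) else NULL
  })
}

# SGD with Nesterov momentum (v = m*v - lr*g; p = p + m*v - lr*g)
.sgd_step <- function(net, grads, vel, lr, momentum) {
  for (i in seq_along(net$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    vW <- momentum * vel[[i]]$W - lr * g$W
    vb <- momentum * vel[[i]]$b - lr * g$b
    net$layers[[i]]$W <- net$layers[[i]]$W + momentum * vW - lr * g$W
    net$layers[[i]]$b <- net$layers[[i]]$b + momentum * vb - lr * g$b
    vel[[i]]$W <- vW
    vel[[i]]$b <- vb
  }
  list(net = net, vel = vel)
}

.net_params <- function(net) {
  lapply(net$layers, function(ly) if (!is.null(ly$W)) list(W = ly$W, b = ly$b))
}

.net_set_params <- function(net, params) {
  for (i in seq_along(params)) {
    if (!is.null(params[[i]])) {
      net$layers[[i]]$W <- params[[i]]$W
      net$layers[[i]]$b <- params[[i]]$b
    }
  }
  net
}

# evaluate loss (and task metric) over a set without training
.net_evaluate <- function(net, X, y, task, batch_size = 256L,
                          idx_cache = NULL) {
  n <- ncol(X)
  losses <- numeric(0)
  preds <- NULL
  for (s in seq(1L, n, by = batch_size)) {
    e <- min(s + batch_size - 1L, n)
    Z <- .net_forward(net, X[, s:e, drop = FALSE],
                      idx_cache = idx_cache)$out
    if (task == "class") {
      hl <- .head_loss(Z, y[s:e], task)
      losses <- c(losses, hl$loss * (e - s + 1L))
      preds <- c(preds, max.col(t(Z)))
    } else {
      hl <- .head_loss(Z, y[s:e], task)
      losses <- c(losses, hl$loss * (e - s + 1L))
      preds <- c(preds, as.vector(Z))
    }
  }
  loss <- sum(losses) / n
  metric <- if (task == "class") mean(preds == y) else mape(y, preds)
  list(loss = loss, metric = metric, preds = preds)
}

# full training loop with per-epoch lr decay lr/(1 + decay * epoch) and
# early stopping on validation loss; returns the best-validation-epoch
# parameters and the epoch history.
.train_net <- function(net, X_train, y_train, X_val, y_val, task, config,
                       max_epochs, patience) {
  idx_cache <- new.env(parent = emptyenv())
  vel <- .zero_velocity(net)
  n <- ncol(X_train)
  bs <- config$batch_size
  best_loss <- Inf
  best_params <- .net_params(net)
  best_epoch <- 0L
  wait <- 0L
  hist <- vector("list", max_epochs)
  for (epoch in seq_len(max_epochs)) {
    lr <- config$learning_rate / (1 + config$decay * (epoch - 1))
    idx <- sample.int(n)
    tr_loss <- 0
    for (s in seq(1L, n, by = bs)) {
      e <- min(s + bs - 1L, n)
      take <- idx[s:e]
      fw <- .net_forward(net, X_train[, take, drop = FALSE], keep = TRUE,
                         idx_cache = idx_cache)
      hl <- .head_loss(fw$out, y_train[take], task)
      bw <- .net_backward(net, fw$caches, hl$dZ)
      st <- .sgd_step(net, bw$grads, vel, lr, config$momentum)
      net <- st$net
      vel <- st$vel
      tr_loss <- tr_loss + hl$loss * length(take)
    }
    ev <- .net_evaluate(net, X_val, y_val, task, idx_cache = idx_cache)
    hist[[epoch]] <- tibble(epoch = epoch, lr = lr,
                            train_loss = tr_loss / n,
                            val_loss = ev$loss, val_metric = ev$metric)
    improved <- ev$loss < best_loss - config$min_delta
    if (ev$loss < best_loss) {
      best_loss <- ev$loss
      best_params <- .net_params(net)
      best_epoch <- epoch
    }
    if (improved) {
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  list(net = .net_set_params(net, best_params),
       history = dplyr::bind_rows(hist),
       best_epoch = best_epoch)
}
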