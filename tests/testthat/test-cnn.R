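# the engine is internal; tests reach it through the package namespace
ns <- asNamespace("octguide")

test_that("backpropagation matches finite-difference gradients", {
  withr::with_seed(42, {
    for (task in c("class", "reg")) {
      n_out <- if (task == "class") 3L else 1L
      net <- ns$.init_net(12L, 11L, c(3L, 4L), n_out)
      X <- matrix(rnorm(132 * 2), 132, 2)
      y <- if (task == "class") c(1L, 3L) else c(1.2, 0.7)
      fw <- ns$.net_forward(net, X, keep = TRUE)
      hl <- ns$.head_loss(fw$out, y, task)
      bw <- ns$.net_backward(net, fw$caches, hl$dZ)
      eps <- 1e-6
      for (i in seq_along(net$layers)) {
        if (is.null(net$layers[[i]]$W)) next
        for (p in c("W", "b")) {
          g <- bw$grads[[i]][[p]]
          for (j in sample(length(g), min(5, length(g)))) {
            n2 <- net
            n2$layers[[i]][[p]][j] <- n2$layers[[i]][[p]][j] + eps
            l2 <- ns$.head_loss(ns$.net_forward(n2, X)$out, y, task)$loss
            n2$layers[[i]][[p]][j] <- n2$layers[[i]][[p]][j] - 2 * eps
            l1 <- ns$.head_loss(ns$.net_forward(n2, X)$out, y, task)$loss
            num <- (l2 - l1) / (2 * eps)
            expect_equal(g[j], num, tolerance = 1e-4)
          }
        }
      }
    }
  })
})

test_that("forward passes are invariant to batch composition", {
  withr::with_seed(7, {
    net <- ns$.init_net(14L, 10L, c(4L, 6L), 2L)
    X <- matrix(rnorm(140 * 9), 140, 9)
    full <- ns$.net_forward(net, X)$out
    one_by_one <- sapply(1:9, function(i) {
      ns$.net_forward(net, X[, i, drop = FALSE])$out
    })
    expect_equal(full, matrix(one_by_one, nrow = 2), tolerance = 1e-10)
    # and to cached vs uncached index paths (reference engine)
    withr::local_options(octguide.engine = "r")
    env <- new.env()
    uncached <- ns$.net_forward(net, X)$out
    cached <- ns$.net_forward(net, X, idx_cache = env)$out
    expect_identical(uncached, cached)
  })
})

test_that("the compiled engine matches the reference R implementation", {
  withr::with_seed(13, {
    for (head in c("gap", "flatten")) {
      net <- ns$.init_net(16L, 13L, c(4L, 6L), 3L, head = head)
      X <- matrix(rnorm(208 * 6), 208, 6)
      y <- sample(1:3, 6, TRUE)
      cpp <- withr::with_options(list(octguide.engine = "cpp"), {
        fw <- ns$.net_forward(net, X, keep = TRUE)
        bw <- ns$.net_backward(net, fw$caches,
                               ns$.head_loss(fw$out, y, "class")$dZ)
        list(out = fw$out, grads = bw$grads)
      })
      ref <- withr::with_options(list(octguide.engine = "r"), {
        fw <- ns$.net_forward(net, X, keep = TRUE)
        bw <- ns$.net_backward(net, fw$caches,
                               ns$.head_loss(fw$out, y, "class")$dZ)
        list(out = fw$out, grads = bw$grads)
      })
      expect_equal(cpp$out, ref$out, tolerance = 1e-12)
      for (i in seq_along(net$layers)) {
        if (is.null(ref$grads[[i]])) next
        expect_equal(cpp$grads[[i]]$W, ref$grads[[i]]$W, tolerance = 1e-12)
        expect_equal(as.vector(cpp$grads[[i]]$b), as.vector(ref$grads[[i]]$b),
                     tolerance = 1e-12)
      }
    }
  })
})

test_that("softmax head produces probability columns", {
  withr::with_seed(9, {
    Z <- matrix(rnorm(15, sd = 5), 3, 5)
    P <- ns$.softmax_cols(Z)
    expect_equal(colSums(P), rep(1, 5))
    expect_true(all(P >= 0))
  })
})

test_that("block-mean downsampling averages disjoint blocks", {
  m <- matrix(1:24, 6, 4)
  d <- ns$.downsample_mean(m, 2L, 2L)
  expect_equal(dim(d), c(3L, 2L))
  expect_equal(d[1, 1], mean(m[1:2, 1:2]))
  expect_equal(d[3, 2], mean(m[5:6, 3:4]))
  # non-multiple edges are cropped
  d2 <- ns$.downsample_mean(matrix(1, 7, 5), 2L, 2L)
  expect_equal(dim(d2), c(3L, 2L))
})
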