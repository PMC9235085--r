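# Minimal convolutional network engine with reverse-mode gradients.
#
# Tensors are 4D arrays [H, W, C, N]. A network is a tree of nodes:
# leaves (conv, bn, lrelu, sigmoid, upsample, gap_dense) and containers
# (seq, res). Forward passes return caches mirroring the tree; backward
# passes consume them and return gradients in the same shape as the
# parameters, which the Adam optimizer walks recursively. Convolutions
# run through im2col + GEMM in compiled code; everything else is
# vectorized R. The hand-written gradients are pinned by finite-difference
# checks in the test suite.

LRELU_SLOPE <- 0.2

nn_conv <- function(in_ch, out_ch, k = 3, stride = 1, pad = NULL) {
  if (is.null(pad)) pad <- (k - 1) %/% 2
  fan_in <- k * k * in_ch
  W <- array(rnorm(k * k * in_ch * out_ch, 0, sqrt(2 / fan_in)),
             c(k, k, in_ch, out_ch))
  list(type = "conv", params = list(W = W, b = numeric(out_ch)),
       cfg = list(stride = as.integer(stride), pad = as.integer(pad)))
}

nn_bn <- function(ch, momentum = 0.1, eps = 1e-5) {
  list(type = "bn",
       params = list(gamma = rep(1, ch), beta = numeric(ch)),
       state = list(mean = numeric(ch), var = rep(1, ch)),
       cfg = list(momentum = momentum, eps = eps))
}

nn_lrelu <- function(slope = LRELU_SLOPE) list(type = "lrelu", cfg = list(slope = slope))
nn_sigmoid <- function() list(type = "sigmoid")
nn_upsample <- function() list(type = "upsample")

nn_gap_dense <- function(ch) {
  list(type = "gap_dense",
       params = list(W = rnorm(ch, 0, sqrt(1 / ch)), b = 0))
}

nn_seq <- function(...) {
  ch <- list(...)
  if (length(ch) == 1L && is.list(ch[[1]]) && is.null(ch[[1]]$type))
    ch <- ch[[1]]
  list(type = "seq", children = ch)
}

nn_res <- function(main, proj = NULL, slope = LRELU_SLOPE) {
  list(type = "res", children = list(main = main, proj = proj),
       cfg = list(slope = slope))
}

# channel-major matrix view for batchnorm: [H,W,C,N] <-> (H*W*N) x C
.to_cmat <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
}
.from_cmat <- function(m, d) {
  aperm(array(m, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
}

nn_forward <- function(node, x, training = TRUE) {
  switch(node$type,
    conv = {
      y <- .conv2d_forward(x, node$params$W, node$params$b,
                           node$cfg$stride, node$cfg$pad)
      list(y = y, cache = list(x = x))
    },
    bn = {
      d <- dim(x)
      m <- .to_cmat(x)
      if (training) {
        mu <- colMeans(m)
        v <- colMeans(m^2) - mu^2
        node$state$mean <- (1 - node$cfg$momentum) * node$state$mean +
          node$cfg$momentum * mu
        node$state$var <- (1 - node$cfg$momentum) * node$state$var +
          node$cfg$momentum * v
      } else {
        mu <- node$state$mean
        v <- node$state$var
      }
      invstd <- 1 / sqrt(v + node$cfg$eps)
      nr <- nrow(m)
      mhat <- (m - rep(mu, each = nr)) * rep(invstd, each = nr)
      y <- mhat * rep(node$params$gamma, each = nr) +
        rep(node$params$beta, each = nr)
      list(y = .from_cmat(y, d), state = node$state,
           cache = list(mhat = mhat, invstd = invstd, d = d,
                        training = training))
    },
    lrelu = {
      neg <- x < 0
      y <- x
      y[neg] <- node$cfg$slope * x[neg]
      list(y = y, cache = list(neg = neg))
    },
    sigmoid = {
      y <- 1 / (1 + exp(-x))
      list(y = y, cache = list(y = y))
    },
    upsample = {
      d <- dim(x)
      y <- x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , ,
             drop = FALSE]
      list(y = y, cache = list(d = d))
    },
    gap_dense = {
      d <- dim(x)
      p <- apply(x, c(3, 4), mean) # C x N
      if (is.null(dim(p))) p <- matrix(p, d[3], d[4])
      y <- as.numeric(crossprod(p, node$params$W)) + node$params$b
      list(y = y, cache = list(p = p, d = d))
    },
    seq = {
      caches <- vector("list", length(node$children))
      states <- vector("list", length(node$children))
      for (i in seq_along(node$children)) {
        r <- nn_forward(node$children[[i]], x, training)
        x <- r$y
        caches[i] <- list(r$cache)  # list-assign: keep NULLs as elements
        states[i] <- list(r$state)
      }
      list(y = x, cache = caches, state = states)
    },
    res = {
      rm_ <- nn_forward(node$children$main, x, training)
      if (!is.null(node$children$proj)) {
        rp <- nn_forward(node$children$proj, x, training)
        s <- rm_$y + rp$y
        pcache <- rp$cache; pstate <- rp$state
      } else {
        s <- rm_$y + x
        pcache <- NULL; pstate <- NULL
      }
      neg <- s < 0
      y <- s
      y[neg] <- node$cfg$slope * s[neg]
      list(y = y,
           cache = list(main = rm_$cache, proj = pcache, neg = neg),
           state = list(main = rm_$state, proj = pstate))
    },
    stop("unknown node type: ", node$type))
}

# Fold updated batch-norm running statistics back into the network tree.
nn_update_state <- function(node, state) {
  if (is.null(state)) return(node)
  switch(node$type,
    bn = { node$state <- state; node },
    seq = {
      for (i in seq_along(node$children))
        node$children[[i]] <- nn_update_state(node$children[[i]], state[[i]])
      node
    },
    res = {
      node$children$main <- nn_update_state(node$children$main, state$main)
      if (!is.null(node$children$proj))
        node$children$proj <- nn_update_state(node$children$proj, state$proj)
      node
    },
    node)
}

nn_backward <- function(node, cache, dy) {
  switch(node$type,
    conv = {
      r <- .conv2d_backward(cache$x, node$params$W, dy,
                            node$cfg$stride, node$cfg$pad)
      list(dx = r$dx, grads = list(W = r$dw, b = r$db))
    },
    bn = {
      d <- cache$d
      dmy <- .to_cmat(dy)
      nr <- nrow(dmy)
      dgamma <- colSums(dmy * cache$mhat)
      dbeta <- colSums(dmy)
      dxhat <- dmy * rep(node$params$gamma, each = nr)
      if (cache$training) {
        s1 <- colSums(dxhat)
        s2 <- colSums(dxhat * cache$mhat)
        dm <- rep(cache$invstd / nr, each = nr) *
          (nr * dxhat - rep(s1, each = nr) - cache$mhat * rep(s2, each = nr))
      } else {
        dm <- dxhat * rep(cache$invstd, each = nr)
      }
      list(dx = .from_cmat(dm, d),
           grads = list(gamma = dgamma, beta = dbeta))
    },
    lrelu = {
      dx <- dy
      dx[cache$neg] <- node$cfg$slope * dy[cache$neg]
      list(dx = dx, grads = NULL)
    },
    sigmoid = {
      list(dx = dy * cache$y * (1 - cache$y), grads = NULL)
    },
    upsample = {
      d <- cache$d
      e1 <- dy[seq(1, 2 * d[1], 2), , , , drop = FALSE] +
        dy[seq(2, 2 * d[1], 2), , , , drop = FALSE]
      dx <- e1[, seq(1, 2 * d[2], 2), , , drop = FALSE] +
        e1[, seq(2, 2 * d[2], 2), , , drop = FALSE]
      list(dx = dx, grads = NULL)
    },
    gap_dense = {
      d <- cache$d
      db <- sum(dy)
      dW <- as.numeric(cache$p %*% dy)
      dp <- outer(node$params$W, dy) / (d[1] * d[2]) # C x N, per-pixel share
      dx <- array(rep(dp, each = d[1] * d[2]), c(d[1], d[2], d[3], d[4]))
      list(dx = dx, grads = list(W = dW, b = db))
    },
    seq = {
      n <- length(node$children)
      grads <- vector("list", n)
      for (i in rev(seq_len(n))) {
        r <- nn_backward(node$children[[i]], cache[[i]], dy)
        dy <- r$dx
        grads[i] <- list(r$grads)  # list-assign: keep NULLs as elements
      }
      list(dx = dy, grads = grads)
    },
    res = {
      ds <- dy
      ds[cache$neg] <- node$cfg$slope * dy[cache$neg]
      rm_ <- nn_backward(node$children$main, cache$main, ds)
      if (!is.null(node$children$proj)) {
        rp <- nn_backward(node$children$proj, cache$proj, ds)
        dx <- rm_$dx + rp$dx
        pgrads <- rp$grads
      } else {
        dx <- rm_$dx + ds
        pgrads <- NULL
      }
      list(dx = dx, grads = list(main = rm_$grads, proj = pgrads))
    },
    stop("unknown node type: ", node$type))
}

# ---- gradient bookkeeping ----

grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.list(a)) {
    for (i in seq_along(a)) a[i] <- list(grads_add(a[[i]], b[[i]]))
    return(a)
  }
  a + b
}

grads_scale <- function(g, s) {
  if (is.null(g)) return(NULL)
  if (is.list(g)) return(lapply(g, grads_scale, s = s))
  g * s
}

# ---- Adam optimizer over the node tree ----

adam_init <- function(node) {
  switch(node$type,
    seq = lapply(node$children, adam_init),
    res = list(main = adam_init(node$children$main),
               proj = if (!is.null(node$children$proj))
                 adam_init(node$children$proj)),
    {
      if (is.null(node$params)) NULL
      else lapply(node$params, function(p) list(m = p * 0, v = p * 0))
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(node, grads, state, lr, beta1 = 0.5, beta2 = 0.999,
                      eps = 1e-8, t = 1) {
  if (is.null(grads)) return(list(node = node, state = state))
  switch(node$type,
    seq = {
      for (i in seq_along(node$children)) {
        r <- adam_step(node$children[[i]], grads[[i]], state[[i]],
                       lr, beta1, beta2, eps, t)
        node$children[[i]] <- r$node
        state[i] <- list(r$state)  # list-assign: keep NULLs as elements
      }
      list(node = node, state = state)
    },
    res = {
      r <- adam_step(node$children$main, grads$main, state$main,
                     lr, beta1, beta2, eps, t)
      node$children$main <- r$node; state$main <- r$state
      if (!is.null(node$children$proj) && !is.null(grads$proj)) {
        r <- adam_step(node$children$proj, grads$proj, state$proj,
                       lr, beta1, beta2, eps, t)
        node$children$proj <- r$node; state$proj <- r$state
      }
      list(node = node, state = state)
    },
    {
      for (p in names(node$params)) {
        g <- grads[[p]]
        st <- state[[p]]
        st$m <- beta1 * st$m + (1 - beta1) * g
        st$v <- beta2 * st$v + (1 - beta2) * g^2
        mhat <- st$m / (1 - beta1^t)
        vhat <- st$v / (1 - beta2^t)
        node$params[[p]] <- node$params[[p]] - lr * mhat / (sqrt(vhat) + eps)
        state[[p]] <- st
      }
      list(node = node, state = state)
    })
}

# flatten all parameters into one numeric vector (checkpointing/tests)
nn_flatten_params <- function(node) {
  switch(node$type,
    seq = unlist(lapply(node$children, nn_flatten_params)),
    res = c(nn_flatten_params(node$children$main),
            if (!is.null(node$children$proj))
              nn_flatten_params(node$children$proj)),
    if (is.null(node$params)) numeric(0) else
      unlist(node$params, use.names = FALSE))
}

nn_unflatten_params <- function(node, values, pos = 1L) {
  switch(node$type,
    seq = {
      for (i in seq_along(node$children)) {
        r <- nn_unflatten_params(node$children[[i]], values, pos)
        node$children[[i]] <- r$node
        pos <- r$pos
      }
      list(node = node, pos = pos)
    },
    res = {
      r <- nn_unflatten_params(node$children$main, values, pos)
      node$children$main <- r$node; pos <- r$pos
      if (!is.null(node$children$proj)) {
        r <- nn_unflatten_params(node$children$proj, values, pos)
        node$children$proj <- r$node; pos <- r$pos
      }
      list(node = node, pos = pos)
    },
    {
      if (!is.null(node$params)) {
        for (p in names(node$params)) {
          n <- length(node$params[[p]])
          arr <- values[pos:(pos + n - 1L)]
          if (!is.null(dim(node$params[[p]]))) dim(arr) <- dim(node$params[[p]])
          node$params[[p]] <- arr
          pos <- pos + n
        }
      }
      list(node = node, pos = pos)
    })
}
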