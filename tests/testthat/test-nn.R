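# Finite-difference verification of the hand-written backward passes.

flatten_grads <- function(g) {
  if (is.null(g)) return(numeric(0))
  if (is.list(g)) return(unlist(lapply(g, flatten_grads), use.names = FALSE))
  as.numeric(g)
}

test_that("network gradients match finite differences (plain layers)", {
  ns <- asNamespace("midfacer")
  set.seed(42)
  net <- ns$nn_seq(list(ns$nn_conv(2, 3, 3, 2), ns$nn_bn(3), ns$nn_lrelu(),
                        ns$nn_upsample(), ns$nn_conv(3, 1, 3, 1),
                        ns$nn_sigmoid()))
  x <- array(rnorm(8 * 8 * 2 * 2), c(8, 8, 2, 2))
  loss_of <- function(net, x) sum(ns$nn_forward(net, x, TRUE)$y^2)
  fwd <- ns$nn_forward(net, x, TRUE)
  bk <- ns$nn_backward(net, fwd$cache, 2 * fwd$y)
  # input gradient
  for (idx in sample(length(x), 6)) {
    eps <- 1e-6
    x1 <- x; x1[idx] <- x1[idx] + eps
    x2 <- x; x2[idx] <- x2[idx] - eps
    num <- (loss_of(net, x1) - loss_of(net, x2)) / (2 * eps)
    expect_equal(bk$dx[idx], num, tolerance = 1e-4)
  }
  # parameter gradients
  flat <- ns$nn_flatten_params(net)
  gflat <- flatten_grads(bk$grads)
  expect_length(gflat, length(flat))
  for (idx in sample(length(flat), 10)) {
    eps <- 1e-6
    f1 <- flat; f1[idx] <- f1[idx] + eps
    f2 <- flat; f2[idx] <- f2[idx] - eps
    num <- (loss_of(ns$nn_unflatten_params(net, f1)$node, x) -
              loss_of(ns$nn_unflatten_params(net, f2)$node, x)) / (2 * eps)
    expect_equal(gflat[idx], num, tolerance = 1e-4)
  }
})

test_that("network gradients match finite differences (residual block + head)", {
  ns <- asNamespace("midfacer")
  set.seed(43)
  net <- ns$nn_seq(list(ns$nn_conv(2, 4, 3, 1),
                        ns$.basic_block(4, 6, 2),
                        ns$nn_gap_dense(6)))
  x <- array(rnorm(8 * 8 * 2 * 2), c(8, 8, 2, 2))
  loss_of <- function(net, x) sum(ns$nn_forward(net, x, TRUE)$y^2)
  fwd <- ns$nn_forward(net, x, TRUE)
  bk <- ns$nn_backward(net, fwd$cache, 2 * fwd$y)
  flat <- ns$nn_flatten_params(net)
  gflat <- flatten_grads(bk$grads)
  expect_length(gflat, length(flat))
  for (idx in sample(length(flat), 12)) {
    eps <- 1e-6
    f1 <- flat; f1[idx] <- f1[idx] + eps
    f2 <- flat; f2[idx] <- f2[idx] - eps
    num <- (loss_of(ns$nn_unflatten_params(net, f1)$node, x) -
              loss_of(ns$nn_unflatten_params(net, f2)$node, x)) / (2 * eps)
    expect_equal(gflat[idx], num, tolerance = 1e-4)
  }
})

test_that("compiled convolution agrees with a direct R convolution", {
  set.seed(44)
  H <- 6; W <- 5; C <- 2; F_ <- 3; k <- 3; pad <- 1; stride <- 2
  x <- array(rnorm(H * W * C), c(H, W, C, 1))
  w <- array(rnorm(k * k * C * F_), c(k, k, C, F_))
  b <- rnorm(F_)
  y <- midfacer:::.conv2d_forward(x, w, b, stride, pad)
  Ho <- (H + 2 * pad - k) %/% stride + 1
  Wo <- (W + 2 * pad - k) %/% stride + 1
  expect_equal(dim(y), c(Ho, Wo, F_, 1))
  # brute-force reference
  xp <- array(0, c(H + 2 * pad, W + 2 * pad, C))
  xp[pad + 1:H, pad + 1:W, ] <- x[, , , 1]
  for (f in 1:F_) for (i in 1:Ho) for (j in 1:Wo) {
    patch <- xp[(i - 1) * stride + 1:k, (j - 1) * stride + 1:k, , drop = FALSE]
    expect_equal(y[i, j, f, 1], sum(patch * w[, , , f]) + b[f],
                 tolerance = 1e-10)
  }
})

test_that("Adam updates shrink a quadratic objective", {
  ns <- asNamespace("midfacer")
  set.seed(45)
  net <- ns$nn_seq(list(ns$nn_conv(1, 1, 3, 1)))
  x <- array(rnorm(6 * 6), c(6, 6, 1, 1))
  st <- ns$adam_init(net)
  loss0 <- NULL
  for (t in 1:50) {
    fwd <- ns$nn_forward(net, x, TRUE)
    if (t == 1) loss0 <- sum(fwd$y^2)
    bk <- ns$nn_backward(net, fwd$cache, 2 * fwd$y)
    r <- ns$adam_step(net, bk$grads, st, lr = 0.05, t = t)
    net <- r$node; st <- r$state
  }
  expect_lt(sum(ns$nn_forward(net, x, TRUE)$y^2), 0.1 * loss0)
})
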