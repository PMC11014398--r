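# The mini CNN framework: layer forward correctness and analytic gradients
# against central finite differences.

fd_layer_check <- function(layer, in_dim, n_checks = 5, training = TRUE,
                           tol = 1e-4, seed = 42) {
  withr::local_seed(seed)
  x <- array(rnorm(prod(in_dim)), in_dim)
  loss_of <- function(l, xx) sum(sin(layer_forward_t(l, xx, training)))
  layer_forward_t <- function(l, xx, tr) ecodistill:::layer_forward(l, xx, tr)$out
  fw <- ecodistill:::layer_forward(layer, x, training)
  gy <- cos(fw$out)
  if (!is.null(dim(fw$out))) dim(gy) <- dim(fw$out) else gy <- matrix(gy, nrow = 1)
  bw <- ecodistill:::layer_backward(layer, fw$cache, gy)
  eps <- 1e-6
  # input gradient at sampled coordinates
  for (i in sample(length(x), n_checks)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    num <- (loss_of(layer, xp) - loss_of(layer, xm)) / (2 * eps)
    expect_equal(bw$gx[i], num, tolerance = tol * max(1, abs(num)))
  }
  # parameter gradients
  ps <- ecodistill:::layer_params(layer)
  for (pn in names(ps)) {
    for (i in sample(length(ps[[pn]]), min(n_checks, length(ps[[pn]])))) {
      pp <- ps; pp[[pn]][i] <- pp[[pn]][i] + eps
      pm <- ps; pm[[pn]][i] <- pm[[pn]][i] - eps
      lp <- ecodistill:::layer_set_params(layer, pp)
      lm <- ecodistill:::layer_set_params(layer, pm)
      num <- (loss_of(lp, x) - loss_of(lm, x)) / (2 * eps)
      expect_equal(bw$grads[[pn]][i], num, tolerance = tol * max(1, abs(num)))
    }
  }
  invisible(NULL)
}

test_that("convolution matches a naive direct computation", {
  withr::local_seed(1)
  H <- 7; W <- 6; C <- 3; N <- 2; k <- 3; Cout <- 4; stride <- 2; pad <- 1
  x <- array(rnorm(H * W * C * N), c(H, W, C, N))
  w <- array(rnorm(k * k * C * Cout), c(k, k, C, Cout))
  b <- rnorm(Cout)
  y <- ecodistill:::.conv2d_fwd(x, w, b, stride, pad, 1L)
  Ho <- (H + 2 * pad - k) %/% stride + 1
  Wo <- (W + 2 * pad - k) %/% stride + 1
  xp <- array(0, c(H + 2 * pad, W + 2 * pad, C, N))
  xp[pad + 1:H, pad + 1:W, , ] <- x
  ref <- array(0, c(Ho, Wo, Cout, N))
  for (n in 1:N) for (co in 1:Cout) for (ho in 1:Ho) for (wo in 1:Wo) {
    patch <- xp[(ho - 1) * stride + 1:k, (wo - 1) * stride + 1:k, , n]
    ref[ho, wo, co, n] <- sum(patch * w[, , , co]) + b[co]
  }
  expect_equal(y, ref, tolerance = 1e-12)
})

test_that("layer gradients agree with finite differences", {
  fd_layer_check(ecodistill:::nn_conv2d(3, 4, 3, stride = 2), c(7, 6, 3, 2))
  fd_layer_check(ecodistill:::nn_conv2d(4, 4, 3, groups = 4, bias = FALSE),
                 c(6, 6, 4, 2))
  fd_layer_check(ecodistill:::nn_batchnorm2d(3), c(5, 5, 3, 4))
  fd_layer_check(ecodistill:::nn_se(8), c(4, 4, 8, 3))
  fd_layer_check(ecodistill:::nn_linear(10, 3), c(10, 4))
  fd_layer_check(ecodistill:::nn_maxpool2(), c(8, 8, 3, 2))
  fd_layer_check(ecodistill:::nn_gap(), c(4, 4, 5, 2))
})

test_that("bottleneck gradients agree with finite differences", {
  fd_layer_check(ecodistill:::nn_bottleneck(6, 12, 6, stride = 1, se = TRUE),
                 c(8, 8, 6, 2), tol = 5e-3)
})

test_that("SE block gates by sigmoid excitation and preserves shape", {
  withr::local_seed(2)
  se <- ecodistill:::nn_se(6)
  x <- array(1, c(3, 3, 6, 2))
  fw <- ecodistill:::layer_forward(se, x)
  expect_equal(dim(fw$out), dim(x))
  # with all-ones input the gate is sigmoid(W2 relu(W1 1 + b1) + b2)
  s <- matrix(1, 6, 2)
  z <- pmax(se$params$w1 %*% s + se$params$b1, 0)
  g <- 1 / (1 + exp(-(se$params$w2 %*% z + se$params$b2)))
  expect_equal(fw$out[1, 1, , ], g, tolerance = 1e-12)
})

test_that("residual bottleneck passes identity when all weights are zero", {
  btl <- ecodistill:::nn_bottleneck(4, 8, 4, stride = 1, se = FALSE)
  ps <- ecodistill:::layer_params(btl)
  ps <- lapply(ps, function(p) p * 0)
  btl <- ecodistill:::layer_set_params(btl, ps)
  x <- array(rnorm(5 * 5 * 4 * 2), c(5, 5, 4, 2))
  out <- ecodistill:::layer_forward(btl, x, training = FALSE)$out
  expect_equal(out, x, tolerance = 1e-12)
})

test_that("batch norm switches between batch and running statistics", {
  withr::local_seed(3)
  bn <- ecodistill:::nn_batchnorm2d(2)
  x <- array(rnorm(4 * 4 * 2 * 8, mean = 3, sd = 2), c(4, 4, 2, 8))
  fw <- ecodistill:::layer_forward(bn, x, training = TRUE)
  # training mode: output standardized per channel
  ch1 <- fw$out[, , 1, ]
  expect_lt(abs(mean(ch1)), 1e-10)
  expect_equal(sd(as.vector(ch1)) * sqrt((length(ch1) - 1) / length(ch1)), 1,
               tolerance = 1e-3)
  # eval mode uses running buffers -> deterministic, batch-size independent
  bn2 <- fw$layer
  out_full <- ecodistill:::layer_forward(bn2, x, training = FALSE)$out
  out_one <- ecodistill:::layer_forward(bn2, x[, , , 1, drop = FALSE],
                                        training = FALSE)$out
  expect_equal(out_full[, , , 1, drop = FALSE], out_one, tolerance = 1e-12)
})
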