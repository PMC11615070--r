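# The neural-network engine: convolution kernels against a direct-loop
# oracle, and finite-difference gradient checks through every layer type.

test_that("convolution forward matches the direct-loop oracle", {
  nf <- asNamespace("neurofuse")
  set.seed(1)
  cases <- list(
    list(xd = c(7, 9, 5, 3), kd = c(3, 3, 3), ci = 3, co = 4,
         stride = c(2, 1, 2), pad = c(1, 1, 1)),
    list(xd = c(6, 20, 1, 2), kd = c(1, 5, 1), ci = 2, co = 3,
         stride = c(1, 2, 1), pad = c(0, 2, 0)),
    list(xd = c(8, 8, 8, 1), kd = c(7, 7, 7), ci = 1, co = 2,
         stride = c(2, 2, 2), pad = c(3, 3, 3)))
  for (cs in cases) {
    x <- array(rnorm(prod(cs$xd)), cs$xd)
    w <- array(rnorm(prod(cs$kd) * cs$ci * cs$co), c(cs$kd, cs$ci, cs$co))
    b <- rnorm(cs$co)
    got <- nf$nf_conv_fwd(x, dim(x)[1:3], w, as.integer(cs$kd), cs$ci, cs$co,
                          b, as.integer(cs$stride), as.integer(cs$pad))
    want <- oracle_conv(x, w, b, cs$stride, cs$pad)
    expect_equal(dim(got), dim(want))
    expect_lt(max(abs(got - want)), 1e-10)
  }
})

test_that("convolution backward matches finite differences", {
  nf <- asNamespace("neurofuse")
  set.seed(2)
  x <- array(rnorm(6 * 7 * 4 * 2), c(6, 7, 4, 2))
  w <- array(rnorm(27 * 2 * 3), c(3, 3, 3, 2, 3))
  b <- rnorm(3)
  kd <- c(3L, 3L, 3L); st <- c(2L, 1L, 1L); pd <- c(1L, 1L, 1L)
  y <- nf$nf_conv_fwd(x, dim(x)[1:3], w, kd, 2L, 3L, b, st, pd)
  gy <- array(rnorm(length(y)), dim(y))
  g <- nf$nf_conv_bwd(x, dim(x)[1:3], w, kd, 2L, 3L, gy, st, pd)
  eps <- 1e-6
  for (i in sample(length(x), 5)) {
    xx <- x; xx[i] <- x[i] + eps
    up <- sum(nf$nf_conv_fwd(xx, dim(x)[1:3], w, kd, 2L, 3L, b, st, pd) * gy)
    xx[i] <- x[i] - eps
    dn <- sum(nf$nf_conv_fwd(xx, dim(x)[1:3], w, kd, 2L, 3L, b, st, pd) * gy)
    expect_lt(abs((up - dn) / (2 * eps) - g$gx[i]), 1e-6)
  }
  for (j in sample(length(w), 5)) {
    ww <- w; ww[j] <- w[j] + eps
    up <- sum(nf$nf_conv_fwd(x, dim(x)[1:3], ww, kd, 2L, 3L, b, st, pd) * gy)
    ww[j] <- w[j] - eps
    dn <- sum(nf$nf_conv_fwd(x, dim(x)[1:3], ww, kd, 2L, 3L, b, st, pd) * gy)
    expect_lt(abs((up - dn) / (2 * eps) - g$gw[j]), 1e-6)
  }
})

test_that("adaptive pooling computes exact window means", {
  nf <- asNamespace("neurofuse")
  x <- array(seq_len(4 * 4), c(4, 4, 1, 1))
  pool <- nf$nn_apool(c(2, 2, 1))
  y <- pool$forward(x)
  for (i in 1:2) for (j in 1:2)
    expect_equal(y[i, j, 1, 1],
                 mean(x[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), 1, 1]))
})

test_that("instance norm handles constant input without NaN", {
  nf <- asNamespace("neurofuse")
  norm <- nf$nn_inorm(3)
  x <- array(0, c(5, 5, 1, 3))
  y <- norm$forward(x)
  expect_true(all(is.finite(y)))
  expect_equal(as.numeric(y), rep(0, length(y)))
})

test_that("a zero-residual block is the identity for nonnegative input", {
  nf <- asNamespace("neurofuse")
  set.seed(3)
  blk <- nf$nn_resblock(2, 2, c(3, 3, 1), c(1, 1, 1))
  # zero the transform branch output: zero final conv and its norm bias
  blk$main[[4]]$par$w[] <- 0
  blk$main[[4]]$par$b[] <- 0
  blk$main[[5]]$par$g[] <- 1
  blk$main[[5]]$par$b[] <- 0
  x <- array(abs(rnorm(6 * 6 * 1 * 2)), c(6, 6, 1, 2))
  y <- blk$forward(x)
  expect_equal(y, x, tolerance = 1e-10)
})

test_that("a strided block halves the strided axis", {
  nf <- asNamespace("neurofuse")
  blk <- nf$nn_resblock(1, 1, c(3, 3, 1), c(1, 2, 1))
  x <- array(rnorm(4 * 8), c(4, 8, 1, 1))
  expect_equal(dim(blk$forward(x))[2], 4)
})

test_that("all five strategies pass end-to-end gradient checks", {
  set.seed(4)
  meg <- matrix(rnorm(6 * 64), 6, 64)
  mri <- array(rnorm(12^3), c(12, 12, 12))
  for (st in c("meg_only", "mri_only", "early", "inter", "late")) {
    model <- nf_model(tiny_model_config(st), seed = 3)
    err <- check_model_gradients(model, meg, mri, n_checks = 5)
    expect_lt(err, 1e-3)
  }
})

test_that("a null Adam step with lr = 0 leaves parameters unchanged", {
  nf <- asNamespace("neurofuse")
  set.seed(5)
  lin <- nf$nn_linear(4, 3)
  before <- lin$par$w
  y <- lin$forward(rnorm(4))
  lin$backward(rnorm(3))
  nf$adam_step(list(lin), lr = 0, weight_decay = 0)
  expect_identical(lin$par$w, before)
})
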