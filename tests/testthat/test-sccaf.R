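# SCCAF: patch embedding, cross-attention and channel-wise aggregation.

test_that("MMPE yields 4096 tokens for both modalities at the canonical pools", {
  set.seed(1)
  f_meg <- array(rnorm(102 * 128 * 1 * 2), c(102, 128, 1, 2))
  f_mri <- array(rnorm(24^3 * 2), c(24, 24, 24, 2))
  tk <- mmpe(f_meg, f_mri)
  expect_equal(nrow(tk$meg), 4096)
  expect_equal(nrow(tk$mri), 4096)
  expect_equal(ncol(tk$meg), 2)
  expect_equal(prod(c(64, 64)), prod(c(16, 16, 16)))
})

test_that("MMPE on a spatially constant map yields identical token rows", {
  f_meg <- array(2, c(8, 8, 1, 3))
  f_mri <- array(-1, c(4, 4, 4, 3))
  tk <- mmpe(f_meg, f_mri, pool_2d = c(8, 8), pool_3d = c(4, 4, 4),
             positional = FALSE)
  expect_equal(max(apply(tk$meg, 2, function(cc) diff(range(cc)))), 0)
  expect_equal(max(apply(tk$mri, 2, function(cc) diff(range(cc)))), 0)
})

test_that("MMPE pooling reproduces explicit window means", {
  x <- array(rnorm(4 * 4 * 2), c(4, 4, 1, 2))
  tk <- mmpe(x, array(rnorm(8), c(2, 2, 2, 2)),
             pool_2d = c(2, 2), pool_3d = c(2, 2, 1), positional = FALSE)
  # token (i, j) = mean of its 2x2 window (tokens in column-major order)
  for (ch in 1:2) {
    want <- c(mean(x[1:2, 1:2, 1, ch]), mean(x[3:4, 1:2, 1, ch]),
              mean(x[1:2, 3:4, 1, ch]), mean(x[3:4, 3:4, 1, ch]))
    expect_equal(unname(tk$meg[, ch]), want, tolerance = 1e-12)
  }
  expect_error(mmpe(x, array(0, c(2, 2, 2, 2)), pool_2d = c(8, 8),
                    pool_3d = c(4, 4, 4)), "")
})

test_that("scaled cross-attention collapses correctly in degenerate cases", {
  # single K/V token: output equals V for any Q
  Q <- matrix(rnorm(6), 3, 2)
  K <- matrix(c(1, 2), 1, 2)
  V <- matrix(c(5, -3), 1, 2)
  Z <- scaled_cross_attention(Q, K, V)
  expect_equal(Z, matrix(rep(V, each = 3), 3, 2), tolerance = 1e-12)

  # identical K rows: uniform attention, each output row = column means of V
  K2 <- matrix(1, 4, 2)
  V2 <- matrix(rnorm(8), 4, 2)
  Z2 <- scaled_cross_attention(Q, K2, V2)
  for (i in 1:3) expect_equal(Z2[i, ], colMeans(V2), tolerance = 1e-12)

  expect_error(scaled_cross_attention(Q, matrix(0, 2, 3), matrix(0, 2, 3)),
               "channel")
})

test_that("attention matches the brute-force softmax oracle on small token sets", {
  set.seed(2)
  for (i in 1:20) {
    P <- sample(2:8, 1); C <- sample(2:4, 1)
    Q <- matrix(rnorm(P * C), P, C)
    K <- matrix(rnorm(P * C), P, C)
    V <- matrix(rnorm(P * C), P, C)
    expect_lt(max(abs(scaled_cross_attention(Q, K, V) -
                        oracle_attention(Q, K, V))), 1e-6)
  }
  # hand-enumerable 2x2 case
  Q <- matrix(c(1, 0, 0, 1), 2, 2)
  K <- matrix(c(1, -1, 0.5, 2), 2, 2)
  V <- matrix(c(3, 1, -2, 0), 2, 2)
  expect_lt(max(abs(scaled_cross_attention(Q, K, V) -
                      oracle_attention(Q, K, V))), 1e-12)
})

test_that("attention rows are row-stochastic and outputs stay in the V hull", {
  set.seed(3)
  Q <- matrix(rnorm(20), 5, 4); K <- matrix(rnorm(24), 6, 4)
  V <- matrix(rnorm(24), 6, 4)
  r <- scaled_cross_attention(Q, K, V, return_attention = TRUE)
  expect_lt(max(abs(rowSums(r$A) - 1)), 1e-6)
  for (j in 1:4) {
    expect_gte(min(r$Z[, j]) + 1e-12, min(V[, j]))
    expect_lte(max(r$Z[, j]) - 1e-12, max(V[, j]))
  }
})

test_that("SCA with identical inputs and tied maps is symmetric, and composes with the attention primitive", {
  set.seed(4)
  tok <- matrix(rnorm(8 * 4), 8, 4)
  Z <- sca(tok, tok, maps = "identity")
  expect_equal(Z$Z_a, Z$Z_b, tolerance = 1e-12)

  ta <- matrix(rnorm(32), 8, 4); tb <- matrix(rnorm(32), 8, 4)
  Z2 <- sca(ta, tb, maps = "identity")
  expect_equal(Z2$Z_a, scaled_cross_attention(tb, ta, ta), tolerance = 1e-12)
  expect_equal(Z2$Z_b, scaled_cross_attention(ta, tb, tb), tolerance = 1e-12)
  expect_error(sca(ta, tb[1:4, ]), "share")
})

test_that("permuting K/V tokens together leaves the attention output unchanged", {
  set.seed(5)
  Q <- matrix(rnorm(24), 6, 4)
  K <- matrix(rnorm(28), 7, 4); V <- matrix(rnorm(28), 7, 4)
  p <- sample(7)
  expect_equal(scaled_cross_attention(Q, K, V),
               scaled_cross_attention(Q, K[p, ], V[p, ]), tolerance = 1e-12)
})

test_that("CFA weights live on the 2-simplex and reproduce the explicit blend", {
  set.seed(6)
  ta <- matrix(rnorm(40), 10, 4); tb <- matrix(rnorm(40), 10, 4)
  Z <- sca(ta, tb, maps = "identity")
  out <- cfa(Z, ta, tb)
  expect_lt(max(abs(out$w_a + out$w_b - 1)), 1e-6)
  expect_true(all(out$w_a > 0 & out$w_a < 1))
  expect_equal(out$fused, out$w_a * ta + out$w_b * tb, tolerance = 1e-12)
})

test_that("CFA collapses to the arithmetic mean under equal logits and saturates to one modality", {
  nf <- asNamespace("neurofuse")
  set.seed(7)
  ta <- matrix(rnorm(24), 6, 4); tb <- matrix(rnorm(24), 6, 4)
  Z <- sca(ta, tb, maps = "identity")
  mlp <- nf$nn_cfa(4)
  mlp$par$w2[] <- 0; mlp$par$b2[] <- 0      # forced equal logits
  out <- cfa(Z, ta, tb, mlp = mlp)
  expect_equal(out$w_a, matrix(0.5, 6, 4))
  expect_equal(out$fused, (ta + tb) / 2, tolerance = 1e-12)

  mlp$par$b2[1:4] <- 50                     # large-margin MEG logits
  sat <- cfa(Z, ta, tb, mlp = mlp)
  expect_lt(max(abs(sat$fused - ta)), 1e-4)
})

test_that("finite nonzero gradients reach both branch inputs through the fused output", {
  nf <- asNamespace("neurofuse")
  set.seed(8)
  model <- nf_model(tiny_model_config("inter"), seed = 2)
  meg <- matrix(rnorm(6 * 64), 6, 64)
  mri <- array(rnorm(12^3), c(12, 12, 12))
  lg <- nf_forward(model, meg, mri, train = TRUE)
  nf$zero_grad(model$modules)
  g <- nf$nf_backward(model, c(1, -1))
  expect_true(all(is.finite(g$g_meg)))
  expect_true(all(is.finite(g$g_mri)))
  expect_gt(sum(abs(g$g_meg)), 0)
  expect_gt(sum(abs(g$g_mri)), 0)
})
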