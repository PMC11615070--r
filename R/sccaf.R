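# Spatial-Channel Cross-Attention Fusion (SCCAF).
#
# Three stages fuse the two branch feature maps:
#   * MMPE (multi-modal patch embedding): adaptive average pooling to fixed
#     grids -- (64, 64) for MEG and (16, 16, 16) for MRI at full size, so both
#     modalities yield P = 4096 tokens -- followed by flattening of spatial
#     positions to a P x C token matrix, a per-channel depth-wise projection
#     (scale + bias), and an optional learned positional embedding.
#   * SCA (spatial-wise cross-modal attention): scaled dot-product attention
#     where the query comes from the opposite modality and key/value from the
#     same modality, Z = softmax(Q K' / sqrt(C)) V.
#   * CFA (channel-wise feature aggregation): the two attended outputs are
#     concatenated, an MLP produces per-token per-channel modality logits, and
#     a pairwise softmax yields convex weights w_a + w_b = 1 that blend the
#     two token matrices.

#' Scaled cross-attention
#'
#' Computes `softmax(Q K' / sqrt(C)) V` with row-wise softmax, the attention
#' primitive used inside the SCA block.  Rows of the attention matrix are
#' convex weights, so each output row lies in the convex hull of the rows
#' of `V`.
#'
#' @param Q,K,V Token matrices; `Q` is P_q x C, `K` and `V` are P_kv x C.
#' @param scale Scaling denominator, default `sqrt(ncol(Q))`.
#' @param return_attention If `TRUE`, also return the attention matrix.
#' @return The attended token matrix (P_q x C), or a list with `Z` and `A`.
#' @export
scaled_cross_attention <- function(Q, K, V, scale = sqrt(ncol(Q)),
                                   return_attention = FALSE) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  if (ncol(Q) != ncol(K)) stop("Q and K must share the channel dimension")
  if (nrow(K) != nrow(V)) stop("K and V must share the token count")
  A <- softmax_rows(tcrossprod(Q, K) / scale)
  Z <- A %*% V
  if (return_attention) list(Z = Z, A = A) else Z
}

softmax_rows <- function(S) {
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E / rowSums(E)
}

# Backward through Z = softmax(QK'/scale) V given cached A, Q, K, V.
attention_backward <- function(gZ, A, Q, K, V, scale) {
  gA <- tcrossprod(gZ, V)             # gZ %*% t(V)
  gV <- crossprod(A, gZ)
  gS <- A * (gA - rowSums(gA * A))    # softmax Jacobian, row-wise
  gQ <- (gS %*% K) / scale
  gK <- crossprod(gS, Q) / scale
  list(gQ = gQ, gK = gK, gV = gV)
}

## ---- MMPE ------------------------------------------------------------------

# One MMPE half: pool -> flatten -> per-channel scale/bias -> (+ pos emb).
nn_mmpe <- function(channels, pool_size, n_tokens = prod(pool_size),
                    positional = TRUE) {
  par <- list(s = rep(1, channels), b = rep(0, channels))
  if (positional)
    par$pos <- matrix(stats::rnorm(n_tokens * channels, sd = 0.02),
                      n_tokens, channels)
  m <- new_module("mmpe", par)
  m$pool <- nn_apool(pool_size)
  m$mods <- list(m$pool)
  m$n_tokens <- n_tokens
  m$forward <- function(x, train = TRUE) {
    p <- m$pool$forward(x, train)
    tok <- matrix(p, m$n_tokens, length(m$par$s))
    m$tok_raw <- tok
    y <- sweep(tok, 2, m$par$s, `*`)
    y <- sweep(y, 2, m$par$b, `+`)
    if (!is.null(m$par$pos)) y <- y + m$par$pos
    y
  }
  m$backward <- function(gy) {
    if (!is.null(m$par$pos)) m$gr$pos <- m$gr$pos + gy
    m$gr$s <- m$gr$s + colSums(gy * m$tok_raw)
    m$gr$b <- m$gr$b + colSums(gy)
    gtok <- sweep(gy, 2, m$par$s, `*`)
    dim(gtok) <- c(m$pool$out_size, length(m$par$s))
    m$pool$backward(gtok)
  }
  m
}

#' Multi-modal patch embedding
#'
#' Pools the MEG feature map to `pool_2d` and the MRI feature map to
#' `pool_3d`, flattens spatial positions into tokens and applies a per-channel
#' depth-wise projection.  At the default pool sizes both modalities yield
#' 64 * 64 = 16^3 = 4096 tokens.
#'
#' @param f_meg MEG feature array (sensors, time, 1, C) as produced by
#'   [meg_branch_forward()].
#' @param f_mri MRI feature array (x, y, z, C).
#' @param pool_2d,pool_3d Pool output sizes; their products must agree.
#' @param positional Add a learned positional embedding (disabled here for
#'   deterministic token inspection; the model version enables it).
#' @return List with token matrices `meg` and `mri`, each P x C.
#' @export
mmpe <- function(f_meg, f_mri, pool_2d = c(64, 64), pool_3d = c(16, 16, 16),
                 positional = FALSE) {
  if (prod(pool_2d) != prod(pool_3d))
    stop("pool sizes must yield the same token count for both modalities")
  f_meg <- as4d(f_meg)
  ch <- dim(f_meg)[4]
  ma <- nn_mmpe(ch, c(pool_2d, 1), positional = positional)
  mb <- nn_mmpe(dim(f_mri)[4], pool_3d, positional = positional)
  list(meg = ma$forward(f_meg, train = FALSE),
       mri = mb$forward(f_mri, train = FALSE))
}

## ---- SCA -------------------------------------------------------------------

# Cross-modal attention with learned Q/K/V maps (C x C, right-multiplied,
# no bias).  Direction a<-b: Z_a = softmax(Q_b K_a'/sqrt(C)) V_a.
nn_sca <- function(channels, init = "default") {
  mk <- function() {
    if (init == "identity") diag(channels)
    else matrix(stats::rnorm(channels^2, sd = 1 / sqrt(channels)),
                channels, channels)
  }
  m <- new_module("sca", list(wq_a = mk(), wk_a = mk(), wv_a = mk(),
                              wq_b = mk(), wk_b = mk(), wv_b = mk()))
  m$channels <- channels
  m$forward2 <- function(ta, tb, train = TRUE) {
    C <- m$channels; sc <- sqrt(C)
    m$ta <- ta; m$tb <- tb
    m$Qb <- tb %*% m$par$wq_b; m$Ka <- ta %*% m$par$wk_a; m$Va <- ta %*% m$par$wv_a
    m$Qa <- ta %*% m$par$wq_a; m$Kb <- tb %*% m$par$wk_b; m$Vb <- tb %*% m$par$wv_b
    m$Aa <- softmax_rows(tcrossprod(m$Qb, m$Ka) / sc)
    m$Ab <- softmax_rows(tcrossprod(m$Qa, m$Kb) / sc)
    m$macs <- 6 * nrow(ta) * C^2 + 2 * nrow(ta) * nrow(tb) * C * 2
    list(Z_a = m$Aa %*% m$Va, Z_b = m$Ab %*% m$Vb)
  }
  m$backward2 <- function(gZa, gZb) {
    sc <- sqrt(m$channels)
    ga <- attention_backward(gZa, m$Aa, m$Qb, m$Ka, m$Va, sc)
    gb <- attention_backward(gZb, m$Ab, m$Qa, m$Kb, m$Vb, sc)
    m$gr$wq_b <- m$gr$wq_b + crossprod(m$tb, ga$gQ)
    m$gr$wk_a <- m$gr$wk_a + crossprod(m$ta, ga$gK)
    m$gr$wv_a <- m$gr$wv_a + crossprod(m$ta, ga$gV)
    m$gr$wq_a <- m$gr$wq_a + crossprod(m$ta, gb$gQ)
    m$gr$wk_b <- m$gr$wk_b + crossprod(m$tb, gb$gK)
    m$gr$wv_b <- m$gr$wv_b + crossprod(m$tb, gb$gV)
    gta <- ga$gK %*% t(m$par$wk_a) + ga$gV %*% t(m$par$wv_a) +
      gb$gQ %*% t(m$par$wq_a)
    gtb <- ga$gQ %*% t(m$par$wq_b) + gb$gK %*% t(m$par$wk_b) +
      gb$gV %*% t(m$par$wv_b)
    list(gta = gta, gtb = gtb)
  }
  m
}

#' Spatial-wise cross-modal attention (SCA)
#'
#' Queries come from the opposite modality; keys and values from the same
#' modality: `Z_a = softmax(Q_b K_a'/sqrt(C)) V_a` and symmetrically `Z_b`.
#'
#' @param tok_meg,tok_mri P x C token matrices (see [mmpe()]).
#' @param maps `"identity"` uses identity Q/K/V maps (the composition used by
#'   the oracle tests); `"random"` draws fresh learned-map initialisations.
#' @return List with attended matrices `Z_a` (MEG-valued) and `Z_b`
#'   (MRI-valued).
#' @export
sca <- function(tok_meg, tok_mri, maps = c("identity", "random")) {
  maps <- match.arg(maps)
  if (!all(dim(tok_meg) == dim(tok_mri)))
    stop("token matrices must share P and C")
  mod <- nn_sca(ncol(tok_meg),
                init = if (maps == "identity") "identity" else "default")
  mod$forward2(tok_meg, tok_mri, train = FALSE)
}

## ---- CFA -------------------------------------------------------------------

# Token-wise MLP on concat(Z_a, Z_b): 2C -> 2C (ReLU) -> 2C, read as C modality
# logit pairs; pairwise softmax gives w_a, w_b on the 2-simplex.
nn_cfa <- function(channels, hidden = 2 * channels) {
  C <- channels
  m <- new_module("cfa", list(
    w1 = matrix(stats::rnorm(hidden * 2 * C, sd = sqrt(2 / (2 * C))), hidden, 2 * C),
    b1 = numeric(hidden),
    w2 = matrix(stats::rnorm(2 * C * hidden, sd = sqrt(2 / hidden)), 2 * C, hidden),
    b2 = numeric(2 * C)))
  m$channels <- C
  m$forward2 <- function(Za, Zb, ta, tb, train = TRUE) {
    Fc <- cbind(Za, Zb)                       # P x 2C
    H <- Fc %*% t(m$par$w1)
    H <- sweep(H, 2, m$par$b1, `+`)
    Hr <- H * (H > 0)
    L <- Hr %*% t(m$par$w2)
    L <- sweep(L, 2, m$par$b2, `+`)
    la <- L[, seq_len(C), drop = FALSE]
    lb <- L[, C + seq_len(C), drop = FALSE]
    wa <- 1 / (1 + exp(lb - la))              # pairwise softmax
    m$Fc <- Fc; m$H <- H; m$Hr <- Hr; m$wa <- wa; m$ta <- ta; m$tb <- tb
    m$macs <- nrow(Fc) * (ncol(Fc) * nrow(m$par$w1) + ncol(Hr) * nrow(m$par$w2))
    list(fused = wa * ta + (1 - wa) * tb, w_a = wa, w_b = 1 - wa)
  }
  m$backward2 <- function(gf) {
    C <- m$channels
    wa <- m$wa
    gta <- gf * wa
    gtb <- gf * (1 - wa)
    gwa <- gf * (m$ta - m$tb)
    gd <- gwa * wa * (1 - wa)                 # d wa / d(la - lb)
    gL <- cbind(gd, -gd)
    gHr <- gL %*% m$par$w2
    m$gr$w2 <- m$gr$w2 + crossprod(gL, m$Hr)
    m$gr$b2 <- m$gr$b2 + colSums(gL)
    gH <- gHr * (m$H > 0)
    m$gr$w1 <- m$gr$w1 + crossprod(gH, m$Fc)
    m$gr$b1 <- m$gr$b1 + colSums(gH)
    gFc <- gH %*% m$par$w1
    list(gZa = gFc[, seq_len(C), drop = FALSE],
         gZb = gFc[, C + seq_len(C), drop = FALSE],
         gta = gta, gtb = gtb)
  }
  m
}

#' Channel-wise feature aggregation (CFA)
#'
#' Concatenates the two attended token matrices, derives per-token per-channel
#' modality weights through an MLP and a pairwise softmax, and blends the two
#' modalities' tokens: `fused = w_a * tok_meg + w_b * tok_mri` with
#' `w_a + w_b = 1` elementwise.
#'
#' @param Z List with `Z_a` and `Z_b` (output of [sca()]).
#' @param tok_meg,tok_mri The MMPE token matrices being recalibrated.
#' @param mlp Optional `nn_cfa` module (a fresh randomly-initialised one is
#'   created when `NULL`).
#' @return List with `fused`, `w_a`, `w_b`.
#' @export
cfa <- function(Z, tok_meg, tok_mri, mlp = NULL) {
  stopifnot(all(dim(Z$Z_a) == dim(tok_meg)), all(dim(Z$Z_b) == dim(tok_mri)),
            all(dim(tok_meg) == dim(tok_mri)))
  if (is.null(mlp)) mlp <- nn_cfa(ncol(tok_meg))
  mlp$forward2(Z$Z_a, Z$Z_b, tok_meg, tok_mri, train = FALSE)
}

# Full SCCAF module used inside the InterFusion model.
nn_sccaf <- function(channels, pool_2d, pool_3d, positional = TRUE) {
  m <- new_module("sccaf")
  m$mmpe_a <- nn_mmpe(channels, c(pool_2d, 1), positional = positional)
  m$mmpe_b <- nn_mmpe(channels, pool_3d, positional = positional)
  m$sca <- nn_sca(channels)
  m$cfa <- nn_cfa(channels)
  m$mods <- list(m$mmpe_a, m$mmpe_b, m$sca, m$cfa)
  m$n_tokens <- prod(pool_2d)
  m$forward2 <- function(f_meg, f_mri, train = TRUE) {
    ta <- m$mmpe_a$forward(f_meg, train)
    tb <- m$mmpe_b$forward(f_mri, train)
    Z <- m$sca$forward2(ta, tb, train)
    out <- m$cfa$forward2(Z$Z_a, Z$Z_b, ta, tb, train)
    m$last_w_a <- out$w_a
    out$fused
  }
  m$backward2 <- function(gf) {
    g <- m$cfa$backward2(gf)
    gs <- m$sca$backward2(g$gZa, g$gZb)
    list(g_meg = m$mmpe_a$backward(g$gta + gs$gta),
         g_mri = m$mmpe_b$backward(g$gtb + gs$gtb))
  }
  m
}
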