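# Model assembly: unimodal classifiers and the three fusion strategies.
#
# * meg_only / mri_only: one branch + classifier head.
# * early:  both raw inputs downscaled to a shared 2D grid (MEG bilinearly
#   resized; MRI mean-projected along z), concatenated as 2 input channels,
#   then a 2D residual network + head.
# * inter:  both branches + SCCAF cross-attention fusion + one head on the
#   fused token matrix.
# * late:   both branches, one head per modality, and a final linear layer on
#   the concatenated per-modality logits.
#
# Heads are adaptive-pool -> flatten -> linear -> ReLU -> linear.  Pooling the
# feature map to a compact grid (rather than a single global average) keeps
# the per-modality classifiers expressive enough that the parameter ordering
# early < inter < late of the three strategies holds at the default widths.

conv_out <- function(n, k, s, p) (n + 2 * p - k) %/% s + 1

# Feature-map spatial shape produced by a branch for a given input shape.
branch_feature_shape <- function(cfg, in_shape, modality = c("meg", "mri")) {
  modality <- match.arg(modality)
  if (modality == "meg") {
    S <- in_shape[1]; T <- in_shape[2]
    T <- conv_out(T, 15, cfg$meg_stem_stride, 7)
    for (s in cfg$meg_block_strides) T <- conv_out(T, 3, s, 1)
    c(S, T)
  } else {
    d <- in_shape
    d <- vapply(d, conv_out, numeric(1), k = 7, s = cfg$mri_stem_stride, p = 3)
    for (s in cfg$mri_block_strides)
      d <- vapply(d, conv_out, numeric(1), k = 3, s = s, p = 1)
    d
  }
}

largest_pow2_below <- function(n, cap) min(cap, 2^floor(log2(n)))

#' Model configuration
#'
#' Describes one classifier: the fusion strategy, branch configuration, input
#' shapes and SCCAF/head sizes.  Defaults correspond to the full-size inputs
#' (102 x 8192 MEG segments, 192^3 padded volumes): SCCAF pools of (64, 64)
#' and (16, 16, 16) give 4096 tokens per modality.  For smaller inputs the
#' pool sizes are derived automatically so that both modalities always yield
#' the same token count.
#'
#' @param strategy One of `"meg_only"`, `"mri_only"`, `"early"`, `"inter"`,
#'   `"late"`.
#' @param branch A [branch_config()].
#' @param meg_shape (sensors, samples) of the MEG input.
#' @param mri_shape (x, y, z) of the MRI input after padding.
#' @param pool_2d,pool_3d SCCAF pool sizes (`NULL` = derive from shapes).
#' @param head_hidden Hidden width of the classifier heads.
#' @param meg_head_pool,mri_head_pool Adaptive-pool grid flattened into the
#'   unimodal classifier heads (`NULL` = derived from the feature shape).
#' @param fused_head_pool For the intermediate-fusion head: `NULL` flattens
#'   the whole token matrix; a length-3 grid pools the tokens (in their 3D
#'   arrangement) first, shrinking the head for small-sample regimes.
#' @param positional Learned positional embeddings in the MMPE block.
#' @param n_classes Number of classes (binary by default).
#' @return An object of class `nf_model_config`.
#' @export
model_config <- function(strategy = c("inter", "meg_only", "mri_only",
                                      "early", "late"),
                         branch = branch_config(),
                         meg_shape = c(102, 8192),
                         mri_shape = c(192, 192, 192),
                         pool_2d = NULL, pool_3d = NULL,
                         head_hidden = 64, positional = TRUE,
                         meg_head_pool = NULL, mri_head_pool = NULL,
                         fused_head_pool = NULL, n_classes = 2) {
  strategy <- match.arg(strategy)
  meg_feat <- branch_feature_shape(branch, meg_shape, "meg")
  mri_feat <- branch_feature_shape(branch, mri_shape, "mri")
  if (is.null(pool_3d)) pool_3d <- pmin(mri_feat, c(16, 16, 16))
  if (is.null(pool_2d)) {
    P <- prod(pool_3d)
    a <- largest_pow2_below(meg_feat[1], 64)
    b <- P / a
    if (b != floor(b) || b > meg_feat[2])
      stop("cannot derive a 2D pool size matching ", P, " tokens; ",
           "pass pool_2d explicitly")
    pool_2d <- c(a, b)
  }
  if (prod(pool_2d) != prod(pool_3d))
    stop("pool_2d and pool_3d must yield the same token count")
  if (any(pool_2d > meg_feat) || any(pool_3d > mri_feat))
    stop("pool output size exceeds branch feature size")
  if (is.null(meg_head_pool))
    meg_head_pool <- c(meg_feat[1], max(1L, meg_feat[2] %/% 4L))
  if (is.null(mri_head_pool)) mri_head_pool <- pmax(1L, mri_feat %/% 2L)
  cfg <- list(strategy = strategy, branch = branch,
              meg_shape = as.integer(meg_shape),
              mri_shape = as.integer(mri_shape),
              meg_feat = as.integer(meg_feat), mri_feat = as.integer(mri_feat),
              pool_2d = as.integer(pool_2d), pool_3d = as.integer(pool_3d),
              head_hidden = as.integer(head_hidden),
              positional = positional,
              meg_head_pool = as.integer(meg_head_pool),
              mri_head_pool = as.integer(mri_head_pool),
              fused_head_pool = if (!is.null(fused_head_pool))
                as.integer(fused_head_pool),
              n_classes = as.integer(n_classes))
  class(cfg) <- "nf_model_config"
  cfg
}

# Classifier head: optional adaptive pool, flatten, linear-ReLU-linear.
nn_head <- function(in_dim, hidden, n_out, pool = NULL) {
  m <- new_module("head")
  m$pool <- if (!is.null(pool)) nn_apool(pool) else NULL
  m$fc1 <- nn_linear(in_dim, hidden)
  m$act <- nn_relu()
  m$fc2 <- nn_linear(hidden, n_out)
  m$mods <- c(if (!is.null(m$pool)) list(m$pool), list(m$fc1, m$act, m$fc2))
  m$forward <- function(x, train = TRUE) {
    if (!is.null(m$pool)) x <- m$pool$forward(x, train)
    m$in_dim_cache <- dim(x) %||% length(x)
    m$fc2$forward(m$act$forward(m$fc1$forward(as.numeric(x), train), train), train)
  }
  m$backward <- function(gy) {
    g <- m$fc1$backward(m$act$backward(m$fc2$backward(gy)))
    dim(g) <- m$in_dim_cache
    if (!is.null(m$pool)) g <- m$pool$backward(g)
    g
  }
  m
}

# Bilinear resize of a matrix to (ho, wo); used to lift the MEG map onto the
# early-fusion grid.  No parameters sit upstream, so no backward is needed.
resize_bilinear <- function(x, out) {
  hi <- nrow(x); wi <- ncol(x); ho <- out[1]; wo <- out[2]
  ri <- if (ho == 1) rep(1, 1) else (seq_len(ho) - 1) * (hi - 1) / (ho - 1) + 1
  ci <- if (wo == 1) rep(1, 1) else (seq_len(wo) - 1) * (wi - 1) / (wo - 1) + 1
  r0 <- pmin(floor(ri), hi - 1L); r1 <- r0 + 1; fr <- ri - r0
  c0 <- pmin(floor(ci), wi - 1L); c1 <- c0 + 1; fc <- ci - c0
  if (hi == 1) { r0 <- r1 <- rep(1, ho); fr <- rep(0, ho) }
  if (wi == 1) { c0 <- c1 <- rep(1, wo); fc <- rep(0, wo) }
  a <- x[r0, c0, drop = FALSE] * outer(1 - fr, 1 - fc) +
    x[r1, c0, drop = FALSE] * outer(fr, 1 - fc) +
    x[r0, c1, drop = FALSE] * outer(1 - fr, fc) +
    x[r1, c1, drop = FALSE] * outer(fr, fc)
  a
}

#' Build a classification model
#'
#' Assembles the network for the requested fusion strategy.  The returned
#' object is untrained; [nf_train()] builds and fits one in a single call.
#'
#' @param cfg A [model_config()].
#' @param seed Integer seed controlling weight initialisation.
#' @return An object of class `nf_model`.
#' @export
nf_model <- function(cfg = model_config(), seed = 1) {
  stopifnot(inherits(cfg, "nf_model_config"))
  set.seed(as.integer(seed))
  C <- cfg$branch$base_channels
  H <- cfg$head_hidden
  K <- cfg$n_classes
  m <- list(strategy = cfg$strategy, config = cfg, seed = as.integer(seed),
            fitted = FALSE, classes = c("HC", "MCI"))

  if (cfg$strategy %in% c("meg_only", "inter", "late"))
    m$meg_branch <- meg_branch(cfg$branch)
  if (cfg$strategy %in% c("mri_only", "inter", "late"))
    m$mri_branch <- mri_branch(cfg$branch)

  meg_pool <- c(cfg$meg_head_pool, 1L)
  mri_pool <- cfg$mri_head_pool

  if (cfg$strategy == "meg_only") {
    m$head <- nn_head(prod(meg_pool) * C, H, K, pool = meg_pool)
  } else if (cfg$strategy == "mri_only") {
    m$head <- nn_head(prod(mri_pool) * C, H, K, pool = mri_pool)
  } else if (cfg$strategy == "early") {
    G <- min(cfg$mri_shape[1:2])
    m$early_grid <- c(G, G)
    mk <- norm_factory("group")
    mods <- list(nn_conv(2, C, c(7, 7, 1), c(2, 2, 1), pad = c(3, 3, 0)),
                 mk(C), nn_relu())
    for (s in c(2, 2, 1, 1))
      mods <- c(mods, list(nn_resblock(C, C, c(3, 3, 1), c(s, s, 1),
                                       norm = mk)))
    m$early_net <- nn_seq(mods)
    g <- G
    g <- conv_out(g, 7, 2, 3)
    for (s in c(2, 2, 1, 1)) g <- conv_out(g, 3, s, 1)
    m$head <- nn_head(g * g * C, H, K)
  } else if (cfg$strategy == "inter") {
    m$sccaf <- nn_sccaf(C, cfg$pool_2d, cfg$pool_3d,
                        positional = cfg$positional)
    if (is.null(cfg$fused_head_pool)) {
      m$head <- nn_head(prod(cfg$pool_2d) * C, H, K)
    } else {
      m$head <- nn_head(prod(cfg$fused_head_pool) * C, H, K,
                        pool = cfg$fused_head_pool)
    }
  } else if (cfg$strategy == "late") {
    m$head_meg <- nn_head(prod(meg_pool) * C, H, K, pool = meg_pool)
    m$head_mri <- nn_head(prod(mri_pool) * C, H, K, pool = mri_pool)
    m$final <- nn_linear(2 * K, K, init_sd = 0.5)
  }

  m$modules <- collect_modules(m[c("meg_branch", "mri_branch", "early_net",
                                   "sccaf", "head", "head_meg", "head_mri",
                                   "final")])
  class(m) <- "nf_model"
  m
}

# Internal: prepare one sample's tensors for a strategy.
prep_sample <- function(model, meg, mri) {
  st <- model$strategy
  need_meg <- st %in% c("meg_only", "inter", "late", "early")
  need_mri <- st %in% c("mri_only", "inter", "late", "early")
  if (need_meg && is.null(meg)) stop("strategy '", st, "' requires MEG input")
  if (need_mri && is.null(mri)) stop("strategy '", st, "' requires MRI input")
  if (!is.null(meg)) {
    if (inherits(meg, "nf_meg")) meg <- meg$data
    if (!all(dim(meg) == model$config$meg_shape))
      stop("MEG input must have shape ",
           paste(model$config$meg_shape, collapse = " x "), ", got ",
           paste(dim(meg), collapse = " x "))
  }
  if (!is.null(mri)) {
    if (inherits(mri, "nf_mri")) mri <- mri$data
    if (!all(dim(mri) == model$config$mri_shape))
      stop("MRI input must have shape ",
           paste(model$config$mri_shape, collapse = " x "), ", got ",
           paste(dim(mri), collapse = " x "))
  }
  list(meg = meg, mri = mri)
}

#' Forward pass: logits for one subject
#'
#' @param model An `nf_model`.
#' @param meg MEG segment (sensors x time matrix) or `NULL` for `mri_only`.
#' @param mri MRI volume (3D array) or `NULL` for `meg_only`.
#' @param train Keep caches for a subsequent backward pass.
#' @return Numeric vector of `n_classes` logits.
#' @export
nf_forward <- function(model, meg = NULL, mri = NULL, train = FALSE) {
  s <- prep_sample(model, meg, mri)
  st <- model$strategy
  if (st == "meg_only") {
    x <- s$meg; dim(x) <- c(dim(x), 1L, 1L)
    return(model$head$forward(model$meg_branch$forward(x, train), train))
  }
  if (st == "mri_only") {
    x <- s$mri; dim(x) <- c(dim(x), 1L)
    return(model$head$forward(model$mri_branch$forward(x, train), train))
  }
  if (st == "early") {
    G <- model$early_grid
    ch1 <- resize_bilinear(s$meg, G)
    ch2 <- apply(s$mri, c(1, 2), mean)
    if (!all(dim(ch2) == G)) ch2 <- resize_bilinear(ch2, G)
    x <- array(c(ch1, ch2), dim = c(G, 1L, 2L))
    return(model$head$forward(model$early_net$forward(x, train), train))
  }
  xa <- s$meg; dim(xa) <- c(dim(xa), 1L, 1L)
  xb <- s$mri; dim(xb) <- c(dim(xb), 1L)
  fa <- model$meg_branch$forward(xa, train)
  fb <- model$mri_branch$forward(xb, train)
  if (st == "inter") {
    fused <- model$sccaf$forward2(fa, fb, train)
    if (!is.null(model$config$fused_head_pool))
      dim(fused) <- c(model$config$pool_3d,
                      model$config$branch$base_channels)
    return(model$head$forward(fused, train))
  }
  # late
  la <- model$head_meg$forward(fa, train)
  lb <- model$head_mri$forward(fb, train)
  model$final$forward(c(la, lb), train)
}

# Backward from d(loss)/d(logits); accumulates parameter gradients and
# returns gradients w.r.t. the branch inputs where they exist.
nf_backward <- function(model, glogits) {
  st <- model$strategy
  if (st == "meg_only")
    return(model$meg_branch$backward(model$head$backward(glogits)))
  if (st == "mri_only")
    return(model$mri_branch$backward(model$head$backward(glogits)))
  if (st == "early")
    return(model$early_net$backward(model$head$backward(glogits)))
  if (st == "inter") {
    gf <- model$head$backward(glogits)
    dim(gf) <- c(model$sccaf$n_tokens, model$config$branch$base_channels)
    g <- model$sccaf$backward2(gf)
    return(list(g_meg = model$meg_branch$backward(g$g_meg),
                g_mri = model$mri_branch$backward(g$g_mri)))
  }
  gl <- model$final$backward(glogits)
  K <- model$config$n_classes
  list(g_meg = model$meg_branch$backward(model$head_meg$backward(gl[seq_len(K)])),
       g_mri = model$mri_branch$backward(model$head_mri$backward(gl[K + seq_len(K)])))
}

#' Cross-entropy between a predicted and a true distribution
#'
#' `L = sum_x p(x) log(1 / q(x))`, averaged over rows when matrices are given.
#' A uniform two-class prediction against a one-hot truth gives `log(2)`.
#'
#' @param q Predicted class probabilities (vector, or matrix with one row per
#'   sample); must be nonnegative and sum to 1 per sample.
#' @param p True distribution, same shape (one-hot allowed).
#' @param eps Clamp for `q` where `p > 0`; set to 0 to report infinite loss.
#' @return Mean cross-entropy.
#' @export
cross_entropy <- function(q, p, eps = 0) {
  q <- rbind(q); p <- rbind(p)
  stopifnot(all(dim(q) == dim(p)), all(q >= 0),
            all(abs(rowSums(q) - 1) < 1e-6))
  if (eps > 0) q <- pmax(q, eps)
  lq <- ifelse(p > 0, log(q), 0)
  mean(-rowSums(p * lq))
}

softmax_vec <- function(z) { e <- exp(z - max(z)); e / sum(e) }

#' Predicted class probabilities
#'
#' @param object A trained (or at least built) `nf_model`.
#' @param newdata List of subjects, each a list with elements `meg` and/or
#'   `mri`; or an `nf_dataset`.
#' @param type `"prob"` for class probabilities, `"class"` for labels,
#'   `"logits"` for raw scores.
#' @param ... Unused.
#' @return Matrix of probabilities / logits, or a factor of class labels.
#' @export
predict.nf_model <- function(object, newdata, type = c("prob", "class", "logits"),
                             ...) {
  type <- match.arg(type)
  if (inherits(newdata, "nf_dataset")) newdata <- newdata$subjects
  if (!is.null(newdata$meg) || !is.null(newdata$mri)) newdata <- list(newdata)
  out <- t(vapply(newdata, function(s)
    nf_forward(object, s$meg, s$mri, train = FALSE),
    numeric(object$config$n_classes)))
  colnames(out) <- object$classes[seq_len(object$config$n_classes)]
  if (type == "logits") return(out)
  pr <- t(apply(out, 1, softmax_vec))
  colnames(pr) <- colnames(out)
  if (type == "prob") pr
  else factor(object$classes[max.col(pr)], levels = object$classes)
}

#' @export
print.nf_model <- function(x, ...) {
  cat("<nf_model> strategy:", x$strategy,
      if (x$fitted) "(fitted)" else "(untrained)", "\n")
  cat("  inputs: MEG", paste(x$config$meg_shape, collapse = "x"),
      "| MRI", paste(x$config$mri_shape, collapse = "x"), "\n")
  cat("  channels:", x$config$branch$base_channels,
      "| parameters:", format(count_params(x), big.mark = ","), "\n")
  if (x$fitted)
    cat("  final epoch mean loss:",
        format(utils::tail(x$loss_trace, 1), digits = 4), "\n")
  invisible(x)
}

#' @export
summary.nf_model <- function(object, ...) {
  counts <- vapply(object$modules,
                   function(m) sum(vapply(m$par, length, 1L)), 1)
  kinds <- vapply(object$modules, function(m) m$kind, "")
  tab <- tapply(counts, kinds, sum)
  out <- list(strategy = object$strategy, params = count_params(object),
              by_kind = tab, fitted = object$fitted,
              loss_trace = object$loss_trace)
  class(out) <- "summary.nf_model"
  out
}

#' @export
print.summary.nf_model <- function(x, ...) {
  cat("Strategy:", x$strategy, "\nTotal parameters:",
      format(x$params, big.mark = ","), "\n\nParameters by layer kind:\n")
  print(x$by_kind)
  if (x$fitted) cat("\nEpochs trained:", length(x$loss_trace), "\n")
  invisible(x)
}

#' @export
coef.nf_model <- function(object, ...) {
  stats::setNames(lapply(object$modules, function(m) m$par),
                  vapply(object$modules, function(m) m$kind, ""))
}

#' @export
plot.nf_model <- function(x, ...) {
  if (!x$fitted || is.null(x$loss_trace))
    stop("model has no training trace to plot")
  graphics::plot(seq_along(x$loss_trace), x$loss_trace, type = "b",
                 xlab = "epoch", ylab = "mean training loss",
                 main = paste("Training loss:", x$strategy), ...)
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single-file archive holding the configuration, seed and
#' all parameter arrays; `nf_load_model()` rebuilds the architecture and
#' restores the weights.
#'
#' @param model An `nf_model`.
#' @param path File path.
#' @return `nf_load_model()` returns the restored `nf_model`.
#' @export
nf_save_model <- function(model, path) {
  saveRDS(list(config = model$config, seed = model$seed,
               fitted = model$fitted, loss_trace = model$loss_trace,
               pars = lapply(model$modules, function(m) m$par)),
          path)
  invisible(path)
}

#' @rdname nf_save_model
#' @export
nf_load_model <- function(path) {
  ck <- readRDS(path)
  model <- nf_model(ck$config, seed = ck$seed)
  stopifnot(length(model$modules) == length(ck$pars))
  for (i in seq_along(ck$pars)) model$modules[[i]]$par <- ck$pars[[i]]
  model$fitted <- ck$fitted
  model$loss_trace <- ck$loss_trace
  model
}
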