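# Independent oracles used across the suite.  Each is a deliberately naive
# implementation (direct loops / closed forms), kept separate from the code
# paths it checks.

# Direct-loop N-d convolution (channels-last, column-major).
oracle_conv <- function(x, w, b, stride, pad) {
  xd <- dim(x); kd <- dim(w)[1:3]; ci <- dim(w)[4]; co <- dim(w)[5]
  od <- (xd[1:3] + 2 * pad - kd) %/% stride + 1
  y <- array(0, c(od, co))
  for (oc in 1:co) for (zo in 1:od[3]) for (yo in 1:od[2]) for (xo in 1:od[1]) {
    acc <- b[oc]
    for (c in 1:ci) for (kz in 1:kd[3]) for (ky in 1:kd[2]) for (kx in 1:kd[1]) {
      xi <- (xo - 1) * stride[1] - pad[1] + kx
      yi <- (yo - 1) * stride[2] - pad[2] + ky
      zi <- (zo - 1) * stride[3] - pad[3] + kz
      if (xi >= 1 && xi <= xd[1] && yi >= 1 && yi <= xd[2] &&
          zi >= 1 && zi <= xd[3])
        acc <- acc + x[xi, yi, zi, c] * w[kx, ky, kz, c, oc]
    }
    y[xo, yo, zo, oc] <- acc
  }
  y
}

# Brute-force softmax-weighted sum, row by row.
oracle_attention <- function(Q, K, V, scale = sqrt(ncol(Q))) {
  Z <- matrix(0, nrow(Q), ncol(V))
  for (i in seq_len(nrow(Q))) {
    s <- numeric(nrow(K))
    for (j in seq_len(nrow(K))) s[j] <- sum(Q[i, ] * K[j, ]) / scale
    w <- exp(s - max(s)); w <- w / sum(w)
    for (j in seq_len(nrow(K))) Z[i, ] <- Z[i, ] + w[j] * V[j, ]
  }
  Z
}

# Metric formulas evaluated independently, straight from their definitions.
oracle_metrics <- function(tp, tn, fp, fn) {
  acc <- (tp + tn) / (tp + tn + fp + fn)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  spec <- if (tn + fp > 0) tn / (tn + fp) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den > 0) (tp * tn - fp * fn) / den else 0
  list(acc = acc, precision = prec, recall = rec, f1 = f1,
       sensitivity = rec, specificity = spec, mcc = mcc)
}

# AUC as the concordant-pair fraction (ties count one half).
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Mean Welch-style band power of a sensor matrix (rectangular-window
# periodogram on the full segment -- deliberately different from the
# package's Hann/segment estimator).
oracle_band_power <- function(x, fs, lo, hi) {
  N <- ncol(x)
  freqs <- seq(0, N - 1) * fs / N
  sel <- freqs >= lo & freqs <= hi & freqs <= fs / 2
  mean(apply(x, 1, function(s) mean(Mod(stats::fft(s))[sel]^2 / N)))
}

# Gradient-check a model's accumulated parameter gradients against central
# finite differences on a sampled set of parameters.
check_model_gradients <- function(model, meg, mri, n_checks = 6, eps = 1e-5) {
  nf <- asNamespace("neurofuse")
  lossf <- function() {
    lg <- nf_forward(model, meg, mri, train = TRUE)
    p <- nf$softmax_vec(lg)
    -log(p[2])
  }
  nf$zero_grad(model$modules)
  lg <- nf_forward(model, meg, mri, train = TRUE)
  p <- nf$softmax_vec(lg)
  nf$nf_backward(model, p - c(0, 1))
  mods <- Filter(function(m) length(m$par) > 0, model$modules)
  errs <- numeric(0)
  for (m in sample(mods, min(n_checks, length(mods)))) {
    nm <- sample(names(m$par), 1)
    i <- sample(length(m$par[[nm]]), 1)
    orig <- m$par[[nm]][i]
    m$par[[nm]][i] <- orig + eps; lp <- lossf()
    m$par[[nm]][i] <- orig - eps; lm <- lossf()
    m$par[[nm]][i] <- orig
    fd <- (lp - lm) / (2 * eps)
    an <- m$gr[[nm]][i]
    errs <- c(errs, abs(fd - an) / max(1e-4, abs(fd), abs(an)))
  }
  max(errs)
}

tiny_model_config <- function(strategy) {
  model_config(strategy,
               branch = branch_config(base_channels = 3,
                                      meg_block_strides = c(2, 1, 1, 1),
                                      mri_block_strides = c(2, 1, 1, 1)),
               meg_shape = c(6, 64), mri_shape = c(12, 12, 12),
               pool_2d = c(3, 9), pool_3d = c(3, 3, 3), head_hidden = 5)
}
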