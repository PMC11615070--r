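# Compact CPU neural-network engine.
#
# Every layer is an environment ("nf_module") holding named parameter arrays
# (`par`), matching gradient accumulators (`gr`), a `forward(x, train)` and a
# `backward(gy)` closure, and a MAC counter updated on each forward pass.
# Feature arrays are column-major with spatial axes first and the channel axis
# last: MEG maps are (sensors, time, 1, C), MRI maps are (x, y, z, C).
# Batches are processed sample-by-sample (gradients accumulate across calls),
# which keeps instance normalisation and attention strictly per-sample.

new_module <- function(kind, par = list()) {
  e <- new.env(parent = emptyenv())
  e$kind <- kind
  e$par <- par
  e$gr <- lapply(par, function(p) array(0, dim = dim(p) %||% length(p)))
  e$macs <- 0
  class(e) <- "nf_module"
  e
}

`%||%` <- function(a, b) if (is.null(a)) b else a

zero_grad <- function(mods) {
  for (m in mods) for (nm in names(m$gr)) m$gr[[nm]][] <- 0
  invisible(NULL)
}

#' @noRd
rand_normal <- function(n, sd) array(stats::rnorm(n, sd = sd), dim = n)

as4d <- function(x) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  dim(x) <- c(d, rep(1L, 4 - length(d)))
  x
}

## ---- convolution -----------------------------------------------------------

# kernel, stride, pad: length-3 integer vectors (use 1s for unused axes)
nn_conv <- function(in_ch, out_ch, kernel, stride = c(1, 1, 1),
                    pad = (kernel - 1L) %/% 2L) {
  kernel <- as.integer(kernel); stride <- as.integer(stride); pad <- as.integer(pad)
  fan_in <- prod(kernel) * in_ch
  w <- array(stats::rnorm(prod(kernel) * in_ch * out_ch, sd = sqrt(2 / fan_in)),
             dim = c(kernel, in_ch, out_ch))
  m <- new_module("conv", list(w = w, b = numeric(out_ch)))
  m$meta <- list(in_ch = in_ch, out_ch = out_ch, kernel = kernel,
                 stride = stride, pad = pad)
  m$forward <- function(x, train = TRUE) {
    x <- as4d(x)
    stopifnot(dim(x)[4] == in_ch)
    m$x <- if (train) x else NULL
    m$xdim <- dim(x)
    fwd <- if (isTRUE(getOption("neurofuse.fp32"))) nf_conv_fwd_f else
      nf_conv_fwd
    y <- fwd(x, dim(x)[1:3], m$par$w, kernel, in_ch, out_ch,
             m$par$b, stride, pad)
    m$macs <- prod(dim(y)) * prod(kernel) * in_ch
    y
  }
  m$backward <- function(gy) {
    bwd <- if (isTRUE(getOption("neurofuse.fp32"))) nf_conv_bwd_f else
      nf_conv_bwd
    g <- bwd(m$x, m$xdim[1:3], m$par$w, kernel, in_ch, out_ch,
             gy, stride, pad)
    m$gr$w <- m$gr$w + g$gw
    m$gr$b <- m$gr$b + g$gb
    g$gx
  }
  m
}

## ---- normalisation ---------------------------------------------------------

# Per-sample normalisation with per-channel affine terms.
# groups = ch, center = TRUE  -> standard instance norm.
# groups < ch, center = TRUE  -> per-channel centring with the group-pooled
#   SD as a shared scale.
# center = FALSE              -> RMS normalisation: division by the
#   group-pooled root-mean-square with no mean subtraction.  This is the
#   variant that preserves per-channel map means *and* relative channel
#   amplitudes -- both statistics carry band-power information in
#   band-limited sensor data, and mean-centring provably erases the global
#   component of the class signal there.
nn_norm <- function(ch, groups = ch, center = TRUE, eps = 1e-5) {
  stopifnot(ch %% groups == 0)
  gsize <- ch %/% groups
  gidx <- rep(seq_len(groups), each = gsize)
  m <- new_module(if (groups == ch && center) "inorm"
                  else if (center) "gnorm" else "rmsnorm",
                  list(g = rep(1, ch), b = rep(0, ch)))
  m$forward <- function(x, train = TRUE) {
    d <- dim(x); nv <- prod(d[-length(d)])
    xm <- matrix(x, nv, ch)
    if (center) {
      mu <- colMeans(xm)
      xc <- xm - rep(mu, each = nv)
    } else xc <- xm
    vch <- colMeans(xc^2)
    s <- numeric(groups)
    xh <- xc
    for (gg in seq_len(groups)) {
      cols <- which(gidx == gg)
      s[gg] <- sqrt(mean(vch[cols]) + eps)
      xh[, cols] <- xc[, cols, drop = FALSE] / s[gg]
    }
    m$xh <- xh; m$s <- s; m$d <- d
    y <- xh * rep(m$par$g, each = nv) + rep(m$par$b, each = nv)
    dim(y) <- d
    y
  }
  m$backward <- function(gy) {
    d <- m$d; nv <- prod(d[-length(d)])
    gym <- matrix(gy, nv, ch)
    m$gr$g <- m$gr$g + colSums(gym * m$xh)
    m$gr$b <- m$gr$b + colSums(gym)
    gxh <- gym * rep(m$par$g, each = nv)
    gx <- gxh
    for (gg in seq_len(groups)) {
      cols <- which(gidx == gg)
      blk <- gxh[, cols, drop = FALSE]
      xhb <- m$xh[, cols, drop = FALSE]
      gc <- if (center) blk - rep(colMeans(blk), each = nv) else blk
      gx[, cols] <- (gc - xhb * mean(blk * xhb)) / m$s[gg]
    }
    dim(gx) <- d
    gx
  }
  m
}

nn_inorm <- function(ch, eps = 1e-5) nn_norm(ch, groups = ch, eps = eps)

## ---- elementwise and dense layers -----------------------------------------

nn_relu <- function() {
  m <- new_module("relu")
  m$forward <- function(x, train = TRUE) { m$mask <- x > 0; x * m$mask }
  m$backward <- function(gy) gy * m$mask
  m
}

nn_linear <- function(in_f, out_f, init_sd = sqrt(2 / in_f)) {
  m <- new_module("linear",
                  list(w = matrix(stats::rnorm(out_f * in_f, sd = init_sd),
                                  out_f, in_f),
                       b = numeric(out_f)))
  m$meta <- list(in_f = in_f, out_f = out_f)
  m$forward <- function(x, train = TRUE) {
    x <- as.numeric(x)
    stopifnot(length(x) == in_f)
    m$x <- x
    m$macs <- out_f * in_f
    drop(m$par$w %*% x) + m$par$b
  }
  m$backward <- function(gy) {
    gy <- as.numeric(gy)
    m$gr$w <- m$gr$w + tcrossprod(gy, m$x)
    m$gr$b <- m$gr$b + gy
    drop(crossprod(m$par$w, gy))
  }
  m
}

## ---- adaptive average pooling ---------------------------------------------

# Pools each spatial axis to `out_size` (length-3) with the standard adaptive
# rule: window for output i on an axis of length n is
# [floor(i*n/o), ceil((i+1)*n/o)).  Channels are preserved.
nn_apool <- function(out_size) {
  out_size <- as.integer(out_size)
  m <- new_module("apool")
  m$out_size <- out_size
  m$forward <- function(x, train = TRUE) {
    x <- as4d(x)
    d <- dim(x); ch <- d[4]
    if (any(out_size > d[1:3]))
      stop("adaptive pool output size exceeds input size")
    key <- paste(d, collapse = "x")
    if (is.null(m$key) || m$key != key) {
      ax <- lapply(1:3, function(a) {
        n <- d[a]; o <- out_size[a]
        lapply(seq_len(o) - 1L, function(i)
          seq.int(floor(i * n / o) + 1L, ceiling((i + 1) * n / o)))
      })
      P <- prod(out_size)
      idx <- vector("list", P)
      grid <- expand.grid(i = seq_len(out_size[1]), j = seq_len(out_size[2]),
                          k = seq_len(out_size[3]))
      for (p in seq_len(P)) {
        ii <- ax[[1]][[grid$i[p]]]; jj <- ax[[2]][[grid$j[p]]]
        kk <- ax[[3]][[grid$k[p]]]
        lin <- outer(ii, (jj - 1L) * d[1], `+`)
        lin <- outer(as.vector(lin), (kk - 1L) * d[1] * d[2], `+`)
        idx[[p]] <- as.vector(lin)
      }
      m$idx <- idx; m$key <- key; m$dkey <- d
      # fast path when the windows partition the input (no overlaps): a
      # grouping vector lets rowsum() do the whole pool in one call
      nv <- prod(d[1:3])
      grp <- integer(nv); cnt <- lengths(idx)
      grp[unlist(idx)] <- rep(seq_along(idx), cnt)
      m$partition <- sum(cnt) == nv && !anyDuplicated(unlist(idx))
      if (m$partition) { m$grp <- grp; m$cnt <- cnt }
    }
    nv <- prod(d[1:3])
    xm <- matrix(x, nv, ch)
    P <- length(m$idx)
    if (m$partition) {
      y <- rowsum(xm, m$grp, reorder = TRUE) / m$cnt
    } else {
      y <- matrix(0, P, ch)
      for (p in seq_len(P)) {
        ii <- m$idx[[p]]
        y[p, ] <- if (length(ii) == 1L) xm[ii, ] else
          colMeans(xm[ii, , drop = FALSE])
      }
    }
    dim(y) <- c(out_size, ch)
    y
  }
  m$backward <- function(gy) {
    d <- m$dkey; ch <- d[4]; nv <- prod(d[1:3])
    gym <- matrix(gy, length(m$idx), ch)
    if (m$partition) {
      gx <- (gym / m$cnt)[m$grp, , drop = FALSE]
    } else {
      gx <- matrix(0, nv, ch)
      for (p in seq_along(m$idx)) {
        ii <- m$idx[[p]]
        gx[ii, ] <- gx[ii, ] + rep(gym[p, ] / length(ii), each = length(ii))
      }
    }
    dim(gx) <- d
    gx
  }
  m
}

## ---- composition -----------------------------------------------------------

nn_seq <- function(...) {
  mods <- list(...)
  if (length(mods) == 1L && is.list(mods[[1]]) &&
      !inherits(mods[[1]], "nf_module")) mods <- mods[[1]]
  m <- new_module("seq")
  m$mods <- mods
  m$forward <- function(x, train = TRUE) {
    for (mm in mods) x <- mm$forward(x, train)
    x
  }
  m$backward <- function(gy) {
    for (mm in rev(mods)) gy <- mm$backward(gy)
    gy
  }
  m
}

# Residual block: conv-norm-relu-conv-norm plus a (projected) shortcut,
# followed by ReLU.  `stride` applies to the first convolution and shortcut.
nn_resblock <- function(in_ch, out_ch, kernel, stride = c(1, 1, 1),
                        norm = nn_inorm) {
  main <- list(nn_conv(in_ch, out_ch, kernel, stride),
               norm(out_ch), nn_relu(),
               nn_conv(out_ch, out_ch, kernel), norm(out_ch))
  proj <- NULL
  if (any(stride != 1L) || in_ch != out_ch)
    proj <- list(nn_conv(in_ch, out_ch, c(1, 1, 1), stride, pad = c(0, 0, 0)),
                 norm(out_ch))
  m <- new_module("resblock")
  m$mods <- c(main, proj)
  m$main <- main; m$proj <- proj
  m$forward <- function(x, train = TRUE) {
    h <- x
    for (mm in main) h <- mm$forward(h, train)
    s <- x
    if (!is.null(proj)) for (mm in proj) s <- mm$forward(s, train)
    y <- h + s
    m$mask <- y > 0
    y * m$mask
  }
  m$backward <- function(gy) {
    gy <- gy * m$mask
    gh <- gy
    for (mm in rev(main)) gh <- mm$backward(gh)
    gs <- gy
    if (!is.null(proj)) for (mm in rev(proj)) gs <- mm$backward(gs)
    gh + gs
  }
  m
}

# Flatten every nf_module reachable from a model part (seq / resblock nesting).
collect_modules <- function(x) {
  if (inherits(x, "nf_module")) {
    kids <- if (!is.null(x$mods)) unlist(lapply(x$mods, collect_modules)) else NULL
    c(list(x), kids)
  } else if (is.list(x)) {
    unlist(lapply(x, collect_modules))
  } else NULL
}

## ---- optimiser -------------------------------------------------------------

# Adam with L2 weight decay folded into the gradient (the convention used by
# common deep-learning defaults).  State lives on each module.
adam_step <- function(mods, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  for (m in mods) {
    if (length(m$par) == 0L) next
    if (is.null(m$opt)) {
      m$opt <- list(t = 0,
                    m1 = lapply(m$par, function(p) p * 0),
                    m2 = lapply(m$par, function(p) p * 0))
    }
    m$opt$t <- m$opt$t + 1
    t <- m$opt$t
    for (nm in names(m$par)) {
      g <- m$gr[[nm]]
      if (weight_decay > 0) g <- g + weight_decay * m$par[[nm]]
      m$opt$m1[[nm]] <- beta1 * m$opt$m1[[nm]] + (1 - beta1) * g
      m$opt$m2[[nm]] <- beta2 * m$opt$m2[[nm]] + (1 - beta2) * g^2
      mhat <- m$opt$m1[[nm]] / (1 - beta1^t)
      vhat <- m$opt$m2[[nm]] / (1 - beta2^t)
      m$par[[nm]] <- m$par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  invisible(NULL)
}
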