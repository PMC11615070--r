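# Training protocol and evaluation: Adam, batch accumulation, stratified
# 5-fold cross-validation, and the strategy-comparison experiment.

#' Training configuration
#'
#' Defaults follow the study protocol: Adam, learning rate 0.001, batch size
#' 2, weight decay 0.0001, 100 epochs, 5 folds.  Reduced-scale experiments
#' override `epochs` and `batch_size` only.
#'
#' @param lr Learning rate.
#' @param batch_size Gradient-accumulation batch size.
#' @param weight_decay L2 weight decay folded into the Adam gradient.
#' @param epochs Number of epochs.
#' @param folds Cross-validation folds.
#' @param seed Integer seed controlling splits, init and data order.
#' @param optimizer Only `"adam"` is implemented.
#' @param clip_norm Global gradient-norm clip (0 disables).
#' @param augment_shift Apply a random circular time shift to each MEG
#'   segment at every presentation.  The shift preserves the spectrum of a
#'   stationary segment exactly while breaking sample identity, which pushes
#'   the network towards spectral features instead of memorisation.
#' @param augment_mri_shift Maximum circular shift (voxels, per axis) applied
#'   to each volume at every presentation; 0 disables.  For stationary
#'   (periodic) fields the shift is distribution-preserving and spatial
#'   effects move by at most this many voxels.
#' @return An object of class `nf_train_config`.
#' @export
train_config <- function(lr = 0.001, batch_size = 2, weight_decay = 0.0001,
                         epochs = 100, folds = 5, seed = 1,
                         optimizer = "adam", clip_norm = 5,
                         augment_shift = TRUE, augment_mri_shift = 0) {
  stopifnot(lr >= 0, batch_size >= 1, weight_decay >= 0, epochs >= 0,
            folds >= 2, clip_norm >= 0, augment_mri_shift >= 0)
  optimizer <- match.arg(optimizer, "adam")
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 weight_decay = weight_decay, epochs = as.integer(epochs),
                 folds = as.integer(folds), seed = as.integer(seed),
                 optimizer = optimizer, clip_norm = clip_norm,
                 augment_shift = isTRUE(augment_shift),
                 augment_mri_shift = as.integer(augment_mri_shift)),
            class = "nf_train_config")
}

# Clip the accumulated gradients to a global L2 norm.
clip_gradients <- function(mods, max_norm) {
  if (max_norm <= 0) return(invisible(NULL))
  tot <- sqrt(sum(vapply(mods, function(m)
    sum(vapply(m$gr, function(g) sum(g^2), 0)), 0)))
  if (is.finite(tot) && tot > max_norm) {
    sc <- max_norm / tot
    for (m in mods) for (nm in names(m$gr)) m$gr[[nm]] <- m$gr[[nm]] * sc
  }
  invisible(NULL)
}

#' Stratified k-fold split
#'
#' Subjects are shuffled within each stratum and dealt round-robin, so folds
#' are disjoint, exhaustive, and per-stratum fold sizes differ by at most one.
#'
#' @param table An `nf_cohort` (or any data.frame with `id` and the
#'   stratification columns).
#' @param k Number of folds.
#' @param seed Integer seed.
#' @param stratify_by Column names defining strata (default `"group"`).
#' @return List of `k` lists with `train_ids` and `val_ids`.
#' @export
kfold_split <- function(table, k = 5, seed = 1, stratify_by = "group") {
  stopifnot(k >= 2)
  strata <- interaction(table[stratify_by], drop = TRUE)
  sizes <- table(strata)
  if (any(sizes < k))
    stop("stratum '", names(sizes)[which.min(sizes)], "' has ",
         min(sizes), " members, fewer than k = ", k)
  set.seed(as.integer(seed))
  fold_of <- integer(nrow(table))
  for (s in levels(strata)) {
    idx <- sample(which(strata == s))
    fold_of[idx] <- rep_len(seq_len(k), length(idx))
  }
  lapply(seq_len(k), function(f)
    list(train_ids = table$id[fold_of != f], val_ids = table$id[fold_of == f]))
}

# Input standardisation: MEG sensors are z-scored row-wise (each sensor to
# mean 0 / SD 1), which removes per-sensor gain differences exactly and
# leaves each sensor's spectral shape; volumes are z-scored globally.
standardize_sample <- function(s) {
  if (!is.null(s$meg)) {
    mu <- rowMeans(s$meg)
    sd_ <- sqrt(rowMeans((s$meg - mu)^2))
    sd_[sd_ == 0] <- 1
    s$meg <- (s$meg - mu) / sd_
  }
  if (!is.null(s$mri)) s$mri <- nf_normalize(s$mri)
  s
}

#' Train a classification model
#'
#' The single fitting entry point: builds the network for `strategy` (unless
#' an existing `nf_model` is passed), then optimises the softmax
#' cross-entropy with Adam over `cfg$epochs` epochs, accumulating gradients
#' over `cfg$batch_size` subjects per step.  Inputs are z-scored per sample.
#' Deterministic given `cfg$seed` on a fixed machine and thread count.
#'
#' @param data An `nf_dataset` (see [generate_dataset()] /
#'   [read_dataset_dir()]), or a list of subjects, each a list with `meg`,
#'   `mri` and `label` ("HC"/"MCI" or 0/1).
#' @param strategy Fusion strategy, or an already-built `nf_model`.
#' @param model_cfg A [model_config()]; shapes must match the data.
#' @param cfg A [train_config()].
#' @param verbose Print a per-epoch loss line.
#' @return A fitted `nf_model` with a `loss_trace` field (mean epoch loss).
#' @export
nf_train <- function(data, strategy = "inter", model_cfg = NULL,
                     cfg = train_config(), verbose = FALSE) {
  subjects <- if (inherits(data, "nf_dataset")) data$subjects else data
  if (length(subjects) == 0) stop("no training subjects supplied")
  labels <- vapply(subjects, function(s) as_label01(s$label), 0L)
  if (inherits(strategy, "nf_model")) {
    model <- strategy
  } else {
    if (is.null(model_cfg)) {
      mshape <- dim(subjects[[1]]$meg)
      vshape <- dim(subjects[[1]]$mri)
      model_cfg <- model_config(strategy, meg_shape = mshape,
                                mri_shape = vshape)
    }
    model <- nf_model(model_cfg, seed = cfg$seed)
  }
  subjects <- lapply(subjects, standardize_sample)
  # training runs convolutions in single precision: round-off (~1e-7
  # relative) is orders of magnitude below gradient noise
  old_fp <- options(neurofuse.fp32 = TRUE)
  on.exit(options(old_fp), add = TRUE)
  n <- length(subjects)
  K <- model$config$n_classes
  set.seed(cfg$seed + 1L)
  trace <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0)
    i <- 1
    while (i <= n) {
      idx <- ord[i:min(n, i + cfg$batch_size - 1)]
      zero_grad(model$modules)
      bl <- 0
      for (j in idx) {
        s <- subjects[[j]]
        if (isTRUE(cfg$augment_shift) && !is.null(s$meg)) {
          sh <- sample.int(ncol(s$meg), 1)
          if (sh < ncol(s$meg))
            s$meg <- s$meg[, c((sh + 1):ncol(s$meg), 1:sh), drop = FALSE]
        }
        k <- cfg$augment_mri_shift %||% 0L
        if (k > 0 && !is.null(s$mri)) {
          d <- dim(s$mri)
          sh <- sample(seq(-k, k), 3, replace = TRUE)
          idx <- lapply(1:3, function(a)
            ((seq_len(d[a]) - 1 + sh[a]) %% d[a]) + 1)
          s$mri <- s$mri[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
        }
        logit <- nf_forward(model, s$meg, s$mri, train = TRUE)
        pr <- softmax_vec(logit)
        y <- numeric(K); y[labels[j] + 1] <- 1
        bl <- bl + cross_entropy(pr, y, eps = 1e-12)
        nf_backward(model, (pr - y) / length(idx))
      }
      if (cfg$lr > 0) {
        clip_gradients(model$modules, cfg$clip_norm %||% 0)
        adam_step(model$modules, lr = cfg$lr,
                  weight_decay = cfg$weight_decay)
      }
      losses <- c(losses, bl / length(idx))
      i <- i + cfg$batch_size
    }
    trace[ep] <- mean(losses)
    if (verbose)
      message(sprintf("epoch %3d/%d  mean loss %.4f", ep, cfg$epochs,
                      trace[ep]))
  }
  model$fitted <- TRUE
  model$loss_trace <- trace
  model
}

as_label01 <- function(l) {
  if (is.numeric(l)) return(as.integer(l != 0))
  if (is.factor(l)) l <- as.character(l)
  if (l %in% c("MCI", "1", "TRUE")) 1L else 0L
}

# MCI-class softmax probability for a list of subjects.
mci_scores <- function(model, subjects) {
  vapply(subjects, function(s) {
    s <- standardize_sample(s)
    softmax_vec(nf_forward(model, s$meg, s$mri, train = FALSE))[2]
  }, 0)
}

#' Cross-validated evaluation of one strategy
#'
#' Trains one model per fold and evaluates on the held-out subjects; scores
#' are the MCI-class softmax probabilities.
#'
#' @inheritParams nf_train
#' @param folds Optional precomputed [kfold_split()] result (shared across
#'   strategies for paired comparisons).
#' @return List of per-fold results (`fold_index`, `metrics`, `val_ids`,
#'   `scores`, `labels`) of class `nf_cv`.
#' @export
nf_cross_validate <- function(data, strategy = "inter", model_cfg = NULL,
                              cfg = train_config(), folds = NULL,
                              verbose = FALSE) {
  stopifnot(inherits(data, "nf_dataset"))
  if (is.null(folds))
    folds <- kfold_split(data$cohort, k = cfg$folds, seed = cfg$seed)
  ids <- vapply(data$subjects, function(s) s$id, "")
  res <- lapply(seq_along(folds), function(f) {
    tr <- data$subjects[ids %in% folds[[f]]$train_ids]
    va <- data$subjects[ids %in% folds[[f]]$val_ids]
    model <- nf_train(tr, strategy, model_cfg,
                      cfg = modify_cfg(cfg, seed = cfg$seed + f),
                      verbose = verbose)
    sc <- mci_scores(model, va)
    lab <- vapply(va, function(s) as_label01(s$label), 0L)
    met <- tryCatch(score_metrics(sc, lab),
                    warning = function(w) suppressWarnings(score_metrics(sc, lab)))
    list(fold_index = f, metrics = met,
         val_ids = vapply(va, function(s) s$id, ""),
         scores = sc, labels = lab)
  })
  structure(res, class = "nf_cv")
}

modify_cfg <- function(cfg, ...) {
  up <- list(...)
  for (nm in names(up)) cfg[[nm]] <- up[[nm]]
  cfg
}

#' Fold-averaged metrics
#'
#' @param cv An `nf_cv` from [nf_cross_validate()].
#' @return Named numeric vector of mean metrics across folds.
#' @export
cv_mean_metrics <- function(cv) {
  nm <- c("acc", "f1", "sensitivity", "specificity", "mcc", "auc", "ap")
  out <- vapply(nm, function(k)
    mean(vapply(cv, function(f) f$metrics[[k]] %||% NA_real_, 0)), 0)
  out
}

#' Compare fusion strategies under identical folds
#'
#' Trains every strategy on the same stratified folds and seed, averages the
#' validation metrics, and reports paired Bonferroni-adjusted t tests of each
#' strategy's fold-wise accuracies against the best strategy.
#'
#' @param strategies Character vector of strategies.
#' @param data An `nf_dataset`.
#' @param cfg A [train_config()].
#' @param model_cfgs Optional named list of [model_config()] per strategy.
#' @param verbose Print progress.
#' @return List with `table` (one row per strategy: accuracy, f1,
#'   sensitivity, specificity, mcc, p_adjusted vs best) and `cv` (per-strategy
#'   fold results).
#' @export
run_experiment <- function(strategies, data, cfg = train_config(),
                           model_cfgs = NULL, verbose = FALSE) {
  stopifnot(inherits(data, "nf_dataset"))
  folds <- kfold_split(data$cohort, k = cfg$folds, seed = cfg$seed)
  cvs <- lapply(strategies, function(st) {
    if (verbose) message("strategy: ", st)
    nf_cross_validate(data, st, model_cfgs[[st]], cfg = cfg, folds = folds,
                      verbose = verbose)
  })
  names(cvs) <- make.unique(strategies)
  mm <- t(vapply(cvs, cv_mean_metrics, numeric(7)))
  accs <- lapply(cvs, function(cv) vapply(cv, function(f) f$metrics$acc, 0))
  best <- which.max(mm[, "acc"])
  m <- max(1, length(strategies) - 1)
  padj <- vapply(seq_along(cvs), function(i) {
    if (i == best) return(NA_real_)
    paired_ttest_bonferroni(accs[[best]], accs[[i]], m = m)$p_adjusted
  }, 0)
  tab <- data.frame(strategy = strategies,
                    accuracy = mm[, "acc"], f1 = mm[, "f1"],
                    sensitivity = mm[, "sensitivity"],
                    specificity = mm[, "specificity"], mcc = mm[, "mcc"],
                    auc = mm[, "auc"], ap = mm[, "ap"],
                    p_adjusted_vs_best = padj,
                    row.names = NULL)
  list(table = tab, cv = cvs, best = strategies[best])
}
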