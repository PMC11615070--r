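# Modality-specific feature extraction branches.
#
# The MEG branch consumes a (sensors x time) map with one input channel.  Its
# stem is a (1, 15) strip convolution along time applied per sensor row,
# followed by a (3, 3) convolution mixing adjacent sensor rows.  Residual
# blocks then downsample the time axis only, so 102 sensors are preserved and
# 8192 samples reduce to 128 (total factor 64).
#
# The MRI branch consumes a 3D volume with one input channel.  Its stem is a
# 7x7x7 convolution (stride 2) with instance normalisation; residual blocks
# downsample isotropically for a total factor of 8 (192 -> 24).

#' Branch configuration
#'
#' Describes one modality-specific feature extraction branch: the number of
#' feature channels, the number of residual blocks, and the per-stage
#' downsampling factors.  The defaults give the full-size contract: MEG input
#' (102, 8192) maps to features (C, 102, 128) and MRI input (192, 192, 192)
#' maps to (C, 24, 24, 24).
#'
#' @param base_channels Feature channel count C (default 16).
#' @param n_blocks Number of residual blocks per branch (default 4).
#' @param meg_stem_stride Time-axis stride of the MEG stem convolution.
#' @param meg_block_strides Per-block time-axis strides (length `n_blocks`).
#' @param mri_stem_stride Isotropic stride of the MRI stem convolution.
#' @param mri_block_strides Per-block isotropic strides (length `n_blocks`).
#' @param meg_stem_init `"filterbank"` (default) initialises the strip-stem
#'   kernels as a learnable log-spaced bank of windowed sinusoids;
#'   `"kaiming"` uses the generic convolution initialisation.
#' @param meg_norm,mri_norm Normalisation, all per-sample (the only reliable
#'   choice at batch size 2): `"instance"` (per channel), `"group"`
#'   (per-channel centring, whole-map scale) or `"rms"` (whole-map RMS
#'   division, no centring).  The MEG branch defaults to `"rms"`: both
#'   instance normalisation and any per-channel mean-centring provably erase
#'   components of the band-power statistics that carry the class signal in
#'   band-limited sensor data.  The MRI branch keeps `"instance"` (spatial
#'   patterns within a channel survive it).
#' @return An object of class `nf_branch_config`.
#' @export
branch_config <- function(base_channels = 16, n_blocks = 4,
                          meg_stem_stride = 2, meg_block_strides = c(2, 2, 2, 4),
                          mri_stem_stride = 2, mri_block_strides = c(2, 2, 1, 1),
                          meg_norm = "rms", mri_norm = "instance",
                          meg_stem_init = "filterbank") {
  stopifnot(base_channels >= 1, n_blocks >= 1,
            length(meg_block_strides) == n_blocks,
            length(mri_block_strides) == n_blocks)
  meg_norm <- match.arg(meg_norm, c("rms", "group", "instance"))
  mri_norm <- match.arg(mri_norm, c("instance", "group"))
  meg_stem_init <- match.arg(meg_stem_init, c("filterbank", "kaiming"))
  cfg <- list(base_channels = as.integer(base_channels),
              n_blocks = as.integer(n_blocks),
              meg_stem_stride = as.integer(meg_stem_stride),
              meg_block_strides = as.integer(meg_block_strides),
              mri_stem_stride = as.integer(mri_stem_stride),
              mri_block_strides = as.integer(mri_block_strides),
              meg_norm = meg_norm, mri_norm = mri_norm,
              meg_stem_init = meg_stem_init)
  class(cfg) <- "nf_branch_config"
  cfg
}

#' Reduced branch configurations for small inputs
#'
#' `branch_config_small()` matches 16 x 512 MEG segments and 32^3 volumes
#' (time 512 -> 128, volume 32 -> 8); `branch_config_tiny()` matches 8 x 256
#' MEG segments and 16^3 volumes (time 256 -> 64, volume 16 -> 4).
#'
#' @param base_channels Feature channel count.
#' @return An `nf_branch_config`.
#' @export
branch_config_small <- function(base_channels = 8) {
  branch_config(base_channels = base_channels,
                meg_block_strides = c(2, 1, 1, 1),
                mri_block_strides = c(2, 1, 1, 1))
}

#' @rdname branch_config_small
#' @export
branch_config_tiny <- function(base_channels = 8) {
  branch_config(base_channels = base_channels,
                meg_block_strides = c(2, 1, 1, 1),
                mri_block_strides = c(2, 1, 1, 1))
}

norm_factory <- function(type) {
  switch(type,
         group = function(c) nn_norm(c, groups = 1),
         rms = function(c) nn_norm(c, groups = 1, center = FALSE),
         function(c) nn_norm(c, groups = c))
}

# Initialise the (1, 15) strip kernels as a log-spaced bank of Hann-windowed
# sinusoids (0.006-0.2 cycles/sample, i.e. 3-100 Hz at 500 Hz).  The stem
# remains fully learnable; starting from band-selective filters rather than
# white noise gives the channels distinct spectral responses from step one,
# which makes oscillatory band-power features learnable within a small epoch
# budget.  Phases alternate between cosine and sine so paired channels can
# approximate an analytic (envelope) response.
filterbank_init <- function(conv, C, klen = 15) {
  fr <- exp(seq(log(0.006), log(0.2), length.out = C))
  t <- seq_len(klen) - (klen + 1) / 2
  win <- 0.5 + 0.5 * cos(pi * t / ((klen - 1) / 2))
  for (c in seq_len(C)) {
    ph <- if (c %% 2 == 0) pi / 2 else 0
    k <- win * cos(2 * pi * fr[c] * t + ph)
    k <- k / sqrt(sum(k^2))
    conv$par$w[1, , 1, 1, c] <- k
  }
  conv$par$b[] <- 0
  conv
}

# Build the MEG branch as a module list.  Input dim: (S, T, 1, 1).
meg_branch <- function(cfg = branch_config()) {
  C <- cfg$base_channels
  mk <- norm_factory(cfg$meg_norm %||% "group")
  stem <- nn_conv(1, C, c(1, 15, 1), c(1, cfg$meg_stem_stride, 1),
                  pad = c(0, 7, 0))
  if ((cfg$meg_stem_init %||% "filterbank") == "filterbank")
    stem <- filterbank_init(stem, C)
  mods <- list(
    stem,
    mk(C), nn_relu(),
    nn_conv(C, C, c(3, 3, 1), c(1, 1, 1), pad = c(1, 1, 0)),
    mk(C), nn_relu())
  for (s in cfg$meg_block_strides)
    mods <- c(mods, list(nn_resblock(C, C, c(3, 3, 1), c(1, s, 1),
                                     norm = mk)))
  nn_seq(mods)
}

# Build the MRI branch.  Input dim: (X, Y, Z, 1).
mri_branch <- function(cfg = branch_config()) {
  C <- cfg$base_channels
  mk <- norm_factory(cfg$mri_norm %||% "instance")
  mods <- list(
    nn_conv(1, C, c(7, 7, 7), rep(cfg$mri_stem_stride, 3), pad = c(3, 3, 3)),
    mk(C), nn_relu())
  for (s in cfg$mri_block_strides)
    mods <- c(mods, list(nn_resblock(C, C, c(3, 3, 3), rep(s, 3),
                                     norm = mk)))
  nn_seq(mods)
}

#' Forward pass through the MEG feature branch
#'
#' @param x MEG segment, a (sensors x time) matrix or an `nf_meg` recording,
#'   or a list of them (a batch).
#' @param branch A branch module built internally by [nf_model()]; if `NULL`
#'   a fresh branch with configuration `cfg` is created.
#' @param cfg An [branch_config()] object.
#' @return Feature array (sensors, time_out, 1, C), or a list of them.
#' @export
meg_branch_forward <- function(x, branch = NULL, cfg = branch_config()) {
  if (is.null(branch)) branch <- meg_branch(cfg)
  one <- function(xx) {
    if (inherits(xx, "nf_meg")) xx <- xx$data
    stopifnot(is.matrix(xx))
    dim(xx) <- c(dim(xx), 1L, 1L)
    branch$forward(xx, train = FALSE)
  }
  if (is.list(x) && !inherits(x, "nf_meg")) lapply(x, one) else one(x)
}

#' Forward pass through the MRI feature branch
#'
#' @param x 3D volume array or `nf_mri` object, or a list of them.
#' @inheritParams meg_branch_forward
#' @return Feature array (x, y, z, C), or a list of them.
#' @export
mri_branch_forward <- function(x, branch = NULL, cfg = branch_config()) {
  if (is.null(branch)) branch <- mri_branch(cfg)
  one <- function(xx) {
    if (inherits(xx, "nf_mri")) xx <- xx$data
    stopifnot(length(dim(xx)) == 3L)
    dim(xx) <- c(dim(xx), 1L)
    branch$forward(xx, train = FALSE)
  }
  if (is.list(x) && !inherits(x, "nf_mri")) lapply(x, one) else one(x)
}
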