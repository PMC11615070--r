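# Reduced-scale reference benchmarks.
#
# Two fixed synthetic study conditions exercise the full pipeline at desk
# scale (8 x 256 MEG segments, 16^3 volumes, 8-channel branches).  The
# 256-sample segments keep the single-segment band-power estimate noisy
# enough that each modality alone is a moderate classifier -- the signal
# regime the fusion architecture is designed for:
#   * "separable":      strong effects (MRI d = 2, MEG high-gamma power
#                       ratio 3), 100 subjects per group -- a sanity check
#                       that training reaches >= 0.9 train accuracy.
#   * "complementary":  the class signal is split across modalities (MRI
#                       d = 1, MEG high-gamma ratio 1.6), 150 per group --
#                       fusion should match or beat each unimodal model in
#                       cross-validated accuracy.
# These conditions are fixed study designs, not tuning knobs.

#' Benchmark effect specifications
#'
#' @param type `"separable"` or `"complementary"`.
#' @return An [effect_spec()].
#' @export
benchmark_effect <- function(type = c("complementary", "separable")) {
  type <- match.arg(type)
  if (type == "separable")
    effect_spec(mri_effect_d = 2, meg_band = "high_gamma",
                meg_power_ratio = 3)
  else
    effect_spec(mri_effect_d = 1, meg_band = "high_gamma",
                meg_power_ratio = 1.6)
}

#' Benchmark dataset at reduced shapes
#'
#' @param type Benchmark condition, see [benchmark_effect()].
#' @param n_per_group Subjects per group (defaults: 100 separable, 150
#'   complementary).
#' @param seed Integer seed.
#' @return An `nf_dataset` with 8 x 256 MEG segments and 16^3 volumes.
#' @export
benchmark_dataset <- function(type = c("complementary", "separable"),
                              n_per_group = NULL, seed = 11) {
  type <- match.arg(type)
  if (is.null(n_per_group))
    n_per_group <- if (type == "separable") 100 else 150
  generate_dataset(n_per_group, n_per_group, seed = seed,
                   meg_shape = c(8, 256), mri_shape = c(16, 16, 16),
                   effect = benchmark_effect(type), sigma = 2)
}

#' Model configuration matched to the benchmark shapes
#'
#' @param strategy Fusion strategy.
#' @return A [model_config()] with 8-channel tiny branches.
#' @export
benchmark_model_config <- function(strategy = "inter") {
  bc <- branch_config(base_channels = 8, meg_stem_stride = 2,
                      meg_block_strides = c(2, 1, 1, 1),
                      mri_block_strides = c(2, 1, 1, 1))
  model_config(strategy, branch = bc,
               meg_shape = c(8, 256), mri_shape = c(16, 16, 16),
               head_hidden = 32, meg_head_pool = c(8, 1),
               fused_head_pool = c(2, 2, 2), positional = FALSE)
}

#' Training configuration for the benchmarks
#'
#' Reduced-scale protocol: Adam at the full protocol's batch size (2) and
#' weight decay, a halved learning rate (5e-4; the tiny heads are prone to
#' ReLU death at 1e-3), gradient clipping, circular-shift MEG augmentation,
#' and fewer epochs.
#'
#' @param epochs Number of epochs (default 15).
#' @param seed Integer seed.
#' @return A [train_config()].
#' @export
benchmark_train_config <- function(epochs = 15, seed = 11) {
  train_config(lr = 5e-4, epochs = epochs, batch_size = 2, folds = 5,
               seed = seed)
}
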