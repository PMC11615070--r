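# Architecture accounting: exact learnable-parameter counts and a declared
# FLOPs convention.  Convention tag "2xMAC-conv-linear-attention": every
# convolution, linear layer and attention product contributes 2 FLOPs per
# multiply-accumulate at its actual output shape; normalisation, activations
# and pooling are excluded.  Absolute published FLOP/parameter figures depend
# on the (unstated) channel width and counting tool of their source, so only
# ordering and ratio relations are asserted anywhere in the package.

FLOPS_CONVENTION <- "2xMAC-conv-linear-attention"

#' Count learnable parameters
#'
#' Sums every learnable scalar: convolution and linear weights and biases,
#' normalisation affine terms, MMPE projections and positional embeddings,
#' attention maps and CFA MLP weights.  Structure-only: invariant to the
#' weight values.
#'
#' @param model An `nf_model`.
#' @return Integer-valued count.
#' @export
count_params <- function(model) {
  sum(vapply(model$modules,
             function(m) sum(vapply(m$par, length, 1L)), 1))
}

#' Count FLOPs for one forward pass
#'
#' Runs a forward pass on zero inputs of the model's configured shapes, during
#' which each counted layer records its multiply-accumulates; the result is
#' `2 x` the MAC total under the declared convention.
#'
#' @param model An `nf_model`.
#' @return List with `flops`, `macs` and the `convention` tag.
#' @export
count_flops <- function(model) {
  for (m in model$modules) m$macs <- 0
  meg <- if (model$strategy != "mri_only")
    matrix(0, model$config$meg_shape[1], model$config$meg_shape[2])
  mri <- if (model$strategy != "meg_only")
    array(0, model$config$mri_shape)
  invisible(nf_forward(model, meg, mri, train = FALSE))
  macs <- sum(vapply(model$modules, function(m) m$macs, 0))
  list(flops = 2 * macs, macs = macs, convention = FLOPS_CONVENTION)
}

#' Complexity table across strategies
#'
#' One row per strategy at the given input sizes, with parameter counts and
#' FLOPs under the declared convention.
#'
#' @param strategies Character vector of strategies.
#' @param meg_shape,mri_shape Input sizes (defaults: 102 x 8192 and 192^3).
#' @param branch A [branch_config()].
#' @param count_flops Also run the forward passes for FLOPs (set `FALSE` to
#'   get parameter counts only, which needs no computation).
#' @return Data frame with `strategy`, `params`, `flops`, `convention`.
#' @export
complexity_table <- function(strategies = c("meg_only", "mri_only", "early",
                                            "inter", "late"),
                             meg_shape = c(102, 8192),
                             mri_shape = c(192, 192, 192),
                             branch = branch_config(),
                             count_flops = TRUE) {
  rows <- lapply(strategies, function(st) {
    model <- nf_model(model_config(st, branch = branch,
                                   meg_shape = meg_shape,
                                   mri_shape = mri_shape), seed = 1)
    fl <- if (count_flops) neurofuse::count_flops(model)$flops else NA_real_
    data.frame(strategy = st, params = count_params(model), flops = fl,
               convention = FLOPS_CONVENTION)
  })
  do.call(rbind, rows)
}
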