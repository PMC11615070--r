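# Strategy assembly, the loss, prediction methods and checkpoints.

test_that("every strategy emits finite 2-class logits with the right contracts", {
  set.seed(1)
  meg <- matrix(rnorm(6 * 64), 6, 64)
  mri <- array(rnorm(12^3), c(12, 12, 12))
  for (st in c("meg_only", "mri_only", "early", "inter", "late")) {
    model <- nf_model(tiny_model_config(st), seed = 1)
    lg <- nf_forward(model,
                     if (st == "mri_only") NULL else meg,
                     if (st == "meg_only") NULL else mri)
    expect_length(lg, 2)
    expect_true(all(is.finite(lg)))
  }
})

test_that("the early-fusion stem receives a 2-channel input", {
  model <- nf_model(tiny_model_config("early"), seed = 1)
  stem <- model$early_net$mods[[1]]
  expect_equal(stem$meta$in_ch, 2)
})

test_that("unimodal models ignore the absent modality but fusion models require both", {
  set.seed(2)
  meg <- matrix(rnorm(6 * 64), 6, 64)
  mri <- array(rnorm(12^3), c(12, 12, 12))
  m <- nf_model(tiny_model_config("meg_only"), seed = 1)
  expect_length(nf_forward(m, meg = meg, mri = NULL), 2)
  expect_error(nf_forward(m, meg = NULL, mri = mri), "requires MEG")
  mi <- nf_model(tiny_model_config("inter"), seed = 1)
  expect_error(nf_forward(mi, meg = meg, mri = NULL), "requires MRI")
  expect_error(nf_forward(mi, meg = meg[1:3, ], mri = mri), "shape")
})

test_that("forward passes are per-sample deterministic (batch permutation)", {
  set.seed(3)
  subs <- lapply(1:4, function(i)
    list(meg = matrix(rnorm(6 * 64), 6, 64),
         mri = array(rnorm(12^3), c(12, 12, 12))))
  model <- nf_model(tiny_model_config("inter"), seed = 2)
  lg <- t(sapply(subs, function(s) nf_forward(model, s$meg, s$mri)))
  p <- c(3, 1, 4, 2)
  lg_p <- t(sapply(subs[p], function(s) nf_forward(model, s$meg, s$mri)))
  expect_equal(lg_p, lg[p, ], tolerance = 1e-12)
})

test_that("cross-entropy matches its closed forms", {
  expect_equal(cross_entropy(c(0, 1), c(0, 1)), 0)
  expect_equal(cross_entropy(c(0.5, 0.5), c(1, 0)), log(2))
  expect_equal(cross_entropy(c(0.8, 0.2), c(1, 0)), -log(0.8))
  expect_equal(round(cross_entropy(c(0.8, 0.2), c(1, 0)), 4), 0.2231)
  # batch averaging
  expect_equal(cross_entropy(rbind(c(0.5, 0.5), c(1, 0)),
                             rbind(c(1, 0), c(1, 0))), log(2) / 2)
  # zero probability where p > 0
  expect_equal(cross_entropy(c(0, 1), c(1, 0)), Inf)
  expect_true(is.finite(cross_entropy(c(0, 1), c(1, 0), eps = 1e-12)))
  expect_gte(cross_entropy(c(0.3, 0.7), c(0, 1)), 0)
})

test_that("saturating the CFA weights to the MEG side reproduces a MEG-token-only head", {
  nf <- asNamespace("neurofuse")
  set.seed(4)
  model <- nf_model(tiny_model_config("inter"), seed = 5)
  # drive w_a -> 1
  model$sccaf$cfa$par$w2[] <- 0
  model$sccaf$cfa$par$b2[] <- c(rep(50, 3), rep(-50, 3))
  meg <- matrix(rnorm(6 * 64), 6, 64)
  mri <- array(rnorm(12^3), c(12, 12, 12))
  lg <- nf_forward(model, meg, mri)
  # oracle: run branches + MMPE by hand, feed tok_meg straight into the head
  fa <- model$meg_branch$forward(nf$as4d(meg), train = FALSE)
  ta <- model$sccaf$mmpe_a$forward(fa, train = FALSE)
  want <- model$head$forward(ta, train = FALSE)
  expect_equal(lg, want, tolerance = 1e-4)
})

test_that("print, summary, coef and checkpoint round trip work", {
  model <- nf_model(tiny_model_config("inter"), seed = 1)
  expect_output(print(model), "strategy: inter")
  s <- summary(model)
  expect_equal(s$params, count_params(model))
  expect_output(print(s), "Total parameters")
  cf <- coef(model)
  expect_true(length(cf) > 0)

  p <- tempfile(fileext = ".rds")
  nf_save_model(model, p)
  back <- nf_load_model(p)
  meg <- matrix(rnorm(6 * 64), 6, 64)
  mri <- array(rnorm(12^3), c(12, 12, 12))
  expect_equal(nf_forward(back, meg, mri), nf_forward(model, meg, mri),
               tolerance = 1e-12)
  unlink(p)
})
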