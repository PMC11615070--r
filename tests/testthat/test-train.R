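# Cross-validation splits and the training loop.

test_that("balanced 10-subject 5-fold split gives one of each group per fold", {
  co <- generate_cohort(5, 5, seed = 1)
  folds <- kfold_split(co, k = 5, seed = 2)
  for (f in folds) {
    expect_length(f$val_ids, 2)
    g <- co$group[co$id %in% f$val_ids]
    expect_setequal(g, c("HC", "MCI"))
  }
})

test_that("folds partition the cohort: disjoint, exhaustive, stratified", {
  for (seed in 1:25) {
    n_hc <- sample(10:40, 1); n_mci <- sample(10:40, 1)
    co <- generate_cohort(n_hc, n_mci, seed = seed)
    k <- sample(2:5, 1)
    folds <- kfold_split(co, k = k, seed = seed)
    vals <- lapply(folds, `[[`, "val_ids")
    expect_setequal(unlist(vals), co$id)
    expect_equal(sum(lengths(vals)), nrow(co))        # pairwise disjoint
    for (f in folds) {
      expect_length(intersect(f$train_ids, f$val_ids), 0)
      per <- table(co$group[co$id %in% f$val_ids])
      expect_lte(max(abs(per["HC"] - n_hc / k)), 1)
      expect_lte(max(abs(per["MCI"] - n_mci / k)), 1)
    }
  }
})

test_that("the cohort-sized split keeps per-fold group counts within one of n/k", {
  co <- generate_cohort(163, 144, seed = 3)
  folds <- kfold_split(co, k = 5, seed = 3)
  for (f in folds) {
    per <- table(co$group[co$id %in% f$val_ids])
    expect_lte(abs(per[["HC"]] - 163 / 5), 1)
    expect_lte(abs(per[["MCI"]] - 144 / 5), 1)
  }
  expect_error(kfold_split(generate_cohort(3, 10, seed = 1), k = 5),
               "fewer than k")
})

test_that("splits are deterministic given the seed", {
  co <- generate_cohort(20, 20, seed = 1)
  expect_identical(kfold_split(co, 5, seed = 9), kfold_split(co, 5, seed = 9))
  expect_false(identical(kfold_split(co, 5, seed = 9),
                         kfold_split(co, 5, seed = 10)))
})

test_that("training with lr = 0 leaves every parameter unchanged", {
  ds <- generate_dataset(3, 3, seed = 6, meg_shape = c(6, 64),
                         mri_shape = c(12, 12, 12), sigma = 2)
  cfg0 <- train_config(lr = 0, weight_decay = 0, epochs = 2, batch_size = 2,
                       seed = 4)
  model <- nf_model(tiny_model_config("inter"), seed = 4)
  before <- lapply(model$modules, function(m) m$par)
  fitted <- nf_train(ds, model, cfg = cfg0)
  after <- lapply(fitted$modules, function(m) m$par)
  expect_identical(before, after)
  expect_length(fitted$loss_trace, 2)
  expect_error(nf_train(list(), "inter"), "no training subjects")
})

test_that("loss descends on a strongly separable tiny benchmark", {
  eff <- effect_spec(mri_effect_d = 2, meg_power_ratio = 3)
  ds <- generate_dataset(10, 10, seed = 8, meg_shape = c(6, 64),
                         mri_shape = c(12, 12, 12), effect = eff, sigma = 2)
  cfg <- train_config(epochs = 8, batch_size = 4, seed = 8)
  model <- nf_train(ds, nf_model(tiny_model_config("inter"), seed = 8),
                    cfg = cfg)
  tr <- model$loss_trace
  expect_lt(mean(utils::tail(tr, 3)), mean(utils::head(tr, 3)))
  expect_true(model$fitted)
  # predictions are valid probabilities
  pr <- predict(model, ds, type = "prob")
  expect_equal(unname(rowSums(pr)), rep(1, 20), tolerance = 1e-9)
})

test_that("run_experiment emits the comparison schema and is deterministic", {
  eff <- effect_spec(mri_effect_d = 2, meg_power_ratio = 3)
  ds <- generate_dataset(8, 8, seed = 12, meg_shape = c(6, 64),
                         mri_shape = c(12, 12, 12), effect = eff, sigma = 2)
  cfg <- train_config(epochs = 2, batch_size = 4, folds = 2, seed = 12)
  mcs <- list(meg_only = tiny_model_config("meg_only"),
              mri_only = tiny_model_config("mri_only"))
  ex <- run_experiment(c("meg_only", "mri_only"), ds, cfg, mcs)
  expect_equal(nrow(ex$table), 2)
  expect_true(all(c("strategy", "accuracy", "f1", "sensitivity",
                    "specificity", "mcc", "p_adjusted_vs_best") %in%
                    names(ex$table)))
  expect_true(all(is.finite(ex$table$accuracy)))

  ex2 <- run_experiment(c("meg_only", "meg_only"), ds, cfg,
                        list(meg_only = tiny_model_config("meg_only")))
  expect_equal(ex2$table$accuracy[1], ex2$table$accuracy[2])
  expect_equal(ex2$table$mcc[1], ex2$table$mcc[2])
})

test_that("fold-averaged metrics are invariant to fold ordering", {
  fake_cv <- lapply(1:4, function(i)
    list(fold_index = i,
         metrics = list(acc = i / 10, f1 = i / 20, sensitivity = 0.5,
                        specificity = 0.6, mcc = 0.1, auc = 0.7, ap = 0.8)))
  class(fake_cv) <- "nf_cv"
  rev_cv <- structure(rev(fake_cv), class = "nf_cv")
  expect_equal(cv_mean_metrics(fake_cv), cv_mean_metrics(rev_cv))
})
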