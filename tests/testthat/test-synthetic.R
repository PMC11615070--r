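# Synthetic cohort generator: metadata marginals, MEG spectra, MRI fields.

test_that("cohort generation is deterministic, exact in counts, and handles the empty case", {
  empty <- generate_cohort(0, 0, seed = 1)
  expect_s3_class(empty, "nf_cohort")
  expect_equal(nrow(empty), 0)

  co <- generate_cohort(166, 158, seed = 7)
  expect_equal(sum(co$group == "HC"), 166)
  expect_equal(sum(co$group == "MCI"), 158)
  expect_false(any(duplicated(co$id)))
  expect_true(all(co$mmse >= 0 & co$mmse <= 30))
  expect_true(all(co$age > 0))
  expect_true(all(co$site %in% c("CBU", "CTB")))
  expect_true(all(co$sex %in% c("M", "F")))

  co2 <- generate_cohort(166, 158, seed = 7)
  expect_identical(co, co2)
  co3 <- generate_cohort(166, 158, seed = 8)
  expect_false(identical(co$age, co3$age))

  expect_error(generate_cohort(-1, 5), "nonnegative")
})

test_that("metadata group means match the declared marginals (Monte-Carlo)", {
  co <- generate_cohort(5000, 5000, seed = 3)
  se_hc <- 1.2 / sqrt(5000)
  se_mci <- 2.8 / sqrt(5000)
  expect_lt(abs(mean(co$mmse[co$group == "HC"]) - 28.8), 3 * se_hc)
  expect_lt(abs(mean(co$mmse[co$group == "MCI"]) - 26.1), 3 * se_mci)
  expect_lt(abs(mean(co$age[co$group == "HC"]) - 71.3), 3 * 7.0 / sqrt(5000))
  expect_lt(abs(mean(co$education[co$group == "MCI"]) - 10.8),
            3 * 5.3 / sqrt(5000))
  # site probabilities
  expect_lt(abs(mean(co$site[co$group == "HC"] == "CBU") - 91 / 166), 0.03)
})

test_that("MEG generator honours shape, determinism and the null effect", {
  rec <- generate_meg(list(group = "HC", id = "s1"), seed = 1, index = 1)
  expect_equal(dim(rec$data), c(102, 8192))
  expect_equal(rec$fs, 500)
  expect_true(all(is.finite(rec$data)))

  # null effect: same sub-seed gives bit-identical arrays regardless of group
  e1 <- effect_spec(meg_power_ratio = 1)
  a <- generate_meg(list(group = "HC", id = "x"), shape = c(4, 256),
                    effect = e1, seed = 5, index = 3)
  b <- generate_meg(list(group = "MCI", id = "x"), shape = c(4, 256),
                    effect = e1, seed = 5, index = 3)
  expect_identical(a$data, b$data)

  expect_error(generate_meg(list(group = "HC", id = "x"), fs = 100,
                            effect = effect_spec(meg_band = "high_gamma")),
               "too low")
})

test_that("MCI band power is scaled by the requested ratio (ensemble check)", {
  eff <- effect_spec(meg_power_ratio = 2, meg_band = "high_gamma")
  bp <- function(group, off) vapply(1:100, function(i) {
    r <- generate_meg(list(group = group, id = "x"), shape = c(8, 512),
                      fs = 500, effect = eff, seed = 42, index = i + off)
    oracle_band_power(r$data, 500, 52, 86)
  }, 0)
  ratio <- mean(bp("MCI", 1000)) / mean(bp("HC", 0))
  expect_lt(abs(ratio - 2), 0.2)
})

test_that("MRI generator honours shape, bounds checking and the null effect", {
  v <- generate_mri(list(group = "HC", id = "s1"), shape = c(48, 48, 40),
                    seed = 1, index = 1, sigma = 3)
  expect_equal(dim(v$data), c(48, 48, 40))
  expect_true(all(is.finite(v$data)))
  # unit voxel SD by construction
  expect_lt(abs(stats::sd(as.vector(v$data)) - 1), 0.2)

  e0 <- effect_spec(mri_effect_d = 0)
  a <- generate_mri(list(group = "HC", id = "x"), shape = c(16, 16, 16),
                    effect = e0, seed = 2, index = 1, sigma = 2)
  b <- generate_mri(list(group = "MCI", id = "x"), shape = c(16, 16, 16),
                    effect = e0, seed = 2, index = 1, sigma = 2)
  expect_identical(a$data, b$data)

  bad <- effect_spec(mri_effect_d = 1)
  bad$mri_region <- rbind(lo = c(1, 1, 1), hi = c(99, 9, 9))
  expect_error(generate_mri(list(group = "MCI", id = "x"),
                            shape = c(16, 16, 16), effect = bad),
               "inside the volume")
})

test_that("standardised region-mean difference recovers the requested d", {
  eff <- effect_spec(mri_effect_d = 1)
  eff$mri_region <- rbind(lo = c(7, 7, 7), hi = c(10, 10, 10))
  rm_ <- function(group, off) vapply(1:250, function(i) {
    v <- generate_mri(list(group = group, id = "x"), shape = c(16, 16, 16),
                      effect = eff, seed = 7, index = i + off, sigma = 2)
    mean(v$data[7:10, 7:10, 7:10])
  }, 0)
  a <- rm_("HC", 0); b <- rm_("MCI", 5000)
  sp <- sqrt((var(a) + var(b)) / 2)
  d <- (mean(a) - mean(b)) / sp
  expect_lt(abs(d - 1), 0.15)
})

test_that("native full-resolution volume shape is generated on request", {
  v <- generate_mri(list(group = "HC", id = "s1"), seed = 1, index = 1)
  expect_equal(dim(v$data), c(192, 192, 182))
})

test_that("a null-effect cohort carries no label information (permutation test)", {
  eff <- effect_spec(mri_effect_d = 0, meg_power_ratio = 1)
  pvals <- vapply(1:20, function(rep) {
    n <- 16
    groups <- rep(c("HC", "MCI"), each = n / 2)
    bp <- vapply(seq_len(n), function(i) {
      r <- generate_meg(list(group = groups[i], id = "x"), shape = c(4, 256),
                        fs = 500, effect = eff, seed = 100 + rep, index = i)
      oracle_band_power(r$data, 500, 52, 86)
    }, 0)
    obs <- mean(bp[groups == "MCI"]) - mean(bp[groups == "HC"])
    set.seed(rep)
    perm <- vapply(1:199, function(k) {
      g <- sample(groups)
      mean(bp[g == "MCI"]) - mean(bp[g == "HC"])
    }, 0)
    (1 + sum(abs(perm) >= abs(obs))) / 200
  }, 0)
  # under the null the p-values are uniform: the mean should sit near 0.5
  expect_gt(mean(pvals), 0.25)
  expect_lt(mean(pvals), 0.75)
  expect_gt(min(pvals), 1 / 200 - 1e-12)
})

test_that("dataset wrapper pairs metadata with arrays deterministically", {
  ds <- generate_dataset(3, 3, seed = 9, meg_shape = c(4, 128),
                         mri_shape = c(12, 12, 12), sigma = 2)
  expect_length(ds$subjects, 6)
  expect_equal(vapply(ds$subjects, function(s) s$id, ""), ds$cohort$id)
  ds2 <- generate_dataset(3, 3, seed = 9, meg_shape = c(4, 128),
                          mri_shape = c(12, 12, 12), sigma = 2)
  expect_identical(ds$subjects[[4]]$meg, ds2$subjects[[4]]$meg)
  expect_identical(ds$subjects[[2]]$mri, ds2$subjects[[2]]$mri)
})
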