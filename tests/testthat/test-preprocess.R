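# Deterministic preprocessing: resampling, band filtering, segmentation,
# padding, normalisation.

test_that("resampling preserves DC, is the identity at equal rates, and keeps spectral peaks", {
  const <- matrix(3.7, 2, 1000)
  out <- nf_resample(const, 500, fs_in = 1000)
  expect_equal(ncol(out$data), 500)
  core <- out$data[, 20:480]
  expect_lt(max(abs(core - 3.7)), 1e-6)

  x <- matrix(rnorm(2 * 256), 2, 256)
  same <- nf_resample(x, 500, fs_in = 500)
  expect_identical(same$data, x)

  # 10 Hz sine sampled at 1000 Hz, downsampled to 500 Hz
  t <- seq(0, 2 - 1e-9, by = 1 / 1000)
  s <- matrix(sin(2 * pi * 10 * t), 1)
  ds <- nf_resample(s, 500, fs_in = 1000)
  expect_equal(ncol(ds$data), 1000)
  sp <- Mod(stats::fft(ds$data[1, ]))[1:500]
  freqs <- (0:499) * 500 / 1000
  expect_equal(freqs[which.max(sp)], 10)

  expect_error(nf_resample(x, -5, fs_in = 500), "positive")
  expect_error(nf_resample(x, 600, fs_in = 500), "upsampling")
})

test_that("band names resolve to the canonical edges", {
  hg <- band_spec("high_gamma")
  expect_equal(c(hg$lo, hg$hi), c(52, 86))
  expect_equal(unname(unlist(band_table()[band_table()$name == "delta",
                                          c("lo", "hi")])), c(2, 4))
  expect_equal(unname(unlist(band_table()[band_table()$name == "broadband",
                                          c("lo", "hi")])), c(0.5, 98))
  expect_error(band_spec("ultra"), "unknown band")
})

test_that("band-pass filtering is zero for zero input and concentrates power in band", {
  z <- matrix(0, 3, 512)
  expect_equal(nf_bandpass(z, "alpha", fs = 500)$data, z)

  set.seed(1)
  x <- matrix(rnorm(2 * 4096), 2, 4096)
  y <- nf_bandpass(x, "alpha", fs = 500)
  # >= 90% of output power within the widened 6-14 Hz window
  inband <- oracle_band_power(y$data, 500, 6, 14) * (14 - 6)
  total <- oracle_band_power(y$data, 500, 0, 250) * 250
  expect_gt(inband / total, 0.9)

  expect_error(nf_bandpass(x, band_spec("x", 100, 260), fs = 500), "Nyquist")
})

test_that("band-pass is near-idempotent and does not create energy", {
  set.seed(2)
  x <- matrix(rnorm(2 * 2048), 2, 2048)
  for (bn in c("theta", "beta", "high_gamma")) {
    y1 <- nf_bandpass(x, bn, fs = 500)
    y2 <- nf_bandpass(y1, bn, fs = 500)
    p1 <- sum(y1$data^2); p2 <- sum(y2$data^2)
    expect_lt(abs(p2 - p1) / p1, 0.05)
    expect_lte(sum(y1$data^2), sum(x^2) * (1 + 1e-6))
  }
})

test_that("segmentation returns the contract window and errors on short input", {
  x <- matrix(seq_len(3 * 60000), 3, 60000, byrow = TRUE)
  seg <- nf_segment(x, 8192)
  expect_equal(dim(seg$data), c(3, 8192))
  expect_equal(seg$data[1, 1], x[1, 1])

  same <- nf_segment(x[, 1:8192, drop = FALSE], 8192)
  expect_equal(same$data, x[, 1:8192])

  off <- nf_segment(x, 100, offset = 100)
  expect_equal(off$data[2, 1], x[2, 101])

  expect_error(nf_segment(x[, 1:100, drop = FALSE], 8192), "120 s")
})

test_that("volume padding splits evenly with the extra voxel trailing and inverts exactly", {
  v <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  p <- nf_pad_volume(v, c(6, 7, 6))
  expect_equal(dim(p), c(6, 7, 6))
  # even split: lo = floor((target - src)/2)
  expect_equal(p[2:5, 2:5, 2:4], v)
  expect_equal(sum(p != 0), sum(v != 0))
  expect_identical(nf_crop_volume(p, dim(v)), v)

  expect_identical(nf_pad_volume(v, dim(v)), v + 0)
  expect_error(nf_pad_volume(v, c(3, 4, 3)), ">= source")

  big <- nf_pad_volume(array(1, c(192, 192, 182)), c(192, 192, 192))
  expect_equal(dim(big), c(192, 192, 192))
})

test_that("normalisation modes satisfy their definitions and the constant convention", {
  x <- array(rnorm(200), c(10, 20))
  z <- nf_normalize(x, "zscore")
  expect_lt(abs(mean(z)), 1e-9)
  expect_lt(abs(sqrt(mean((z - mean(z))^2)) - 1), 1e-9)

  r <- nf_normalize(matrix(0:9, 1), "unit_range")
  expect_equal(as.numeric(r), (0:9) / 9)

  expect_equal(nf_normalize(matrix(5, 3, 3), "zscore"), matrix(0, 3, 3))
  expect_equal(nf_normalize(matrix(5, 3, 3), "unit_range"), matrix(0, 3, 3))
})
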