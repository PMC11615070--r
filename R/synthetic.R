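# Synthetic cohort generator.
#
# Emulates the *outputs* of a two-site MEG+MRI dementia cohort pipeline:
# subject metadata with group-dependent marginals, resting-state MEG
# magnetometer segments (102 sensors x 8192 samples at 500 Hz) and registered
# T1 volumes (192 x 192 x 182 voxels).  Class-dependent effects are injected
# with tunable sizes: a multiplicative band-power factor for MCI in one MEG
# frequency band, and a standardised negative mean shift inside an MRI region
# (an atrophy stand-in).  All randomness flows from one integer seed through
# a documented per-subject sub-seed scheme.

# Per-subject sub-seed: a simple multiplicative hash, kept below 2^31.
subject_seed <- function(seed, index, salt = 0L) {
  ((as.double(seed) %% 2147483647) * 1000003 + index * 7919 + salt * 104729) %%
    2147483647
}

#' Table-style metadata marginals
#'
#' Per-group means/SDs for the continuous variables and category probabilities
#' for site and sex.  The defaults follow the summary table of the emulated
#' cohort: HC age 71.3 (7.0), education 14.5 (4.4), MMSE 28.8 (1.2), recording
#' duration 481.5 (262), site CBU 91/166, male 82/166; MCI age 72.9 (6.7),
#' education 10.8 (5.3), MMSE 26.1 (2.8), duration 180.0 (305), site CBU
#' 68/158, male 80/158.
#'
#' @return A list with one entry per group (`HC`, `MCI`).
#' @export
cohort_marginals <- function() {
  list(
    HC = list(p_cbu = 91 / 166, p_male = 82 / 166,
              age = c(71.3, 7.0), education = c(14.5, 4.4),
              mmse = c(28.8, 1.2), duration = c(481.5, 262)),
    MCI = list(p_cbu = 68 / 158, p_male = 80 / 158,
               age = c(72.9, 6.7), education = c(10.8, 5.3),
               mmse = c(26.1, 2.8), duration = c(180.0, 305))
  )
}

# Truncated normal whose post-truncation MEAN equals `target` (the location
# parameter is moment-matched by root finding); plain truncation would bias
# the mean, e.g. MMSE ~ N(28.8, 1.2) truncated at 30 loses ~0.35 points.
rtruncnorm_mean <- function(n, target, sd, lo = -Inf, hi = Inf) {
  if (n == 0) return(numeric(0))
  tmean <- function(mu) {
    a <- (lo - mu) / sd; b <- (hi - mu) / sd
    # stable tail handling: compute the normalising mass on the smaller side
    z <- if (a > 0) stats::pnorm(a, lower.tail = FALSE) -
      stats::pnorm(b, lower.tail = FALSE)
    else stats::pnorm(b) - stats::pnorm(a)
    if (!is.finite(z) || z < 1e-300) {
      # mass entirely in one far tail: first-order Mills-ratio approximation
      return(if (a > 0) lo + sd / a else hi + sd / abs(b))
    }
    mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
  }
  mu <- if (abs(tmean(target) - target) < 1e-9) {
    target
  } else {
    stats::uniroot(function(m) tmean(m) - target,
                   interval = target + c(-10, 10) * sd, extendInt = "upX",
                   tol = 1e-8)$root
  }
  x <- stats::qnorm(stats::runif(n, stats::pnorm(lo, mu, sd),
                                 stats::pnorm(hi, mu, sd)), mu, sd)
  pmin(pmax(x, lo), hi)
}

#' Generate a synthetic cohort table
#'
#' Draws `n_hc + n_mci` subjects with metadata sampled from the declared
#' per-group marginal distributions.  Continuous variables are truncated
#' normals (MMSE in \[0, 30\], age > 0, duration >= 120 s) whose post-truncation
#' means match the declared group means; site and sex are Bernoulli draws.
#'
#' @param n_hc,n_mci Group sizes (the emulated cohort has 163 HC / 144 MCI
#'   after exclusions; the summary-table marginals imply 166/158).
#' @param seed Integer seed; the draw is deterministic given it.
#' @param marginals Per-group distribution parameters, see
#'   [cohort_marginals()].
#' @return A data.frame of class `nf_cohort` with columns
#'   `id, group, site, sex, age, education, mmse, recording_duration`.
#' @export
generate_cohort <- function(n_hc, n_mci, seed = 1,
                            marginals = cohort_marginals()) {
  if (n_hc < 0 || n_mci < 0) stop("group counts must be nonnegative")
  set.seed(as.integer(seed) %% 2147483647L)
  one_group <- function(n, group, mg, offset) {
    if (n == 0) return(NULL)
    data.frame(
      id = sprintf("sub-%s%04d", tolower(group), seq_len(n)),
      group = group,
      site = ifelse(stats::runif(n) < mg$p_cbu, "CBU", "CTB"),
      sex = ifelse(stats::runif(n) < mg$p_male, "M", "F"),
      age = rtruncnorm_mean(n, mg$age[1], mg$age[2], lo = 40, hi = 100),
      education = rtruncnorm_mean(n, mg$education[1], mg$education[2],
                                  lo = 0, hi = 30),
      mmse = rtruncnorm_mean(n, mg$mmse[1], mg$mmse[2], lo = 0, hi = 30),
      recording_duration = rtruncnorm_mean(n, mg$duration[1], mg$duration[2],
                                           lo = 120, hi = 3600),
      stringsAsFactors = FALSE)
  }
  tab <- rbind(one_group(n_hc, "HC", marginals$HC, 0),
               one_group(n_mci, "MCI", marginals$MCI, n_hc))
  if (is.null(tab))
    tab <- data.frame(id = character(0), group = character(0),
                      site = character(0), sex = character(0),
                      age = numeric(0), education = numeric(0),
                      mmse = numeric(0), recording_duration = numeric(0))
  attr(tab, "seed") <- as.integer(seed)
  class(tab) <- c("nf_cohort", "data.frame")
  tab
}

#' Class-effect specification
#'
#' Describes how the MCI group differs from HC in the synthetic data: the MEG
#' band whose power is multiplied by `meg_power_ratio`, and the axis-aligned
#' MRI voxel box whose mean intensity is lowered by `mri_effect_d` standard
#' deviations of the region-mean statistic (a standardised atrophy effect).
#'
#' @param mri_region 2x3 matrix of inclusive voxel bounds (rows = lo, hi), or
#'   `NULL` for a centred box covering ~1/4 of each axis.
#' @param mri_effect_d Standardised mean difference (Cohen's d) of the region
#'   mean between groups.
#' @param meg_band Band name (see [band_table()]) or an `nf_band`.
#' @param meg_power_ratio Multiplicative MCI band-power factor (> 0).
#' @return An object of class `nf_effect`.
#' @export
effect_spec <- function(mri_region = NULL, mri_effect_d = 0,
                        meg_band = "high_gamma", meg_power_ratio = 1) {
  if (meg_power_ratio <= 0) stop("meg_power_ratio must be positive")
  if (is.character(meg_band)) meg_band <- band_spec(meg_band)
  e <- list(mri_region = mri_region, mri_effect_d = mri_effect_d,
            meg_band = meg_band, meg_power_ratio = meg_power_ratio)
  class(e) <- "nf_effect"
  e
}

default_region <- function(shape) {
  lo <- pmax(1L, round(shape * 3 / 8))
  hi <- pmin(shape, round(shape * 5 / 8))
  rbind(lo = lo, hi = hi)
}

#' Generate a synthetic resting-state MEG recording
#'
#' Builds each sensor's signal in the frequency domain: a 1/f (pink) amplitude
#' background plus Gaussian spectral bumps at alpha (10 Hz), beta (20 Hz) and
#' gamma (65 Hz), with complex-normal coefficients (random phase), restricted
#' to the 0.5--98 Hz pass band.  For MCI subjects every Fourier coefficient in
#' `effect$meg_band` is scaled by `sqrt(meg_power_ratio)`, so the expected
#' band power is multiplied exactly by the ratio.
#'
#' @param record One-row cohort entry (or any list with `group` and `id`).
#' @param shape (sensors, samples), default the full 102 x 8192 segment.
#' @param fs Sampling rate in Hz (default 500).
#' @param effect An [effect_spec()].
#' @param seed Cohort-level seed; the subject's draw uses a sub-seed hashed
#'   from it and `index`.
#' @param index Subject index used in the sub-seed hash.
#' @return An object of class `nf_meg`: list with `data` (sensors x samples),
#'   `fs`, `subject_id`.
#' @export
generate_meg <- function(record, shape = c(102, 8192), fs = 500,
                         effect = effect_spec(), seed = 1, index = 1) {
  stopifnot(all(shape >= 1))
  band <- effect$meg_band
  if (band$hi >= fs / 2)
    stop("sampling rate ", fs, " Hz is too low for band [", band$lo, ", ",
         band$hi, "] Hz (needs fs > 2 x ", band$hi, ")")
  S <- shape[1]; N <- shape[2]
  set.seed(subject_seed(seed, index, salt = 1L))
  freqs <- seq(0, fs / 2, by = fs / N)        # rfft bin frequencies
  nb <- length(freqs)
  amp_profile <- 1 / sqrt(pmax(freqs, 0.5)) +
    0.6 * exp(-(freqs - 10)^2 / (2 * 2^2)) +
    0.3 * exp(-(freqs - 20)^2 / (2 * 4^2)) +
    0.15 * exp(-(freqs - 65)^2 / (2 * 10^2))
  amp_profile[freqs < 0.5 | freqs > 98] <- 0   # acquisition band-pass
  gain <- rep(1, nb)
  if (!is.null(record$group) && record$group == "MCI")
    gain[freqs >= band$lo & freqs <= band$hi] <- sqrt(effect$meg_power_ratio)
  subj_scale <- exp(stats::rnorm(1, 0, 0.1))  # global amplitude variability
  dat <- matrix(0, S, N)
  for (s in seq_len(S)) {
    sens_scale <- exp(stats::rnorm(1, 0, 0.2))
    co <- complex(real = stats::rnorm(nb), imaginary = stats::rnorm(nb)) *
      amp_profile * gain * subj_scale * sens_scale
    co[1] <- 0
    if (N %% 2 == 0) co[nb] <- complex(real = Re(co[nb]), imaginary = 0)
    tail_start <- if (N %% 2 == 0) nb - 1 else nb
    full <- c(co, Conj(co[seq(tail_start, 2)]))
    dat[s, ] <- Re(stats::fft(full, inverse = TRUE)) / sqrt(N)
  }
  structure(list(data = dat, fs = fs,
                 subject_id = record$id %||% "sub-0000"),
            class = "nf_meg")
}

# Gaussian kernel on a periodic grid, frequency response via FFT.
gauss_kernel_fft <- function(shape, sigma) {
  ax <- lapply(shape, function(n) {
    d <- c(0:(n %/% 2), -((n - (n %/% 2) - 1):1))
    exp(-d^2 / (2 * sigma^2))
  })
  k <- outer(outer(ax[[1]], ax[[2]]), ax[[3]])
  dim(k) <- shape
  stats::fft(k / sum(k))
}

# Closed-form SD of the region spatial mean of the unit-variance smoothed
# field: region mean = <smooth(u), w> / (V * ||g||), with w white unit noise.
region_mean_sd <- function(shape, sigma, region) {
  Kf <- gauss_kernel_fft(shape, sigma)
  u <- array(0, shape)
  u[region[1, 1]:region[2, 1], region[1, 2]:region[2, 2],
    region[1, 3]:region[2, 3]] <- 1
  V <- sum(u)
  gu <- Re(stats::fft(stats::fft(u) * Kf, inverse = TRUE)) / prod(shape)
  gnorm <- sqrt(sum(Mod(Kf)^2) / prod(shape))  # ||g||_2 by Parseval
  sqrt(sum(gu^2)) / (V * gnorm)
}

#' Generate a synthetic structural MRI volume
#'
#' The background is a smooth Gaussian random field (white noise convolved
#' with an isotropic Gaussian kernel, normalised to unit voxel SD).  For MCI
#' subjects the mean intensity inside `effect$mri_region` is shifted by
#' `-mri_effect_d` standard deviations of the *region-mean* statistic, so the
#' standardised between-group difference of region means equals
#' `mri_effect_d` by construction.
#'
#' @inheritParams generate_meg
#' @param shape Voxel grid, default the native (192, 192, 182).
#' @param sigma Smoothing kernel SD in voxels.
#' @param voxel_size Voxel edge lengths in mm.
#' @return An object of class `nf_mri`: list with `data`, `voxel_size`,
#'   `affine`, `subject_id`.
#' @export
generate_mri <- function(record, shape = c(192, 192, 182),
                         effect = effect_spec(), seed = 1, index = 1,
                         sigma = 4, voxel_size = c(1, 1, 1)) {
  region <- effect$mri_region %||% default_region(shape)
  if (any(region[1, ] < 1) || any(region[2, ] > shape) ||
      any(region[1, ] > region[2, ]))
    stop("mri_region must be an axis-aligned box inside the volume")
  set.seed(subject_seed(seed, index, salt = 2L))
  w <- array(stats::rnorm(prod(shape)), shape)
  Kf <- gauss_kernel_fft(shape, sigma)
  f <- Re(stats::fft(stats::fft(w) * Kf, inverse = TRUE)) / prod(shape)
  gnorm <- sqrt(sum(Mod(Kf)^2) / prod(shape))
  f <- f / gnorm                               # unit voxel SD field
  if (!is.null(record$group) && record$group == "MCI" &&
      effect$mri_effect_d != 0) {
    sd_rm <- region_mean_sd(shape, sigma, region)
    f[region[1, 1]:region[2, 1], region[1, 2]:region[2, 2],
      region[1, 3]:region[2, 3]] <-
      f[region[1, 1]:region[2, 1], region[1, 2]:region[2, 2],
        region[1, 3]:region[2, 3]] - effect$mri_effect_d * sd_rm
  }
  affine <- diag(c(voxel_size, 1))
  structure(list(data = f, voxel_size = voxel_size, affine = affine,
                 subject_id = record$id %||% "sub-0000"),
            class = "nf_mri")
}

#' Generate a full paired dataset in memory
#'
#' Convenience wrapper producing the cohort table plus per-subject MEG and MRI
#' arrays with the requested class effects -- the object consumed by
#' [nf_train()] and [run_experiment()].
#'
#' @inheritParams generate_cohort
#' @param meg_shape,mri_shape Array shapes per subject.
#' @param fs MEG sampling rate (Hz).
#' @param effect An [effect_spec()].
#' @param sigma MRI smoothing kernel SD (voxels).
#' @return An `nf_dataset`: list with `cohort` and `subjects` (each subject a
#'   list with `id`, `label`, `meg`, `mri`).
#' @export
generate_dataset <- function(n_hc, n_mci, seed = 1,
                             meg_shape = c(102, 8192),
                             mri_shape = c(192, 192, 182),
                             fs = 500, effect = effect_spec(), sigma = 4) {
  cohort <- generate_cohort(n_hc, n_mci, seed = seed)
  subjects <- lapply(seq_len(nrow(cohort)), function(i) {
    rec <- cohort[i, ]
    meg <- generate_meg(rec, shape = meg_shape, fs = fs, effect = effect,
                        seed = seed, index = i)
    mri <- generate_mri(rec, shape = mri_shape, effect = effect, seed = seed,
                        index = i, sigma = sigma)
    list(id = rec$id, label = rec$group, meg = meg$data, mri = mri$data)
  })
  structure(list(cohort = cohort, subjects = subjects, seed = seed),
            class = "nf_dataset")
}
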