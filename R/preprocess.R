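# Deterministic preprocessing: resampling, band filtering, segmentation,
# volume padding, intensity normalisation.

#' Canonical frequency bands
#'
#' delta 2-4, theta 4-8, alpha 8-12, beta 12-30, low_gamma 30-48, high_gamma
#' 52-86, broadband 0.5-98 Hz.
#'
#' @return Data frame with columns `name`, `lo`, `hi` (Hz).
#' @export
band_table <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta", "low_gamma",
                      "high_gamma", "broadband"),
             lo = c(2, 4, 8, 12, 30, 52, 0.5),
             hi = c(4, 8, 12, 30, 48, 86, 98),
             stringsAsFactors = FALSE)
}

#' Band specification
#'
#' @param name A canonical band name (see [band_table()]), or any label when
#'   `lo`/`hi` are supplied explicitly.
#' @param lo,hi Band edges in Hz.
#' @return An object of class `nf_band`.
#' @export
band_spec <- function(name, lo = NULL, hi = NULL) {
  tab <- band_table()
  if (is.null(lo) || is.null(hi)) {
    row <- tab[tab$name == name, ]
    if (nrow(row) != 1) stop("unknown band name '", name, "'")
    lo <- row$lo; hi <- row$hi
  }
  if (!(lo > 0 && lo < hi)) stop("band edges must satisfy 0 < lo < hi")
  structure(list(name = name, lo = lo, hi = hi), class = "nf_band")
}

as_meg <- function(x, fs = NULL) {
  if (inherits(x, "nf_meg")) return(x)
  structure(list(data = as.matrix(x), fs = fs %||% 500, subject_id = ""),
            class = "nf_meg")
}

#' Resample a MEG recording
#'
#' Polyphase windowed-sinc resampling of each sensor: every output sample is
#' an anti-aliased interpolation of the input at position `m * fs_in/fs_out`,
#' with the sinc cutoff placed at the output Nyquist when downsampling.  Each
#' polyphase tap set is normalised to unit sum, so constant signals are
#' preserved exactly and the passband gain is exactly 1 at DC.  Output length
#' is `round(n * fs_out / fs_in)`; edges use reflection.
#'
#' @param rec An `nf_meg` or sensors-x-samples matrix.
#' @param fs_out Target rate (Hz), at most the input rate.
#' @param fs_in Input rate, taken from the recording when omitted.
#' @param half_width Half-width of the interpolation kernel in zero crossings.
#' @return An `nf_meg` at `fs_out`.
#' @export
nf_resample <- function(rec, fs_out, fs_in = NULL, half_width = 10) {
  rec <- as_meg(rec, fs_in)
  if (fs_out <= 0) stop("fs_out must be positive")
  if (fs_out > rec$fs) stop("upsampling above the input rate is not supported")
  if (fs_out == rec$fs) return(rec)
  n_in <- ncol(rec$data)
  n_out <- round(n_in * fs_out / rec$fs)
  r <- fs_out / rec$fs                      # < 1: cutoff at output Nyquist
  K <- ceiling(half_width / r)
  pos <- (seq_len(n_out) - 1) / r           # 0-based input-domain positions
  base <- floor(pos)
  offs <- seq(-K + 1, K)
  # tap index matrix (n_out x taps), reflected at the edges
  idx <- outer(base, offs, `+`)             # 0-based
  idx <- abs(idx)                           # reflect left edge
  idx <- ifelse(idx > n_in - 1, 2 * (n_in - 1) - idx, idx)
  frac <- pos - base
  targ <- -outer(frac, offs, `-`)           # (j - pos) per tap
  snc <- function(z) ifelse(z == 0, 1, sin(pi * z) / (pi * z))
  w <- snc(targ * r) * 0.5 * (1 + cos(pi * pmin(abs(targ) / K, 1)))  # Hann
  w <- w / rowSums(w)                       # exact DC / unit gain
  out <- matrix(0, nrow(rec$data), n_out)
  for (s in seq_len(nrow(rec$data))) {
    xs <- rec$data[s, ]
    out[s, ] <- rowSums(w * matrix(xs[idx + 1], nrow(idx), ncol(idx)))
  }
  structure(list(data = out, fs = fs_out, subject_id = rec$subject_id),
            class = "nf_meg")
}

# Squared magnitude response of the zero-phase band-pass: raised-cosine
# transitions of width `tw` (Hz) centred on each edge, 1 inside the band.
bandpass_response <- function(freqs, lo, hi, tw) {
  edge <- function(f, c0, rising) {
    z <- (f - (c0 - tw / 2)) / tw
    z <- pmin(pmax(z, 0), 1)
    s <- 0.5 - 0.5 * cos(pi * z)
    if (rising) s else 1 - s
  }
  edge(freqs, lo, TRUE) * edge(freqs, hi, FALSE)
}

#' Band-pass filter a MEG recording
#'
#' Zero-phase band-pass filtering applied to each sensor independently.  The
#' filter is applied in the frequency domain on a reflect-padded signal with
#' a steep raised-cosine squared-magnitude response (transition width 5% of
#' the bandwidth), so narrow low-frequency bands are handled without the
#' numerical instability of high-order IIR cascades, re-filtering the same
#' band changes the passband power by only a few percent, and no energy is
#' created at any frequency.  Shape is preserved.
#'
#' @param rec An `nf_meg` or matrix.
#' @param band An `nf_band` or canonical band name.
#' @param transition Transition width as a fraction of the bandwidth.
#' @param fs Sampling rate when `rec` is a bare matrix.
#' @return Filtered `nf_meg`.
#' @export
nf_bandpass <- function(rec, band, transition = 0.05, fs = NULL) {
  rec <- as_meg(rec, fs)
  if (is.character(band)) band <- band_spec(band)
  nyq <- rec$fs / 2
  if (band$hi >= nyq) stop("band edge ", band$hi,
                           " Hz is at or above Nyquist (", nyq, " Hz)")
  n <- ncol(rec$data)
  np <- min(n - 1, max(64, ceiling(rec$fs / band$lo) * 4))
  tw <- max(transition * (band$hi - band$lo), 0.05)
  ntot <- n + 2 * np
  freqs <- seq(0, ntot - 1) * rec$fs / ntot
  freqs <- pmin(freqs, rec$fs - freqs)      # two-sided spectrum
  H2 <- bandpass_response(freqs, band$lo, band$hi, tw)
  out <- t(apply(rec$data, 1, function(x) {
    xp <- c(2 * x[1] - rev(x[2:(np + 1)]), x,
            2 * x[n] - rev(x[(n - np):(n - 1)]))
    y <- Re(stats::fft(stats::fft(xp) * H2, inverse = TRUE)) / ntot
    y[(np + 1):(np + n)]
  }))
  structure(list(data = out, fs = rec$fs, subject_id = rec$subject_id),
            class = "nf_meg")
}

#' Extract a fixed-length segment
#'
#' Returns a contiguous window of `n_samples` starting at `offset` (0-based).
#' The acquisition protocol guarantees at least 120 s of data, i.e. 60000
#' samples at 500 Hz, from which the canonical 8192-sample segment is cut.
#'
#' @param rec An `nf_meg` or matrix.
#' @param n_samples Window length (default 8192).
#' @param offset 0-based start sample.
#' @return Segmented `nf_meg` of shape (sensors, n_samples).
#' @export
nf_segment <- function(rec, n_samples = 8192, offset = 0) {
  rec <- as_meg(rec)
  n <- ncol(rec$data)
  if (n < offset + n_samples)
    stop("recording too short: ", n, " samples < offset + ", n_samples,
         " (the protocol guarantees >= 120 s, i.e. 60000 samples at 500 Hz)")
  rec$data <- rec$data[, (offset + 1):(offset + n_samples), drop = FALSE]
  rec
}

#' Zero-pad a volume to a target shape
#'
#' Padding is split evenly per axis with the extra voxel on the trailing side;
#' [nf_crop_volume()] inverts it exactly.
#'
#' @param volume An `nf_mri` or 3D array.
#' @param target Target shape (default `c(192, 192, 192)`).
#' @return Padded object of the same type.
#' @export
nf_pad_volume <- function(volume, target = c(192, 192, 192)) {
  x <- if (inherits(volume, "nf_mri")) volume$data else volume
  d <- dim(x)
  if (any(target < d)) stop("target shape must be >= source shape on all axes")
  lo <- (target - d) %/% 2
  out <- array(0, target)
  out[lo[1] + seq_len(d[1]), lo[2] + seq_len(d[2]), lo[3] + seq_len(d[3])] <- x
  if (inherits(volume, "nf_mri")) { volume$data <- out; volume } else out
}

#' @rdname nf_pad_volume
#' @param source Original shape to crop back to.
#' @export
nf_crop_volume <- function(volume, source) {
  x <- if (inherits(volume, "nf_mri")) volume$data else volume
  d <- dim(x)
  lo <- (d - source) %/% 2
  out <- x[lo[1] + seq_len(source[1]), lo[2] + seq_len(source[2]),
           lo[3] + seq_len(source[3]), drop = FALSE]
  if (inherits(volume, "nf_mri")) { volume$data <- out; volume } else out
}

#' Normalise intensities
#'
#' `zscore` maps to mean 0 / SD 1 over all elements; `unit_range` maps to
#' \[0, 1\].  Constant inputs return all zeros by convention.
#'
#' @param x An `nf_meg`, `nf_mri`, matrix or array.
#' @param mode `"zscore"` or `"unit_range"`.
#' @return Same type as the input.
#' @export
nf_normalize <- function(x, mode = c("zscore", "unit_range")) {
  mode <- match.arg(mode)
  dat <- if (inherits(x, c("nf_meg", "nf_mri"))) x$data else x
  if (!all(is.finite(dat))) stop("input must be finite")
  r <- range(dat)
  out <- if (r[1] == r[2]) {
    dat * 0
  } else if (mode == "zscore") {
    # population SD so that the output SD is exactly 1
    (dat - mean(dat)) / sqrt(mean((dat - mean(dat))^2))
  } else {
    (dat - r[1]) / (r[2] - r[1])
  }
  if (inherits(x, c("nf_meg", "nf_mri"))) { x$data <- out; x } else out
}

#' Band-power of a recording via Welch's method
#'
#' Mean power in `[lo, hi]` Hz across sensors, estimated from modified
#' periodograms of Hann-windowed segments.  Used by the generator tests and
#' the band-wise analyses.
#'
#' @param rec An `nf_meg` or matrix.
#' @param band An `nf_band` or band name.
#' @param nperseg Segment length for Welch averaging.
#' @param fs Sampling rate for bare matrices.
#' @return Scalar mean band power.
#' @export
band_power <- function(rec, band, nperseg = 256, fs = NULL) {
  rec <- as_meg(rec, fs)
  if (is.character(band)) band <- band_spec(band)
  N <- ncol(rec$data)
  nperseg <- min(nperseg, N)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / (nperseg + 1))
  starts <- seq(1, N - nperseg + 1, by = max(1, nperseg %/% 2))
  freqs <- seq(0, nperseg - 1) * rec$fs / nperseg
  sel <- freqs >= band$lo & freqs <= band$hi & freqs <= rec$fs / 2
  pows <- vapply(seq_len(nrow(rec$data)), function(s) {
    mean(vapply(starts, function(o) {
      seg <- rec$data[s, o:(o + nperseg - 1)] * win
      sp <- Mod(stats::fft(seg))^2 / sum(win^2)
      mean(sp[sel])
    }, 0))
  }, 0)
  mean(pows)
}
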