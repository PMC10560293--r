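# LFP band power: DPSS multitaper spectrogram, baseline z-scoring,
# channel selection, Welch PSD for QC, and velocity-matched resampling.

# Cache DPSS tapers across calls (they depend only on n, nw, k).
.dpss_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' First `k` DPSS sequences of length `n` with time-bandwidth product
#' `nw`, computed as the top eigenvectors of the standard symmetric
#' tridiagonal form of the spectral-concentration problem.
#'
#' @param n sequence length, samples.
#' @param nw time-bandwidth product.
#' @param k number of tapers (at most `2 * nw - 1` is well concentrated).
#' @return n x k matrix, columns unit-energy tapers.
#' @export
dpss_tapers <- function(n, nw = 2, k = 3) {
  key <- paste(n, nw, k, sep = "_")
  if (!is.null(.dpss_cache[[key]])) return(.dpss_cache[[key]])
  W <- nw / n
  t <- seq_len(n) - 1
  diag_v <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * W)
  off_v <- (t[-1] * (n - t[-1]) / 2)[seq_len(n - 1)]
  A <- Matrix::bandSparse(n, n, k = c(-1, 0, 1),
                          diagonals = list(off_v, diag_v, off_v),
                          symmetric = FALSE)
  # shift-invert just above the Gershgorin bound: fast and reliable for
  # the largest (most concentrated) eigenpairs at any window length
  ub <- max(diag_v + c(0, off_v) + c(off_v, 0)) + 1
  ev <- tryCatch(
    RSpectra::eigs_sym(A, k = k, which = "LM", sigma = ub),
    error = function(e) RSpectra::eigs_sym(A, k = k, which = "LA",
                                           opts = list(maxitr = 10000)))
  tap <- ev$vectors[, order(ev$values, decreasing = TRUE), drop = FALSE]
  # fix sign convention: each taper's mean (odd ones: initial slope) >= 0
  for (j in seq_len(k)) {
    s <- sum(tap[, j])
    if (abs(s) < 1e-8) s <- tap[2, j] - tap[1, j]
    if (s < 0) tap[, j] <- -tap[, j]
  }
  .dpss_cache[[key]] <- tap
  tap
}

# Multitaper PSD of one window (mean over tapers of |fft|^2 / fs),
# one-sided.  Returns list(freq, psd).
multitaper_psd <- function(x, fs, tapers) {
  n <- length(x)
  nf <- floor(n / 2) + 1
  acc <- numeric(nf)
  for (j in seq_len(ncol(tapers))) {
    X <- stats::fft(x * tapers[, j])[seq_len(nf)]
    acc <- acc + (Mod(X)^2) / fs
  }
  list(freq = (seq_len(nf) - 1) * fs / n, psd = acc / ncol(tapers))
}

#' Band-power time course with baseline z-scoring
#'
#' Non-overlapping windows of `window_s` seconds; each window's DPSS
#' multitaper PSD is integrated over `band` and the resulting series is
#' z-scored to the mean and SD of the baseline windows.
#'
#' @param lfp an `lfp_trace` (see [simulate_lfp()]) or a numeric vector
#'   (then supply `fs`).
#' @param band frequency band `c(lo, hi)`, Hz; theta is 5-11 Hz, fast
#'   gamma 50-110 Hz.
#' @param fs sampling rate, Hz, when `lfp` is a plain vector.
#' @param window_s spectrogram window, s.
#' @param nw,k multitaper time-bandwidth product and taper count.
#' @param baseline_s time range `c(start, end)` of the baseline epoch used
#'   for z-scoring; default the whole trace.
#' @return data.frame: `time` (window centers, s), `power` (raw band
#'   integral), `z`.
#' @export
band_power <- function(lfp, band, fs = NULL, window_s = 1, nw = 2, k = 3,
                       baseline_s = NULL) {
  if (inherits(lfp, "lfp_trace")) { x <- lfp$samples; fs <- lfp$fs }
  else x <- as.numeric(lfp)
  if (is.null(fs)) stop("fs required for a plain vector")
  if (band[2] > fs / 2) stop("band exceeds the Nyquist frequency")
  n_win <- floor(length(x) / (window_s * fs))
  if (n_win < 1) stop("trace shorter than one window")
  wlen <- round(window_s * fs)
  tapers <- dpss_tapers(wlen, nw, k)
  freq <- (seq_len(floor(wlen / 2) + 1) - 1) * fs / wlen
  in_band <- freq >= band[1] & freq <= band[2]
  df <- fs / wlen
  power <- vapply(seq_len(n_win), function(w) {
    seg <- x[((w - 1) * wlen + 1):(w * wlen)]
    sum(multitaper_psd(seg, fs, tapers)$psd[in_band]) * df
  }, numeric(1))
  time <- (seq_len(n_win) - 0.5) * window_s
  if (is.null(baseline_s)) baseline_s <- range(time)
  bl <- power[time >= baseline_s[1] & time <= baseline_s[2]]
  z <- (power - mean(bl)) / stats::sd(bl)
  data.frame(time = time, power = power, z = z)
}

#' Welch power spectral density (QC)
#'
#' Hann-windowed segments with 50% overlap, averaged periodograms.
#'
#' @param x numeric signal.
#' @param fs sampling rate, Hz.
#' @param window_s segment length, s.
#' @return data.frame: `freq`, `psd`.
#' @export
welch_psd <- function(x, fs, window_s = 1) {
  wlen <- round(window_s * fs)
  step <- floor(wlen / 2)
  starts <- seq(1, length(x) - wlen + 1, by = step)
  h <- 0.5 - 0.5 * cos(2 * pi * (seq_len(wlen) - 1) / (wlen - 1))
  norm <- sum(h^2) * fs
  nf <- floor(wlen / 2) + 1
  acc <- numeric(nf)
  for (s in starts) {
    X <- stats::fft(x[s:(s + wlen - 1)] * h)[seq_len(nf)]
    acc <- acc + Mod(X)^2 / norm
  }
  data.frame(freq = (seq_len(nf) - 1) * fs / wlen, psd = acc / length(starts))
}

#' Pick the channel with the highest theta power
#'
#' @param lfp_matrix channels x samples.
#' @param fs sampling rate, Hz.
#' @param band band used for selection, Hz.
#' @return index of the selected channel.
#' @export
select_channel <- function(lfp_matrix, fs, band = c(5, 11)) {
  pw <- apply(lfp_matrix, 1, function(ch) {
    p <- welch_psd(ch, fs)
    sum(p$psd[p$freq >= band[1] & p$freq <= band[2]])
  })
  which.max(pw)
}

#' Velocity-matched resampling of a band-power series
#'
#' For each baseline time bin, the paired-epoch bin whose mean running
#' speed is closest (absolute difference; exact ties take the first index)
#' is selected, with replacement.  Comparing the resampled paired-epoch
#' power to baseline removes power differences that merely track running
#' speed.
#'
#' @param power paired-epoch band power per 1 s bin.
#' @param speed paired-epoch mean speed per bin, cm/s.
#' @param baseline_speed baseline-epoch mean speed per bin.
#' @param seed seed (reserved for stochastic tie handling; matching itself
#'   is deterministic).
#' @return resampled power vector, one value per baseline bin.
#' @export
velocity_matched_resample <- function(power, speed, baseline_speed,
                                      seed = 1) {
  if (!length(power)) stop("empty paired epoch")
  if (length(power) != length(speed)) stop("power/speed length mismatch")
  idx <- vapply(baseline_speed, function(v) which.min(abs(speed - v)),
                integer(1))
  power[idx]
}
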