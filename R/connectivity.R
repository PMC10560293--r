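# Monosynaptic connectivity from cross-correlograms: pointwise 99% CI
# detection against an ISI-permutation null, and time-resolved transmission
# probability (post-window minus pre-window spiking probability).

#' Spike-train cross-correlogram
#'
#' Counts of B-spike lags relative to each A spike, in `bin_ms` bins over
#' `[-window_ms, +window_ms)`.
#'
#' @param a,b sorted spike-time vectors, s (A is the reference train).
#' @param window_ms half-width of the correlogram, ms.
#' @param bin_ms lag bin width, ms.
#' @return list: `counts`, `lag_ms` (bin lower edges), `n_ref`.
#' @export
spike_ccg <- function(a, b, window_ms = 50, bin_ms = 1) {
  W <- window_ms / 1000
  bw <- bin_ms / 1000
  nbin <- 2L * as.integer(round(W / bw))
  counts <- integer(nbin)
  if (length(a) && length(b)) {
    lo <- findInterval(a - W, b)
    hi <- findInterval(a + W - 1e-12, b)
    ni <- hi - lo
    keep <- ni > 0
    if (any(keep)) {
      ai <- rep.int(a[keep], ni[keep])
      bi <- sequence(ni[keep]) + rep.int(lo[keep], ni[keep])
      d <- b[bi] - ai
      k <- floor((d + W) / bw) + 1
      k <- k[k >= 1 & k <= nbin]
      counts <- tabulate(k, nbins = nbin)
    }
  }
  list(counts = counts,
       lag_ms = (seq_len(nbin) - 1) * bin_ms - window_ms,
       n_ref = length(a))
}

# Permute B's inter-spike intervals (rate- and ISI-marginal-preserving null).
isi_shuffle <- function(b) {
  if (length(b) < 3) return(b)
  b[1] + c(0, cumsum(sample(diff(b))))
}

#' Detect putative monosynaptic pairs
#'
#' For each ordered pair (A, B) the cross-correlogram is compared, bin by
#' bin over the 5 ms following an A spike, with a null built from
#' `n_shuffles` ISI permutations of B.  A pair is flagged excitatory if any
#' of those bins exceeds the pointwise 99% CI (above the 99.5th percentile
#' of the shuffles) and inhibitory if any falls below the 0.5th percentile.
#' The CI is pointwise, not family-wise, so the null flag rate per pair is
#' roughly `1 - 0.995^5` per sign; measure it on simulated independent
#' pairs rather than assuming it.
#'
#' @param spikes list of sorted spike-time vectors, s.
#' @param pairs optional 2-column matrix of (pre, post) indices to test;
#'   default all ordered pairs.
#' @param n_shuffles null permutations per pair.
#' @param window_ms stored correlogram half-width, ms.
#' @param min_spikes trains with fewer spikes are skipped.
#' @param seed integer seed for the permutations.
#' @return data.frame: `pre`, `post`, `sign`
#'   (`"excitatory"/"inhibitory"/"none"`), `peak_bin_ms`, `n_pre`, `n_post`,
#'   `skipped`.
#' @export
detect_monosynaptic_pairs <- function(spikes, pairs = NULL,
                                      n_shuffles = 1000, window_ms = 50,
                                      min_spikes = 100, seed = 1) {
  n <- length(spikes)
  if (is.null(pairs)) {
    pairs <- as.matrix(expand.grid(pre = seq_len(n), post = seq_len(n)))
    pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  }
  set.seed(derive_seed(seed, "ccg_null"))
  res <- data.frame(pre = pairs[, 1], post = pairs[, 2], sign = "none",
                    peak_bin_ms = NA_real_, n_pre = NA_integer_,
                    n_post = NA_integer_, skipped = FALSE,
                    stringsAsFactors = FALSE)
  for (r in seq_len(nrow(pairs))) {
    a <- spikes[[pairs[r, 1]]]
    b <- spikes[[pairs[r, 2]]]
    res$n_pre[r] <- length(a); res$n_post[r] <- length(b)
    if (length(a) < min_spikes || length(b) < min_spikes) {
      res$skipped[r] <- TRUE
      next
    }
    obs <- spike_ccg(a, b, window_ms = 5, bin_ms = 1)$counts[6:10]
    null_counts <- matrix(0L, n_shuffles, 5L)
    for (s in seq_len(n_shuffles)) {
      bs <- isi_shuffle(b)
      null_counts[s, ] <- spike_ccg(a, bs, window_ms = 5,
                                    bin_ms = 1)$counts[6:10]
    }
    hi <- apply(null_counts, 2, stats::quantile, 0.995, names = FALSE)
    lo <- apply(null_counts, 2, stats::quantile, 0.005, names = FALSE)
    exc <- obs > hi
    inh <- obs < lo
    if (any(exc)) {
      res$sign[r] <- "excitatory"
      res$peak_bin_ms[r] <- which.max(obs - hi) - 0.5
    } else if (any(inh)) {
      res$sign[r] <- "inhibitory"
      res$peak_bin_ms[r] <- which.min(obs - lo) - 0.5
    }
  }
  res
}

#' Time-resolved transmission probability
#'
#' The session is cut into `bin_s` windows; within each, the A->B
#' cross-correlogram is normalised by the number of A spikes (a spiking
#' probability given one A spike) and the probability mass at +1..+5 ms is
#' baseline-corrected by subtracting the mass at -5..-1 ms, cancelling
#' rate changes in B that are independent of A.
#'
#' @param a,b sorted spike-time vectors, s.
#' @param duration_s session length, s.
#' @param bin_s window length, s.
#' @return data.frame: `t_start`, `n_pre`, `prob` (`NA` where the window
#'   has no A spikes); mean over windows estimates the connection efficacy.
#' @export
transmission_probability <- function(a, b, duration_s, bin_s = 10) {
  starts <- seq(0, duration_s - 1e-9, by = bin_s)
  out <- data.frame(t_start = starts, n_pre = 0L, prob = NA_real_)
  for (i in seq_along(starts)) {
    t0 <- starts[i]; t1 <- min(t0 + bin_s, duration_s)
    aw <- a[a >= t0 & a < t1]
    bw <- b[b >= t0 - 0.01 & b < t1 + 0.01]
    out$n_pre[i] <- length(aw)
    if (!length(aw)) next
    cc <- spike_ccg(aw, bw, window_ms = 5, bin_ms = 1)$counts
    # bins: 1..5 cover [-5,0) ms, 6..10 cover [0,5) ms
    plus <- sum(cc[7:10])    # [1, 5) ms after
    minus <- sum(cc[1:4])    # [-5, -1) ms before
    out$prob[i] <- (plus - minus) / length(aw)
  }
  out
}
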