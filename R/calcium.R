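# Hippocampal CA1 calcium analysis: event binarization, 2D rate maps on a
# circular arena, shuffle-based place-cell classification, cross-session
# spatial correlation and position-matched downsampling.

#' Binarize deconvolved calcium traces into events
#'
#' An event is any frame where the deconvolved trace exceeds 3 times the
#' SD of the whole trace (zeros included), per cell.  The threshold scales
#' with the trace, so rescaling a trace leaves its events unchanged.
#'
#' @param traces cells x frames matrix (or a single-cell vector) of
#'   nonnegative deconvolved activity.
#' @param sd_mult threshold multiplier.
#' @return binary matrix (or vector) of the same shape.
#' @export
binarize_events <- function(traces, sd_mult = 3) {
  if (is.null(dim(traces))) {
    return(as.integer(traces > sd_mult * stats::sd(traces)))
  }
  thr <- apply(traces, 1, stats::sd) * sd_mult
  out <- (traces > thr) * 1L
  dimnames(out) <- dimnames(traces)
  out
}

# Spatial bin grid for a circular arena; returns the per-frame bin index
# (NA outside the arena) and the mask of in-arena bins.
arena_bins <- function(position, arena_diameter, bin_cm) {
  R <- arena_diameter / 2
  nb <- ceiling(arena_diameter / bin_cm)
  ix <- floor((position[, 1] + R) / bin_cm) + 1L
  iy <- floor((position[, 2] + R) / bin_cm) + 1L
  ok <- ix >= 1 & ix <= nb & iy >= 1 & iy <= nb
  idx <- ifelse(ok, (iy - 1L) * nb + ix, NA_integer_)
  centers <- (seq_len(nb) - 0.5) * bin_cm - R
  cx <- rep(centers, times = nb)
  cy <- rep(centers, each = nb)
  mask <- sqrt(cx^2 + cy^2) <= R + bin_cm / 2
  list(idx = idx, nb = nb, mask = mask)
}

# 2D Gaussian smoothing (separable) honoring NA bins: values and validity
# weights are convolved separately and their ratio taken.
smooth_2d <- function(m, sd_bins) {
  if (sd_bins <= 0) return(m)
  na <- is.na(m)
  v <- ifelse(na, 0, m)
  w <- ifelse(na, 0, 1)
  sm <- function(z) {
    z <- apply(z, 2, gauss_smooth, sd = sd_bins)
    t(apply(z, 1, gauss_smooth, sd = sd_bins))
  }
  out <- sm(v) / sm(w)
  out[na] <- NA_real_
  out
}

#' 2D calcium-event rate map
#'
#' Events per second per `bin_cm` square bin of the circular arena,
#' excluding frames slower than `speed_floor`, with bins outside the arena
#' masked.  Returns both the raw map (used for information scores, with an
#' occupancy floor) and a 2D-Gaussian-smoothed map (used for spatial
#' correlations).
#'
#' @param events binary event vector for one cell (frames).
#' @param position frames x 2 matrix of (x, y), cm, arena-centered.
#' @param speed per-frame speed, cm/s.
#' @param fs frame rate, Hz.
#' @param arena_diameter cm.
#' @param bin_cm square bin side, cm.
#' @param smooth_sd_bins smoothing SD in bins.
#' @param speed_floor cm/s.
#' @return list of class `rate_map_2d`: `rate`, `smoothed`, `occupancy`
#'   (s), all nb x nb with `NA` outside the arena or never occupied, `nb`,
#'   `bin_cm`.
#' @export
rate_map_2d <- function(events, position, speed, fs, arena_diameter = 36,
                        bin_cm = 1.75, smooth_sd_bins = 2,
                        speed_floor = 2) {
  ab <- arena_bins(position, arena_diameter, bin_cm)
  keep <- speed >= speed_floor & !is.na(ab$idx)
  if (!any(keep)) stop("no occupancy above the speed floor")
  nb2 <- ab$nb^2
  occ <- tabulate(ab$idx[keep], nbins = nb2) / fs
  cnt <- tabulate(ab$idx[keep & events > 0], nbins = nb2)
  rate <- cnt / occ
  rate[occ == 0] <- NA_real_
  rate[!ab$mask] <- NA_real_
  occ[!ab$mask] <- NA_real_
  rate_m <- matrix(rate, ab$nb, ab$nb)
  occ_m <- matrix(occ, ab$nb, ab$nb)
  structure(list(rate = rate_m, smoothed = smooth_2d(rate_m, smooth_sd_bins),
                 occupancy = occ_m, nb = ab$nb, bin_cm = bin_cm),
            class = "rate_map_2d")
}

# Skaggs information of a binned event map with an occupancy floor.
info_from_counts <- function(cnt, occ, occ_floor = 0.1) {
  ok <- occ >= occ_floor
  if (!any(ok)) return(0)
  spatial_information(cnt[ok] / occ[ok], occ[ok])
}

#' Shuffle-based place-cell test
#'
#' Spatial information (bits/s, events as spikes, raw map with a 0.1 s
#' occupancy floor) is compared with the 95th percentile of `n_shuffles`
#' circular time-shifts of the event train (minimum shift `min_shift_s` to
#' break the position coupling).  A cell is a place cell when its
#' information exceeds that threshold and its overall mean event rate is
#' at least `min_rate` Hz.
#'
#' @inheritParams rate_map_2d
#' @param n_shuffles shuffle count.
#' @param min_rate event-rate floor, Hz.
#' @param min_shift_s minimum circular shift, s.
#' @param occ_floor bin occupancy floor, s.
#' @param seed integer seed for the shuffle offsets.
#' @return list: `is_place_cell`, `si` (bits/s), `threshold` (95th
#'   percentile of the null), `mean_rate` (Hz).
#' @export
place_cell_test <- function(events, position, speed, fs,
                            arena_diameter = 36, bin_cm = 1.75,
                            n_shuffles = 1000, min_rate = 0.1,
                            min_shift_s = 20, occ_floor = 0.1,
                            speed_floor = 2, seed = 1) {
  n <- length(events)
  ab <- arena_bins(position, arena_diameter, bin_cm)
  keep <- speed >= speed_floor & !is.na(ab$idx)
  if (!any(keep)) stop("degenerate occupancy")
  nb2 <- ab$nb^2
  occ <- tabulate(ab$idx[keep], nbins = nb2) / fs
  ev_frames <- which(events > 0)
  si_of <- function(frames) {
    f <- frames[keep[frames]]
    info_from_counts(tabulate(ab$idx[f], nbins = nb2), occ, occ_floor)
  }
  si <- si_of(ev_frames)
  set.seed(derive_seed(seed, "place_shuffle"))
  min_shift <- round(min_shift_s * fs)
  shifts <- sample(seq(min_shift, n - min_shift), n_shuffles, replace = TRUE)
  null_si <- vapply(shifts, function(s)
    si_of(((ev_frames - 1 + s) %% n) + 1), numeric(1))
  threshold <- stats::quantile(null_si, 0.95, names = FALSE)
  mean_rate <- length(ev_frames) / (n / fs)
  list(is_place_cell = si > threshold && mean_rate >= min_rate,
       si = si, threshold = threshold, mean_rate = mean_rate)
}

#' Spatial correlation between two session rate maps
#'
#' Pearson correlation of the smoothed maps over bins valid in both; `NA`
#' when fewer than `min_bins` bins overlap.
#'
#' @param map_a,map_b [rate_map_2d()] results on the same grid.
#' @param min_bins minimum jointly valid bins.
#' @return correlation coefficient or `NA`.
#' @export
session_spatial_correlation <- function(map_a, map_b, min_bins = 10) {
  a <- map_a$smoothed; b <- map_b$smoothed
  if (!identical(dim(a), dim(b))) stop("maps are on different grids")
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < min_bins) return(NA_real_)
  if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) return(NA_real_)
  stats::cor(a[ok], b[ok])
}

#' Position-matched downsampling of two sessions
#'
#' Equalises spatial sampling before cross-session comparisons: within
#' each spatial bin, the session with more (speed-filtered, in-arena)
#' frames randomly drops frames, and their events, until the counts match.
#' Metrics (mean and peak event rate, spatial information, spatial
#' correlation between the two downsampled maps) are recomputed on each of
#' `n_iter` random drops and averaged.  Only two sessions are matched at a
#' time.
#'
#' @param events_a,events_b binary event vectors for the cell in each
#'   session.
#' @param position_a,position_b frames x 2 positions, cm.
#' @param speed_a,speed_b per-frame speed, cm/s.
#' @param fs frame rate, Hz.
#' @param n_iter downsampling iterations.
#' @param seed integer seed.
#' @inheritParams rate_map_2d
#' @param occ_floor occupancy floor for information, s.
#' @return list: `metrics` data.frame (session a/b rows: `mean_rate`,
#'   `peak_rate`, `si`), `spatial_corr`, `n_iter`.
#' @export
position_matched_downsample <- function(events_a, position_a, speed_a,
                                        events_b, position_b, speed_b,
                                        fs, n_iter = 50, seed = 1,
                                        arena_diameter = 36, bin_cm = 1.75,
                                        smooth_sd_bins = 2,
                                        speed_floor = 2, occ_floor = 0.1) {
  ab_a <- arena_bins(position_a, arena_diameter, bin_cm)
  ab_b <- arena_bins(position_b, arena_diameter, bin_cm)
  keep_a <- which(speed_a >= speed_floor & !is.na(ab_a$idx))
  keep_b <- which(speed_b >= speed_floor & !is.na(ab_b$idx))
  bins_a <- ab_a$idx[keep_a]; bins_b <- ab_b$idx[keep_b]
  nb2 <- ab_a$nb^2
  na_bin <- tabulate(bins_a, nbins = nb2)
  nb_bin <- tabulate(bins_b, nbins = nb2)
  target <- pmin(na_bin, nb_bin)
  if (all(target == 0)) stop("sessions have no overlapping occupancy")
  by_a <- split(keep_a, bins_a)
  by_b <- split(keep_b, bins_b)
  set.seed(derive_seed(seed, "downsample"))
  acc <- matrix(0, 2, 3,
                dimnames = list(c("a", "b"), c("mean_rate", "peak_rate", "si")))
  corr_acc <- 0; corr_n <- 0
  one <- function(by, tgt) {
    kept <- lapply(names(by), function(k) {
      b <- as.integer(k); fr <- by[[k]]
      if (tgt[b] == 0) return(integer(0))
      if (length(fr) > tgt[b]) sample(fr, tgt[b]) else fr
    })
    unlist(kept)
  }
  for (it in seq_len(n_iter)) {
    fa <- one(by_a, target); fb <- one(by_b, target)
    occ <- target / fs     # identical for both sessions by construction
    cnt_a <- tabulate(ab_a$idx[fa[events_a[fa] > 0]], nbins = nb2)
    cnt_b <- tabulate(ab_b$idx[fb[events_b[fb] > 0]], nbins = nb2)
    dur <- sum(occ)
    rate_a <- cnt_a / occ; rate_a[occ == 0] <- NA_real_
    rate_b <- cnt_b / occ; rate_b[occ == 0] <- NA_real_
    acc["a", ] <- acc["a", ] + c(sum(cnt_a) / dur,
                                 max(rate_a, na.rm = TRUE),
                                 info_from_counts(cnt_a, occ, occ_floor))
    acc["b", ] <- acc["b", ] + c(sum(cnt_b) / dur,
                                 max(rate_b, na.rm = TRUE),
                                 info_from_counts(cnt_b, occ, occ_floor))
    ma <- smooth_2d(matrix(ifelse(ab_a$mask, rate_a, NA_real_),
                           ab_a$nb, ab_a$nb), smooth_sd_bins)
    mb <- smooth_2d(matrix(ifelse(ab_b$mask, rate_b, NA_real_),
                           ab_b$nb, ab_b$nb), smooth_sd_bins)
    ok <- !is.na(ma) & !is.na(mb)
    if (sum(ok) >= 10 && stats::sd(ma[ok]) > 0 && stats::sd(mb[ok]) > 0) {
      corr_acc <- corr_acc + stats::cor(ma[ok], mb[ok])
      corr_n <- corr_n + 1
    }
  }
  list(metrics = as.data.frame(acc / n_iter),
       spatial_corr = if (corr_n > 0) corr_acc / corr_n else NA_real_,
       n_iter = n_iter)
}
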