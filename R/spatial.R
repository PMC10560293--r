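# Single-cell spatial coding: trial x position firing-rate maps and the
# derived metrics (Skaggs spatial information in bits/s, trial-to-trial
# stability, crest factor), functional classification (interneuron /
# spatial / putative grid) and shuffle-thresholded field widths.

#' Trial x position firing-rate map
#'
#' Divides the track into `bin_cm` bins and each trial's dwell time and
#' spike count among them, omitting all periods (both spikes and occupancy)
#' when the animal ran slower than `speed_floor`.  Bins a trial never
#' occupied above the speed floor are `NA`, not 0 Hz.
#'
#' @param spikes spike times, s, for one cell.
#' @param trace a behavior trace (see [preprocess_position()]).
#' @param bin_cm spatial bin width, cm.
#' @param speed_floor cm/s; slower periods are excluded.
#' @return list of class `spatial_rate_map`: `rate` and `occupancy`
#'   (trials x bins), `counts`, `bin_cm`, `bin_centers`.
#' @export
compute_rate_map <- function(spikes, trace, bin_cm = 2, speed_floor = 2) {
  L <- attr(trace, "track_length") %||% 400
  fs <- attr(trace, "fs") %||% 50
  nb <- ceiling(L / bin_cm)
  n_trials <- max(trace$trial)
  keep <- trace$speed >= speed_floor
  bin <- pmin(nb, floor(trace$position / bin_cm) + 1L)
  occ <- matrix(0, n_trials, nb)
  tb <- table(factor(trace$trial[keep], levels = seq_len(n_trials)),
              factor(bin[keep], levels = seq_len(nb)))
  occ[] <- as.numeric(tb) / fs

  counts <- matrix(0, n_trials, nb)
  if (length(spikes)) {
    spikes <- spikes[spikes >= trace$time[1] & spikes <= trace$time[nrow(trace)]]
    at <- trace_at_times(trace, spikes)
    ok <- at$speed >= speed_floor
    if (any(ok)) {
      sb <- pmin(nb, floor(at$position[ok] / bin_cm) + 1L)
      tc <- table(factor(at$trial[ok], levels = seq_len(n_trials)),
                  factor(sb, levels = seq_len(nb)))
      counts[] <- as.numeric(tc)
    }
  }
  rate <- counts / occ
  rate[occ == 0] <- NA_real_
  structure(list(rate = rate, occupancy = occ, counts = counts,
                 bin_cm = bin_cm,
                 bin_centers = (seq_len(nb) - 0.5) * bin_cm,
                 track_length = L),
            class = "spatial_rate_map")
}

#' Occupancy-weighted mean tuning curve over a block of trials
#'
#' @param map a [compute_rate_map()] result.
#' @param trials trial indices to average; default all.
#' @return numeric vector of mean rates per bin (Hz), `NA` where never
#'   occupied.
#' @export
tuning_curve <- function(map, trials = NULL) {
  trials <- trials %||% seq_len(nrow(map$rate))
  weighted_tuning(map$rate[trials, , drop = FALSE],
                  map$occupancy[trials, , drop = FALSE])
}

#' Skaggs spatial information rate (bits/s)
#'
#' `I = sum_i p_i * lambda_i * log2(lambda_i / lambda_bar)` with occupancy
#' probabilities `p_i` and mean rate `lambda_bar = sum_i p_i lambda_i`.
#' Zero-rate bins contribute 0; a silent cell returns 0.  `NA` bins are
#' dropped and the occupancy renormalised.
#'
#' @param rates mean firing rate per bin, Hz.
#' @param occupancy dwell time (or probability) per bin; normalised
#'   internally.
#' @return information rate, bits/s (>= 0).
#' @export
spatial_information <- function(rates, occupancy) {
  ok <- !is.na(rates) & !is.na(occupancy) & occupancy > 0
  if (!any(ok)) return(0)
  p <- occupancy[ok] / sum(occupancy[ok])
  lam <- rates[ok]
  lbar <- sum(p * lam)
  if (lbar <= 0) return(0)
  pos <- lam > 0
  sum(p[pos] * lam[pos] * log2(lam[pos] / lbar))
}

#' Trial-to-trial spatial stability
#'
#' Each trial's rate vector is Gaussian-smoothed (SD `smooth_sd_cm`,
#' circular, matching the looped track), max-normalised, and Pearson
#' correlated with the preceding and following trials; the trial's score is
#' the mean of the two (single neighbor at the ends).  Zero-variance trials
#' give `NA` and are excluded from neighbor means.
#'
#' @param map a [compute_rate_map()] result.
#' @param smooth_sd_cm smoothing SD, cm.
#' @return numeric vector, one stability score per trial, in `[-1, 1]`.
#' @export
stability_score <- function(map, smooth_sd_cm = 2) {
  r <- map$rate
  n_trials <- nrow(r)
  if (n_trials < 2) stop("stability needs at least 2 trials")
  sm <- t(apply(r, 1, function(v) {
    v2 <- gauss_smooth(v, sd = smooth_sd_cm / map$bin_cm, circular = TRUE)
    mx <- max(v2, na.rm = TRUE)
    if (is.finite(mx) && mx > 0) v2 / mx else v2
  }))
  adj <- rep(NA_real_, n_trials - 1)
  for (i in seq_len(n_trials - 1)) {
    a <- sm[i, ]; b <- sm[i + 1, ]
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) > 2 && stats::sd(a[ok]) > 0 && stats::sd(b[ok]) > 0) {
      adj[i] <- stats::cor(a[ok], b[ok])
    }
  }
  out <- numeric(n_trials)
  out[1] <- adj[1]
  out[n_trials] <- adj[n_trials - 1]
  if (n_trials > 2) {
    for (i in 2:(n_trials - 1)) {
      out[i] <- mean(c(adj[i - 1], adj[i]), na.rm = TRUE)
      if (is.nan(out[i])) out[i] <- NA_real_
    }
  }
  out
}

#' Crest factor of a spatial tuning curve
#'
#' Peak value divided by the root mean square of the curve; 1 for a flat
#' curve, up to `sqrt(N)` for a single active bin out of `N`.  Measures how
#' peaked the spatial firing is, independent of overall rate.
#'
#' @param tuning nonnegative rate vector (NA bins dropped).
#' @return scalar >= 1.
#' @export
crest_factor <- function(tuning) {
  x <- tuning[!is.na(tuning)]
  if (!length(x) || all(x == 0)) stop("crest factor undefined for an all-zero curve")
  max(x) / sqrt(mean(x^2))
}

#' Functional classification of units
#'
#' Interneurons are units with mean firing rate > 15 Hz.  Spatial cells are
#' excitatory units whose mean baseline-epoch stability exceeds 0.2.
#' Putative grid cells are spatial cells whose spatial information averaged
#' over baseline trials exceeds 3 bits/s and whose tuning on the visual
#' gain-change trials decorrelates (Pearson r < 0.2) from the tuning on the
#' last normal trials - the gain manipulation dissociates path integration
#' from visual cues, to which grid cells are preferentially sensitive.
#'
#' @param maps list of [compute_rate_map()] results, one per cell.
#' @param epochs named list of trial ranges with at least `baseline`;
#'   `gain` enables the grid test.
#' @param stability_threshold,si_threshold,gain_threshold,rate_threshold
#'   classification thresholds (paper defaults).
#' @return data.frame: `cell`, `mean_rate`, `baseline_stability`,
#'   `baseline_si`, `gain_r`, `class` in
#'   `{"interneuron","putative_grid","spatial","other"}`.
#' @export
classify_cells <- function(maps, epochs,
                           stability_threshold = 0.2, si_threshold = 3,
                           gain_threshold = 0.2, rate_threshold = 15) {
  bl <- epochs$baseline
  has_gain <- !is.null(epochs$gain)
  n <- length(maps)
  out <- data.frame(cell = seq_len(n), mean_rate = NA_real_,
                    baseline_stability = NA_real_, baseline_si = NA_real_,
                    gain_r = NA_real_, class = "other",
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    m <- maps[[i]]
    out$mean_rate[i] <- sum(m$counts) / sum(m$occupancy)
    bl_tr <- seq(bl[1], bl[2])
    stab <- stability_score(structure(
      list(rate = m$rate[bl_tr, , drop = FALSE],
           occupancy = m$occupancy[bl_tr, , drop = FALSE],
           bin_cm = m$bin_cm), class = "spatial_rate_map"))
    out$baseline_stability[i] <- mean(stab, na.rm = TRUE)
    si_tr <- vapply(bl_tr, function(t_i)
      spatial_information(m$rate[t_i, ], m$occupancy[t_i, ]), numeric(1))
    out$baseline_si[i] <- mean(si_tr, na.rm = TRUE)
    if (has_gain) {
      g <- epochs$gain
      n_gain <- g[2] - g[1] + 1
      gain_tc <- tuning_curve(m, seq(g[1], g[2]))
      norm_tc <- tuning_curve(m, seq(g[1] - n_gain, g[1] - 1))
      ok <- !is.na(gain_tc) & !is.na(norm_tc)
      if (sum(ok) > 2 && stats::sd(gain_tc[ok]) > 0 &&
          stats::sd(norm_tc[ok]) > 0) {
        out$gain_r[i] <- stats::cor(gain_tc[ok], norm_tc[ok])
      }
    }
  }
  is_int <- out$mean_rate > rate_threshold
  is_spatial <- !is_int & !is.na(out$baseline_stability) &
    out$baseline_stability > stability_threshold
  is_grid <- is_spatial & has_gain & !is.na(out$gain_r) &
    out$gain_r < gain_threshold & out$baseline_si > si_threshold
  out$class[is_spatial] <- "spatial"
  out$class[is_grid] <- "putative_grid"
  out$class[is_int] <- "interneuron"
  out
}

# Local maxima of a curve (interior strict-on-the-right maxima).
find_peaks <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] >= x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
}

# Width of the peak at index p at half its height, linear interpolation at
# the crossings; clamped at the curve ends.
half_height_width <- function(x, p, bin_cm) {
  h <- x[p] / 2
  n <- length(x)
  left <- p
  while (left > 1 && !is.na(x[left - 1]) && x[left - 1] >= h) left <- left - 1
  lx <- if (left == 1 || is.na(x[left - 1])) left - 0.5 else {
    left - 1 + (h - x[left - 1]) / (x[left] - x[left - 1]) - 0.5
  }
  right <- p
  while (right < n && !is.na(x[right + 1]) && x[right + 1] >= h) right <- right + 1
  rx <- if (right == n || is.na(x[right + 1])) right - 0.5 else {
    right - 1 + (x[right] - h) / (x[right] - x[right + 1]) + 0.5
  }
  (rx - lx) * bin_cm
}

#' Field width with a spatial-shuffle detection threshold
#'
#' The trial block's rate map is averaged into a tuning curve; each trial
#' row is independently circularly rotated (by at least `min_shift_bins`)
#' `n_shuffles` times and re-averaged, and the 80th percentile of the
#' shuffled curves' peak heights sets the detection threshold.  Peaks of
#' the real curve above threshold are measured at half their height; the
#' maximum width is returned, or `NA` when no peak clears the threshold.
#'
#' @param map a [compute_rate_map()] result.
#' @param trials trial block to use (e.g. a 50-trial block); default all.
#' @param n_shuffles shuffle count.
#' @param min_shift_bins minimum circular rotation, bins.
#' @param seed integer seed for the shuffle rotations.
#' @return list: `width_cm` (NA if no field), `threshold`, `peaks` (bin
#'   indices of detected fields), `tuning`.
#' @export
field_width <- function(map, trials = NULL, n_shuffles = 1000,
                        min_shift_bins = 5, seed = 1) {
  trials <- trials %||% seq_len(nrow(map$rate))
  r <- map$rate[trials, , drop = FALSE]
  occ <- map$occupancy[trials, , drop = FALSE]
  tc <- weighted_tuning(r, occ)
  nb <- ncol(r)
  set.seed(derive_seed(seed, "field_width"))
  shuf_peaks <- numeric(n_shuffles)
  for (s in seq_len(n_shuffles)) {
    sh <- sample(seq(min_shift_bins, nb - min_shift_bins), length(trials),
                 replace = TRUE)
    rs <- r; os <- occ
    for (ti in seq_along(trials)) {
      idx <- ((seq_len(nb) - 1 + sh[ti]) %% nb) + 1
      rs[ti, ] <- r[ti, idx]
      os[ti, ] <- occ[ti, idx]
    }
    shuf_peaks[s] <- max(weighted_tuning(rs, os), na.rm = TRUE)
  }
  threshold <- stats::quantile(shuf_peaks, 0.8, names = FALSE)
  tc0 <- ifelse(is.na(tc), 0, tc)
  pk <- find_peaks(tc0)
  pk <- pk[tc0[pk] > threshold]
  if (!length(pk)) {
    return(list(width_cm = NA_real_, threshold = threshold,
                peaks = integer(0), tuning = tc))
  }
  widths <- vapply(pk, half_height_width, numeric(1), x = tc0,
                   bin_cm = map$bin_cm)
  list(width_cm = max(widths), threshold = threshold, peaks = pk,
       tuning = tc)
}
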