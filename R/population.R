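# Population-level analyses: cell-pair temporal correlations across epochs,
# trial x trial population similarity matrices, and remapping scores
# against the baseline spatial template.

# Time-bin index sets per epoch, from bin times and the behavior trace.
epoch_bins <- function(times, trace, epochs) {
  trial_of_bin <- trace_at_times(trace, pmin(pmax(times, trace$time[1]),
                                             trace$time[nrow(trace)]))$trial
  lapply(epochs, function(r) which(trial_of_bin >= r[1] & trial_of_bin <= r[2]))
}

#' Cell-pair temporal correlations across epochs
#'
#' Pearson correlations between the smoothed temporally binned firing
#' rates of cell pairs, computed separately within each epoch's time bins.
#' Only pairs of the supplied (spatially stable, non-interneuron) cells
#' whose baseline correlation is significant at `p_threshold` qualify.
#' The session-level statistic for an epoch pair is the Pearson
#' correlation (rho) between the vector of pair correlations in one epoch
#' and the same vector in the other: rho stays high when the co-firing
#' structure is preserved and collapses when it is reorganised.
#'
#' @param trm a [temporal_rate_matrix()] for the whole session.
#' @param trace the session's behavior trace (maps time bins to trials).
#' @param epochs named list of trial ranges; must include `baseline`.
#' @param cell_ids indices of qualifying cells (default all).
#' @param p_threshold baseline significance cut for pair inclusion.
#' @return list of class `pair_epoch_correlation`: `pairs` (data.frame
#'   with `cell_a`, `cell_b`, `baseline_p` and one `r_<epoch>` column per
#'   epoch) and `rho` (epoch x epoch matrix of session-level
#'   correlations).
#' @export
cellpair_correlations <- function(trm, trace, epochs, cell_ids = NULL,
                                  p_threshold = 0.05) {
  cell_ids <- cell_ids %||% seq_len(nrow(trm$rates))
  if (length(cell_ids) < 2) stop("need at least 2 qualifying cells")
  bins <- epoch_bins(trm$times, trace, epochs)
  if (!length(bins$baseline)) stop("baseline epoch has no time bins")
  cmb <- utils::combn(cell_ids, 2)
  R <- trm$rates
  base_idx <- bins$baseline
  n_pair <- ncol(cmb)
  keep <- logical(n_pair); pval <- numeric(n_pair)
  for (k in seq_len(n_pair)) {
    a <- R[cmb[1, k], base_idx]; b <- R[cmb[2, k], base_idx]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) next
    ct <- stats::cor.test(a, b)
    pval[k] <- ct$p.value
    keep[k] <- ct$p.value < p_threshold
  }
  if (sum(keep) < 2) stop("fewer than 2 significantly correlated baseline pairs")
  cmb <- cmb[, keep, drop = FALSE]
  pairs <- data.frame(cell_a = cmb[1, ], cell_b = cmb[2, ],
                      baseline_p = pval[keep])
  for (nm in names(epochs)) {
    idx <- bins[[nm]]
    r <- rep(NA_real_, ncol(cmb))
    if (length(idx) > 2) {
      for (k in seq_len(ncol(cmb))) {
        a <- R[cmb[1, k], idx]; b <- R[cmb[2, k], idx]
        if (stats::sd(a) > 0 && stats::sd(b) > 0) r[k] <- stats::cor(a, b)
      }
    }
    pairs[[paste0("r_", nm)]] <- r
  }
  ep <- names(epochs)
  rho <- matrix(NA_real_, length(ep), length(ep), dimnames = list(ep, ep))
  for (i in seq_along(ep)) for (j in seq_along(ep)) {
    x <- pairs[[paste0("r_", ep[i])]]; y <- pairs[[paste0("r_", ep[j])]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) > 2 && stats::sd(x[ok]) > 0 && stats::sd(y[ok]) > 0) {
      rho[i, j] <- stats::cor(x[ok], y[ok])
    }
  }
  structure(list(pairs = pairs, rho = rho),
            class = "pair_epoch_correlation")
}

#' Trial x trial population similarity matrix
#'
#' Concatenates every cell's trial x position rate matrix column-wise into
#' a population matrix and correlates trials (rows) pairwise (Pearson,
#' pairwise-complete over bins both trials occupied).
#'
#' @param maps list of [compute_rate_map()] results sharing the trial/bin
#'   grid.
#' @return trials x trials correlation matrix; `NA` where a trial has no
#'   usable variance.
#' @export
trial_similarity_matrix <- function(maps) {
  P <- do.call(cbind, lapply(maps, function(m) m$rate))
  suppressWarnings(stats::cor(t(P), use = "pairwise.complete.obs"))
}

#' Per-trial correlation to the baseline spatial template
#'
#' Each cell's baseline template is its mean tuning over the baseline
#' trials.  A trial's score correlates the cell's rate vector on that
#' trial with the template, averaged over cells (`method = "percell"`), or
#' correlates the concatenated population vectors (`method = "concat"`).
#' Within the baseline epoch the template is recomputed leaving the scored
#' trial out, so baseline scores are not inflated by self-correlation.
#'
#' @param maps list of [compute_rate_map()] results.
#' @param baseline_trials trial indices forming the template.
#' @param method `"percell"` (default) or `"concat"`.
#' @return numeric vector, one score per trial.
#' @export
baseline_template_correlation <- function(maps, baseline_trials = 1:50,
                                          method = c("percell", "concat")) {
  method <- match.arg(method)
  n_trials <- nrow(maps[[1]]$rate)
  out <- rep(NA_real_, n_trials)
  templates <- lapply(maps, function(m)
    weighted_tuning(m$rate[baseline_trials, , drop = FALSE],
                    m$occupancy[baseline_trials, , drop = FALSE]))
  for (j in seq_len(n_trials)) {
    if (j %in% baseline_trials) {
      bl <- setdiff(baseline_trials, j)
      tmpl <- lapply(maps, function(m)
        weighted_tuning(m$rate[bl, , drop = FALSE],
                        m$occupancy[bl, , drop = FALSE]))
    } else tmpl <- templates
    if (method == "percell") {
      rs <- vapply(seq_along(maps), function(i) {
        a <- tmpl[[i]]; b <- maps[[i]]$rate[j, ]
        ok <- !is.na(a) & !is.na(b)
        if (sum(ok) > 2 && stats::sd(a[ok]) > 0 && stats::sd(b[ok]) > 0)
          stats::cor(a[ok], b[ok]) else NA_real_
      }, numeric(1))
      out[j] <- mean(rs, na.rm = TRUE)
    } else {
      a <- unlist(tmpl)
      b <- unlist(lapply(maps, function(m) m$rate[j, ]))
      ok <- !is.na(a) & !is.na(b)
      if (sum(ok) > 2 && stats::sd(a[ok]) > 0 && stats::sd(b[ok]) > 0)
        out[j] <- stats::cor(a[ok], b[ok])
    }
  }
  out
}

#' Remapping score around an injection
#'
#' Mean template correlation over the `n` trials before the injection
#' trial minus the mean over the `n` trials starting `skip` trials after
#' it (skipping the acute decoherence trials); positive values mean the
#' spatial map moved away from baseline.
#'
#' @param template_corr output of [baseline_template_correlation()].
#' @param injection_trial last pre-injection trial.
#' @param n trials averaged on each side.
#' @param skip trials skipped after the injection before the "after"
#'   window starts.
#' @return scalar difference (before minus after).
#' @export
remap_difference <- function(template_corr, injection_trial, n = 25,
                             skip = 0) {
  pre <- template_corr[seq(injection_trial - n + 1, injection_trial)]
  post <- template_corr[seq(injection_trial + 1 + skip,
                            injection_trial + n + skip)]
  mean(pre, na.rm = TRUE) - mean(post, na.rm = TRUE)
}
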