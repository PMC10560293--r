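# End-to-end orchestration over one or many sessions, plus plain-JSON
# session interchange.

#' Run the full analysis pipeline on one VR session
#'
#' Executes behavior -> spatial coding -> (optional) connectivity ->
#' decoherence detection -> population analyses -> decoding -> (optional)
#' LFP on a `vr_session`, returning a summary bundle and optionally
#' writing per-stage CSV/JSON outputs.  Defaults are desk-scale: the
#' decoherence embedding uses 0.2 s bins and connectivity is limited to
#' `conn_max_cells` cells; set `deco_bin_s = 0.02` and raise the limits
#' for full-resolution runs.
#'
#' @param session a `vr_session` (see [simulate_vr_session()]).
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @param seed integer seed for the stochastic stages (embedding,
#'   shuffles).
#' @param bin_cm,speed_floor spatial binning and speed filter.
#' @param deco_bin_s,deco_smoothing_sd temporal binning for the embedding.
#' @param connectivity run the monosynaptic-pair stage.
#' @param conn_n_shuffles,conn_max_cells connectivity nulls and cell cap.
#' @param decoder_mode `"trajectory_nn"` or `"logistic_argmax"`.
#' @return list of class `ketamap_report`; see its `summary` element for
#'   the headline per-epoch metrics.
#' @export
run_pipeline <- function(session, out_dir = NULL, seed = 1,
                         bin_cm = 2, speed_floor = 2,
                         deco_bin_s = 0.2, deco_smoothing_sd = 0.2,
                         connectivity = TRUE, conn_n_shuffles = 200,
                         conn_max_cells = 12,
                         decoder_mode = "trajectory_nn") {
  if (!inherits(session, "vr_session")) stop("expected a vr_session")
  for (grp in c("spikes", "behavior", "epochs")) {
    if (is.null(session[[grp]])) stop("session is missing required group: ", grp)
  }
  epochs <- session$epochs
  trace <- as_behavior_trace(session)
  t_end <- trace$time[nrow(trace)]

  # behavior
  lick <- lick_accuracy(trace)
  lick$epoch <- epoch_of_trial(epochs, lick$trial)
  spd <- speed_by_position(trace, epochs)

  # spatial coding
  maps <- lapply(session$spikes, compute_rate_map, trace = trace,
                 bin_cm = bin_cm, speed_floor = speed_floor)
  classes <- classify_cells(maps, epochs)
  epoch_metrics <- list()
  for (nm in names(epochs)) {
    r <- epochs[[nm]]; tr <- seq(r[1], r[2])
    per_cell <- vapply(maps, function(m) {
      occ <- sum(m$occupancy[tr, ])
      c(rate = if (occ > 0) sum(m$counts[tr, ]) / occ else NA_real_,
        si = spatial_information(tuning_curve(m, tr),
                                 colSums(m$occupancy[tr, , drop = FALSE])),
        stab = mean(stability_score(structure(
          list(rate = m$rate[tr, , drop = FALSE],
               occupancy = m$occupancy[tr, , drop = FALSE],
               bin_cm = m$bin_cm), class = "spatial_rate_map")),
          na.rm = TRUE))
    }, numeric(3))
    epoch_metrics[[nm]] <- data.frame(
      epoch = nm,
      mean_rate = mean(per_cell["rate", ], na.rm = TRUE),
      spatial_information = mean(per_cell["si", ], na.rm = TRUE),
      stability = mean(per_cell["stab", ], na.rm = TRUE),
      lick_accuracy = mean(lick$accuracy[lick$epoch == nm]))
  }
  epoch_metrics <- do.call(rbind, epoch_metrics)

  # connectivity (desk-scale cap)
  conn <- NULL
  if (isTRUE(connectivity)) {
    eligible <- which(vapply(session$spikes, length, integer(1)) >= 100)
    eligible <- utils::head(eligible, conn_max_cells)
    if (length(eligible) >= 2) {
      prs <- t(utils::combn(eligible, 2))
      prs <- rbind(prs, prs[, 2:1])
      det <- detect_monosynaptic_pairs(session$spikes, pairs = prs,
                                       n_shuffles = conn_n_shuffles,
                                       seed = seed)
      hits <- det[det$sign != "none", , drop = FALSE]
      trans <- lapply(seq_len(nrow(hits)), function(i)
        transmission_probability(session$spikes[[hits$pre[i]]],
                                 session$spikes[[hits$post[i]]],
                                 duration_s = t_end))
      conn <- list(pairs = det, detected = hits, transmission = trans)
    }
  }

  # decoherence
  trm <- temporal_rate_matrix(session$spikes, 0, t_end, bin_s = deco_bin_s,
                              smoothing_sd = deco_smoothing_sd)
  clus <- embed_and_cluster(trm, seed = seed)
  period <- if (!is.null(session$injections$ketamine) &&
                !is.na(session$injections$ketamine)) {
    identify_decoherence_period(clus, session$injections$ketamine)
  } else NULL

  # population
  spatial_ids <- classes$cell[classes$class %in% c("spatial", "putative_grid")]
  pair_corr <- tryCatch(
    cellpair_correlations(trm, trace, five_epochs(epochs),
                          cell_ids = spatial_ids),
    error = function(e) NULL)
  S <- trial_similarity_matrix(maps)
  bl <- seq(epochs$baseline[1], epochs$baseline[2])
  template_corr <- baseline_template_correlation(maps, bl)
  remap <- if (!is.null(epochs$control)) {
    remap_difference(template_corr, epochs$control[2],
                     n = min(25, length(bl)))
  } else NA_real_

  # decoding
  pos_of_bin <- trace_at_times(trace, pmin(trm$times, t_end))
  bl_bins <- pos_of_bin$trial >= epochs$baseline[1] &
    pos_of_bin$trial <= epochs$baseline[2]
  decoder <- fit_position_decoder(trm$rates[, bl_bins, drop = FALSE],
                                  pos_of_bin$position[bl_bins],
                                  track_length = session$track_length,
                                  bin_cm = bin_cm)
  test_bins <- which(!bl_bins)
  decoded <- decode_position(decoder, trm$rates[, test_bins, drop = FALSE],
                             mode = decoder_mode)
  rmse_by_trial <- vapply(sort(unique(pos_of_bin$trial[test_bins])),
                          function(tr) {
    sel <- pos_of_bin$trial[test_bins] == tr
    circular_rmse(decoded[sel], pos_of_bin$position[test_bins][sel],
                  session$track_length)
  }, numeric(1))
  rmse <- data.frame(trial = sort(unique(pos_of_bin$trial[test_bins])),
                     rmse = rmse_by_trial)
  rmse$epoch <- epoch_of_trial(epochs, rmse$trial)

  # lfp (optional input)
  lfp_out <- NULL
  if (!is.null(session$lfp)) {
    bl_time <- range(trace$time[trace$trial >= epochs$baseline[1] &
                                  trace$trial <= epochs$baseline[2]])
    lfp_out <- list(
      theta = band_power(session$lfp, c(5, 11), baseline_s = bl_time),
      gamma = band_power(session$lfp, c(50, 110), baseline_s = bl_time))
  } else message("session has no LFP; skipping the band-power stage")

  summary <- list(
    n_cells = length(session$spikes),
    n_trials = max(trace$trial),
    duration_s = t_end,
    epochs = epochs,
    epoch_metrics = epoch_metrics,
    n_spatial = length(spatial_ids),
    class_counts = table(classes$class),
    decoherence = if (is.null(period)) NULL else
      c(start_s = period$start_s, end_s = period$end_s),
    rho = if (is.null(pair_corr)) NULL else pair_corr$rho,
    remap_difference = remap,
    rmse_by_epoch = tapply(rmse$rmse, rmse$epoch, mean),
    lfp = if (is.null(lfp_out)) NULL else
      vapply(lfp_out, function(b) mean(b$z), numeric(1)))

  report <- structure(list(
    summary = summary, classes = classes, lick = lick, speed = spd,
    maps = maps, connectivity = conn, clustering = clus, period = period,
    pair_correlations = pair_corr, similarity = S,
    template_correlation = template_corr, decoder = decoder, rmse = rmse,
    lfp = lfp_out, seed = seed), class = "ketamap_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# The five comparison epochs used for cell-pair correlations: acute
# ketamine is the first third of the ketamine epoch, late ketamine the
# last portion before the gain trials.
five_epochs <- function(epochs) {
  ket <- epochs$ketamine
  span <- ket[2] - ket[1] + 1
  acute_len <- min(50, max(2, floor(span / 4)))
  late_len <- min(40, max(2, floor(span / 5)))
  out <- list(baseline = epochs$baseline, control = epochs$control,
              acute_ketamine = c(ket[1], ket[1] + acute_len - 1),
              late_ketamine = c(ket[2] - late_len + 1, ket[2]))
  if (!is.null(epochs$gain)) out$gain_change <- epochs$gain
  out
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$classes, file.path(out_dir, "cell_classes.csv"),
                   row.names = FALSE)
  utils::write.csv(report$lick, file.path(out_dir, "lick_accuracy.csv"),
                   row.names = FALSE)
  utils::write.csv(report$summary$epoch_metrics,
                   file.path(out_dir, "epoch_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(report$rmse, file.path(out_dir, "decoder_rmse.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(trial = seq_along(report$template_correlation),
                              template_corr = report$template_correlation),
                   file.path(out_dir, "template_correlation.csv"),
                   row.names = FALSE)
  s <- report$summary
  s$class_counts <- as.list(s$class_counts)
  s$rmse_by_epoch <- as.list(s$rmse_by_epoch)
  jsonlite::write_json(s, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.ketamap_report <- function(x, ...) {
  s <- x$summary
  cat("ketamap report:", s$n_cells, "cells,", s$n_trials, "trials\n")
  print(s$epoch_metrics, row.names = FALSE)
  if (!is.null(s$decoherence)) {
    cat(sprintf("decoherence period: %.1f-%.1f min\n",
                s$decoherence[1] / 60, s$decoherence[2] / 60))
  } else cat("no decoherence period detected\n")
  invisible(x)
}

#' Aggregate session summaries into a cohort table
#'
#' Across-session mean and SEM per epoch metric, with two-sided Wilcoxon
#' matched-pairs signed-rank tests between epochs (Sidak-corrected over
#' the epoch-pair comparisons of each metric).  Sessions are the pairing
#' unit.  Identical metric values across sessions give degenerate
#' signed-rank tests; their p-values are reported as `NA`.
#'
#' @param reports list of at least two `ketamap_report`s (or of their
#'   `summary` elements).
#' @return list: `table` (epoch x metric mean/SEM), `tests` (pairwise
#'   Wilcoxon results with raw and Sidak-corrected p).
#' @export
aggregate_sessions <- function(reports) {
  if (length(reports) < 2) stop("aggregation needs at least 2 sessions")
  summaries <- lapply(reports, function(r)
    if (inherits(r, "ketamap_report")) r$summary else r)
  ep0 <- summaries[[1]]$epochs
  for (s in summaries) {
    if (!identical(s$epochs, ep0)) stop("sessions have mismatched epoch specs")
  }
  metrics <- c("mean_rate", "spatial_information", "stability",
               "lick_accuracy")
  em <- lapply(summaries, `[[`, "epoch_metrics")
  epochs <- em[[1]]$epoch
  tab <- expand.grid(epoch = epochs, metric = metrics,
                     stringsAsFactors = FALSE)
  tab$mean <- tab$sem <- NA_real_
  for (i in seq_len(nrow(tab))) {
    v <- vapply(em, function(d)
      d[[tab$metric[i]]][d$epoch == tab$epoch[i]], numeric(1))
    tab$mean[i] <- mean(v)
    tab$sem[i] <- stats::sd(v) / sqrt(length(v))
  }
  pairs <- utils::combn(as.character(epochs), 2)
  tests <- list()
  for (m in metrics) {
    p_raw <- numeric(ncol(pairs)); stat <- numeric(ncol(pairs))
    for (k in seq_len(ncol(pairs))) {
      x <- vapply(em, function(d) d[[m]][d$epoch == pairs[1, k]], numeric(1))
      y <- vapply(em, function(d) d[[m]][d$epoch == pairs[2, k]], numeric(1))
      res <- tryCatch(
        suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                            exact = TRUE)),
        error = function(e) NULL)
      p_raw[k] <- if (is.null(res) || is.na(res$p.value)) NA_real_ else res$p.value
      stat[k] <- if (is.null(res)) NA_real_ else unname(res$statistic)
    }
    m_comp <- sum(!is.na(p_raw))
    tests[[m]] <- data.frame(metric = m, epoch_a = pairs[1, ],
                             epoch_b = pairs[2, ], V = stat, p = p_raw,
                             p_sidak = 1 - (1 - p_raw)^max(1, m_comp))
  }
  list(table = tab[, c("epoch", "metric", "mean", "sem")],
       tests = do.call(rbind, tests))
}

#' Write a session to a plain-JSON container
#'
#' Keyed groups mirror the analysis inputs: spikes (ragged per-cell
#' times), behavior, events (injections, epoch table), optional lfp, plus
#' the generator config as metadata.
#'
#' @param session a `vr_session`.
#' @param path output file path (.json).
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  obj <- list(
    spikes = session$spikes,
    behavior = session$behavior,
    lick_times = session$lick_times,
    injections = session$injections,
    epochs = session$epochs,
    track_length = session$track_length,
    fs = session$fs,
    lfp = if (is.null(session$lfp)) NULL else
      list(samples = session$lfp$samples, fs = session$lfp$fs))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a session from a plain-JSON container
#'
#' @param path file written by [write_session()].
#' @return a `vr_session`.
#' @export
read_session <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spikes <- lapply(obj$spikes, as.numeric)
  lfp <- NULL
  if (!is.null(obj$lfp)) {
    lfp <- structure(list(samples = as.numeric(obj$lfp$samples),
                          fs = obj$lfp$fs,
                          time = seq_along(obj$lfp$samples) / obj$lfp$fs,
                          truth = NULL), class = "lfp_trace")
  }
  structure(list(spikes = spikes,
                 behavior = as.data.frame(obj$behavior),
                 lick_times = as.numeric(obj$lick_times),
                 injections = obj$injections,
                 epochs = lapply(obj$epochs, as.numeric),
                 track_length = obj$track_length, fs = obj$fs,
                 lfp = lfp, config = NULL),
            class = "vr_session")
}
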