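# Unsupervised identification of the acute post-ketamine decoherence state:
# smoothed population rate vectors per time bin, UMAP embedding, density
# clustering (DBSCAN), and the first-major-cluster rule gated to 2-15 min
# after the injection.

#' Temporally binned, smoothed population firing-rate matrix
#'
#' Spike counts per `bin_s` bin, divided by the bin width and Gaussian
#' smoothed along time per cell.  The kernel is normalised, so per-cell
#' rate mass (`sum(rate) * bin_s`) equals the spike count.
#'
#' @param spikes list of per-cell spike-time vectors, s.
#' @param t_start,t_end session span covered by the bins, s.
#' @param bin_s bin width, s (0.02 for full resolution; coarser bins keep
#'   the embedding cheap on long sessions).
#' @param smoothing_sd temporal smoothing SD, s; 0 disables.
#' @return list of class `temporal_rate_matrix`: `rates` (cells x T, Hz),
#'   `times` (bin centers, s), `bin_s`.
#' @export
temporal_rate_matrix <- function(spikes, t_start, t_end, bin_s = 0.02,
                                 smoothing_sd = 0.2) {
  nb <- ceiling((t_end - t_start) / bin_s)
  rates <- matrix(0, length(spikes), nb)
  for (i in seq_along(spikes)) {
    s <- spikes[[i]]
    s <- s[s >= t_start & s < t_start + nb * bin_s]
    if (length(s)) {
      k <- floor((s - t_start) / bin_s) + 1
      r <- tabulate(k, nbins = nb) / bin_s
      if (smoothing_sd > 0) r <- gauss_smooth(r, sd = smoothing_sd / bin_s)
      rates[i, ] <- r
    }
  }
  structure(list(rates = rates,
                 times = t_start + (seq_len(nb) - 0.5) * bin_s,
                 bin_s = bin_s),
            class = "temporal_rate_matrix")
}

#' Density-based clustering (DBSCAN)
#'
#' Standard DBSCAN: points with at least `min_pts` neighbors within `eps`
#' (themselves included) are core points; clusters are the connected
#' components of core points under the eps-neighborhood relation, plus
#' reachable border points; everything else is noise (label 0).  For 2D
#' input (the usual embedding), neighbor search uses an eps-sized grid
#' hash; higher dimensions fall back to blocked brute force.
#'
#' @param x numeric matrix, points in rows.
#' @param eps neighborhood radius.
#' @param min_pts core-point threshold (neighbor count including self).
#' @return integer labels, 0 = noise.
#' @export
dbscan_cluster <- function(x, eps, min_pts) {
  x <- as.matrix(x)
  n <- nrow(x)
  nbrs <- vector("list", n)
  if (ncol(x) == 2) {
    cx <- floor(x[, 1] / eps); cy <- floor(x[, 2] / eps)
    key <- paste(cx, cy)
    cellmap <- split(seq_len(n), key)
    for (cell in names(cellmap)) {
      pts <- cellmap[[cell]]
      cc <- as.numeric(strsplit(cell, " ", fixed = TRUE)[[1]])
      cand <- integer(0)
      for (dx in -1:1) for (dy in -1:1) {
        k2 <- paste(cc[1] + dx, cc[2] + dy)
        cand <- c(cand, cellmap[[k2]])
      }
      d2 <- outer(x[pts, 1], x[cand, 1], "-")^2 +
        outer(x[pts, 2], x[cand, 2], "-")^2
      within <- d2 <= eps^2
      for (j in seq_along(pts)) nbrs[[pts[j]]] <- cand[within[j, ]]
    }
  } else {
    block <- max(1L, floor(2e6 / n))
    for (s in seq(1, n, by = block)) {
      idx <- s:min(s + block - 1L, n)
      d2 <- outer(rowSums(x[idx, , drop = FALSE]^2), rowSums(x^2), "+") -
        2 * x[idx, , drop = FALSE] %*% t(x)
      for (j in seq_along(idx)) {
        nbrs[[idx[j]]] <- which(d2[j, ] <= eps^2)
      }
    }
  }
  core <- vapply(nbrs, length, integer(1)) >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- nbrs[[i]]
    while (length(queue)) {
      q <- queue[[1]]; queue <- queue[-1]
      if (labels[q] == 0L) {
        labels[q] <- cl
        if (core[q]) queue <- c(queue, nbrs[[q]][labels[nbrs[[q]]] == 0L])
      }
    }
  }
  labels
}

#' Epsilon from the knee of the k-NN distance curve
#'
#' Sorts each point's distance to its k-th nearest neighbor and returns the
#' value at the point of maximum deviation from the chord joining the ends
#' of the curve (the standard elbow heuristic for choosing DBSCAN's eps).
#'
#' @param x numeric matrix, points in rows.
#' @param k neighbor rank (use the intended `min_pts`).
#' @return eps estimate.
#' @export
knee_eps <- function(x, k = 50) {
  k <- min(k, nrow(x) - 1L)
  d <- sort(FNN::knn.dist(x, k = k)[, k])
  n <- length(d)
  t <- seq(0, 1, length.out = n)
  chord <- d[1] + t * (d[n] - d[1])
  # the sorted k-NN curve is flat then rises sharply; the elbow is the
  # point of maximum deviation below the chord
  d[which.max(chord - d)]
}

#' Embed population activity and cluster time bins
#'
#' UMAP embedding of the time bins of a [temporal_rate_matrix()] (each
#' point is a population rate vector), followed by density clustering in
#' the embedding space.  Defaults: `n_neighbors = 15`, `n_components = 2`,
#' Euclidean metric, `min_dist = 0.3`; DBSCAN with `min_samples = 50` and
#' eps from the k-NN knee when not supplied.
#'
#' @param trm a [temporal_rate_matrix()].
#' @param n_neighbors,n_components,min_dist,metric UMAP parameters.
#' @param eps DBSCAN radius; `NULL` uses [knee_eps()].
#' @param min_samples DBSCAN core threshold (and knee k).
#' @param seed integer seed (embedding is stochastic).
#' @return list of class `state_clustering`: `labels` (per time bin, 0 =
#'   noise), `embedding`, `times`, `eps`, `params`.
#' @export
embed_and_cluster <- function(trm, n_neighbors = 15, n_components = 2,
                              min_dist = 0.3, metric = "euclidean",
                              eps = NULL, min_samples = 50, seed = 1) {
  X <- t(trm$rates)
  if (nrow(X) < 100) stop("too few time bins to embed")
  if (all(apply(X, 2, stats::sd) == 0)) {
    warning("constant population activity; single cluster")
    return(structure(list(labels = rep(1L, nrow(X)), embedding = NULL,
                          times = trm$times, eps = NA_real_,
                          params = list(degenerate = TRUE)),
                     class = "state_clustering"))
  }
  set.seed(derive_seed(seed, "umap"))
  emb <- uwot::umap(X, n_neighbors = n_neighbors,
                    n_components = n_components, min_dist = min_dist,
                    metric = metric, n_threads = 1, n_sgd_threads = 1)
  if (is.null(eps)) eps <- knee_eps(emb, k = min_samples)
  labels <- dbscan_cluster(emb, eps = eps, min_pts = min_samples)
  structure(list(labels = labels, embedding = emb, times = trm$times,
                 eps = eps,
                 params = list(n_neighbors = n_neighbors,
                               n_components = n_components,
                               min_dist = min_dist, metric = metric,
                               min_samples = min_samples,
                               clusterer = "dbscan")),
            class = "state_clustering")
}

#' Identify the acute decoherence period
#'
#' Scans the clustered time bins for the first cluster with a contiguous
#' span (gaps up to `max_gap_s` merged) longer than `min_duration_s` that
#' starts between `gate_min[1]` and `gate_min[2]` minutes after the
#' ketamine injection.  Returns `NULL` when no cluster qualifies, mirroring
#' sessions where no decoherence state is observed.
#'
#' @param clustering an [embed_and_cluster()] result, or an integer label
#'   vector (then supply `times`).
#' @param injection_time_s ketamine injection time, s.
#' @param times bin-center times when `clustering` is a plain vector.
#' @param min_duration_s minimum duration (> 1 min).
#' @param gate_min onset gate after the injection, minutes.
#' @param max_gap_s label gaps merged into one run, s.
#' @return list(`start_s`, `end_s`, `cluster_id`) or `NULL`.
#' @export
identify_decoherence_period <- function(clustering, injection_time_s,
                                        times = NULL, min_duration_s = 60,
                                        gate_min = c(2, 15), max_gap_s = 5) {
  if (inherits(clustering, "state_clustering")) {
    labels <- clustering$labels
    times <- clustering$times
  } else {
    labels <- clustering
    if (is.null(times)) stop("times required with a plain label vector")
  }
  gate <- injection_time_s + gate_min * 60
  best <- NULL
  for (cl in setdiff(sort(unique(labels)), 0L)) {
    tt <- times[labels == cl]
    if (length(tt) < 2) next
    breaks <- which(diff(tt) > max_gap_s)
    starts <- tt[c(1, breaks + 1)]
    ends <- tt[c(breaks, length(tt))]
    ok <- (ends - starts) > min_duration_s &
      starts >= gate[1] & starts <= gate[2]
    if (any(ok)) {
      s <- min(starts[ok])
      e <- ends[ok][which.min(starts[ok])]
      if (is.null(best) || s < best$start_s) {
        best <- list(start_s = s, end_s = e, cluster_id = cl)
      }
    }
  }
  best
}

#' Jaccard overlap of two time intervals
#'
#' Intersection over union of `c(start, end)` intervals; used to score a
#' recovered decoherence period against ground truth.
#'
#' @param a,b intervals as `c(start, end)`.
#' @return overlap in `[0, 1]`.
#' @export
interval_jaccard <- function(a, b) {
  if (length(a) != 2 || length(b) != 2 || anyNA(a) || anyNA(b)) {
    stop("intervals must be c(start, end) without NAs")
  }
  inter <- max(0, min(a[2], b[2]) - max(a[1], b[1]))
  uni <- max(a[2], b[2]) - min(a[1], b[1])
  if (uni <= 0) return(0)
  inter / uni
}
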