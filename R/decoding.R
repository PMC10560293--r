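# Position decoding: baseline-trained decoder (nearest point on the mean
# encoding trajectory, with an optional L2 multinomial-logistic readout)
# and circular RMSE on the looped track.

#' Fit a position decoder on baseline activity
#'
#' Firing rates are z-scored per cell using baseline statistics (these are
#' frozen: test-time activity is standardised with the same parameters, so
#' genuine rate surges push population vectors off the encoding manifold
#' rather than being renormalised away).  The mean z-scored population
#' vector per spatial bin defines the encoding trajectory.  Optionally an
#' L2-regularised multinomial logistic model over the spatial-bin classes
#' is fitted as well (inverse regularisation strength `C`, matching the
#' `lambda = 1 / (C * n)` ridge penalty).
#'
#' @param rates cells x T matrix of baseline firing rates (Hz), e.g. the
#'   baseline time bins of a [temporal_rate_matrix()].
#' @param positions track position per time bin, cm.
#' @param track_length loop length, cm.
#' @param bin_cm spatial class width, cm (2 cm gives 200 classes).
#' @param fit_logistic also fit the logistic readout (slower; the
#'   trajectory readout is the default decoder).
#' @param C inverse L2 strength for the logistic readout.
#' @return list of class `position_decoder`: `mu`, `sd` (per-cell
#'   z-scoring), `trajectory` (occupied bins x cells), `bin_positions`
#'   (cm, bin centers of occupied bins), `cells_used`, `logistic`.
#' @export
fit_position_decoder <- function(rates, positions, track_length = 400,
                                 bin_cm = 2, fit_logistic = FALSE,
                                 C = 0.03) {
  if (nrow(rates) < 2) stop("need at least 2 cells")
  if (ncol(rates) != length(positions)) stop("rates/positions length mismatch")
  mu <- rowMeans(rates)
  sd_ <- apply(rates, 1, stats::sd)
  keep <- sd_ > 0
  if (!any(keep)) stop("no cell has baseline variance")
  z <- (rates[keep, , drop = FALSE] - mu[keep]) / sd_[keep]
  nb <- ceiling(track_length / bin_cm)
  bin <- pmin(nb, floor((positions %% track_length) / bin_cm) + 1L)
  occupied <- sort(unique(bin))
  traj <- t(vapply(occupied, function(b)
    rowMeans(z[, bin == b, drop = FALSE]), numeric(nrow(z))))
  logistic <- NULL
  lam <- 1 / (C * length(bin))
  if (fit_logistic) {
    # ridge path down to the target penalty (glmnet converges poorly when
    # handed a single small lambda); predictions are made at lambda = lam
    path <- exp(seq(log(max(50, lam * 100)), log(lam), length.out = 30))
    logistic <- glmnet::glmnet(t(z), factor(bin, levels = occupied),
                               family = "multinomial", alpha = 0,
                               lambda = path)
  }
  structure(list(mu = mu[keep], sd = sd_[keep], trajectory = traj,
                 bin_positions = (occupied - 0.5) * bin_cm,
                 occupied_bins = occupied,
                 cells_used = which(keep), track_length = track_length,
                 bin_cm = bin_cm, logistic = logistic, lambda = lam),
            class = "position_decoder")
}

#' Decode position from population activity
#'
#' `trajectory_nn` (default, the readout used to produce decoded
#' positions): each test vector is z-scored with the frozen baseline
#' statistics and assigned the spatial bin whose encoding-trajectory point
#' is nearest in Euclidean distance (ties: lowest bin index).
#' `logistic_argmax`: class of maximum probability under the logistic
#' readout.
#'
#' @param model a [fit_position_decoder()].
#' @param rates cells x T matrix (full cell set the model was fitted from).
#' @param mode `"trajectory_nn"` or `"logistic_argmax"`.
#' @return decoded positions, cm (bin centers).
#' @export
decode_position <- function(model, rates,
                            mode = c("trajectory_nn", "logistic_argmax")) {
  mode <- match.arg(mode)
  if (max(model$cells_used) > nrow(rates)) stop("rates lack fitted cells")
  z <- (rates[model$cells_used, , drop = FALSE] - model$mu) / model$sd
  if (mode == "trajectory_nn") {
    TR <- model$trajectory
    d2 <- outer(rowSums(TR^2), rep(1, ncol(z))) - 2 * TR %*% z
    pick <- apply(d2, 2, which.min)   # ties: first (lowest bin index)
    model$bin_positions[pick]
  } else {
    if (is.null(model$logistic)) stop("model fitted without the logistic readout")
    pr <- stats::predict(model$logistic, newx = t(z), type = "response",
                         s = model$lambda)[, , 1]
    if (is.null(dim(pr))) pr <- matrix(pr, nrow = 1)
    pick <- apply(pr, 1, which.max)
    model$bin_positions[pick]
  }
}

#' Circular root-mean-squared decoding error
#'
#' Per-sample error is the shortest distance around the loop,
#' `min(|d - a|, L - |d - a|)`, so the maximum possible error is `L / 2`
#' (200 cm on the 400 cm track) and chance level under uniform occupancy
#' is `L / (2 * sqrt(3))` (about 115.5 cm).
#'
#' @param decoded,actual position vectors, cm.
#' @param track_length loop length, cm.
#' @return RMSE, cm.
#' @export
circular_rmse <- function(decoded, actual, track_length = 400) {
  if (!length(decoded)) stop("empty input")
  if (length(decoded) != length(actual)) stop("length mismatch")
  sqrt(mean(circular_distance(decoded, actual, track_length)^2))
}

#' Baseline RMSE by leave-one-trial-out jackknife
#'
#' Refits the encoding trajectory with each baseline trial held out,
#' decodes the held-out trial, and reports the mean circular RMSE - the
#' decoder's error floor on data from the training condition.
#'
#' @param rates cells x T baseline rate matrix.
#' @param positions positions per bin, cm.
#' @param trials trial index per time bin.
#' @param ... passed to [fit_position_decoder()].
#' @return list: `rmse` (mean over folds), `per_trial`.
#' @export
baseline_decoder_rmse <- function(rates, positions, trials, ...) {
  ids <- sort(unique(trials))
  per <- vapply(ids, function(tr) {
    test <- trials == tr
    m <- fit_position_decoder(rates[, !test, drop = FALSE],
                              positions[!test], ...)
    dec <- decode_position(m, rates[, test, drop = FALSE])
    circular_rmse(dec, positions[test], m$track_length)
  }, numeric(1))
  list(rmse = mean(per), per_trial = data.frame(trial = ids, rmse = per))
}
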