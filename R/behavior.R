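# Behavior preprocessing: uniform 50 Hz resampling of VR position, trial
# segmentation, speed estimation, lick accuracy and speed-by-position maps.

#' Preprocess raw VR position into an analysis-ready behavior trace
#'
#' Resamples the variable-frame-rate VR stream to a constant rate by linear
#' interpolation, wraps positions onto the circular track, segments trials
#' at teleport events (per-step position difference below -100 cm), and
#' computes a smoothed running speed (forward difference divided by the
#' frame interval, first sample copied from the second, Gaussian kernel of
#' SD 0.2 s).
#'
#' Raw positions may be given either already wrapped to `[0, track_length)`
#' or cumulative ("infinite track"); wrapped input is unwrapped before
#' interpolation so teleports are not smeared across samples.
#'
#' @param raw_time sample times, s, strictly increasing.
#' @param raw_position positions, cm.
#' @param track_length loop length, cm.
#' @param fs output sampling rate, Hz.
#' @param lick_times optional lick event times, s, carried through.
#' @param speed_smooth_sd speed smoothing SD, s.
#' @return data.frame of class `behavior_trace` with columns `time`,
#'   `position`, `trial`, `speed`; attributes `track_length`, `fs`,
#'   `lick_times`.
#' @export
preprocess_position <- function(raw_time, raw_position, track_length = 400,
                                fs = 50, lick_times = NULL,
                                speed_smooth_sd = 0.2) {
  if (length(raw_time) == 0) stop("empty input")
  if (any(diff(raw_time) <= 0)) stop("raw_time must be strictly increasing")
  # unwrap: any backwards jump beyond half the track is a teleport
  d <- diff(raw_position)
  wraps <- cumsum(c(0, d < -track_length / 4))
  unwrapped <- raw_position + wraps * track_length

  t_out <- seq(raw_time[1], raw_time[length(raw_time)], by = 1 / fs)
  p_un <- stats::approx(raw_time, unwrapped, xout = t_out)$y
  position <- p_un %% track_length

  dp <- diff(position)
  trial <- cumsum(c(1L, as.integer(dp < -100)))

  speed <- c(NA, diff(p_un)) * fs
  speed[1] <- speed[2]
  speed <- pmax(0, speed)
  speed <- gauss_smooth(speed, sd = speed_smooth_sd * fs)

  out <- data.frame(time = t_out, position = position, trial = trial,
                    speed = speed)
  attr(out, "track_length") <- track_length
  attr(out, "fs") <- fs
  attr(out, "lick_times") <- lick_times
  class(out) <- c("behavior_trace", "data.frame")
  out
}

# Coerce a vr_session's behavior data.frame to the behavior_trace contract.
as_behavior_trace <- function(session) {
  b <- session$behavior
  attr(b, "track_length") <- session$track_length
  attr(b, "fs") <- session$fs
  attr(b, "lick_times") <- session$lick_times
  class(b) <- c("behavior_trace", "data.frame")
  b
}

# Interpolate trace columns at arbitrary event times (constant trial within
# a frame; position interpolated on the unwrapped track).
trace_at_times <- function(trace, times) {
  L <- attr(trace, "track_length") %||% 400
  idx <- findInterval(times, trace$time, all.inside = TRUE)
  data.frame(time = times,
             position = trace$position[idx],
             trial = trace$trial[idx],
             speed = trace$speed[idx])
}

#' Per-trial lick accuracy
#'
#' A lick is accurate when it occurs within 50 cm (circular distance, so
#' positions just past the teleport count as near-reward) of the reward
#' tower at `track_length` cm.  Accuracy is accurate licks over total licks
#' per trial; trials without licks score 0.
#'
#' @param trace a [preprocess_position()] trace (or one carrying
#'   `lick_times` as an attribute).
#' @param lick_times optional override of the trace's lick times, s.
#' @param reward_position cm; defaults to the track length (= position 0).
#' @param window_cm accuracy window, cm.
#' @return data.frame with `trial`, `n_licks`, `accuracy`.
#' @export
lick_accuracy <- function(trace, lick_times = NULL, reward_position = NULL,
                          window_cm = 50) {
  L <- attr(trace, "track_length") %||% 400
  reward_position <- reward_position %||% L
  lick_times <- lick_times %||% attr(trace, "lick_times") %||% numeric(0)
  trials <- sort(unique(trace$trial))
  out <- data.frame(trial = trials, n_licks = 0L, accuracy = 0)
  if (length(lick_times)) {
    lick_times <- lick_times[lick_times >= trace$time[1] &
                               lick_times <= trace$time[nrow(trace)]]
    at <- trace_at_times(trace, lick_times)
    ok <- circular_distance(at$position, reward_position, L) <= window_cm
    for (i in seq_along(trials)) {
      sel <- at$trial == trials[i]
      n <- sum(sel)
      out$n_licks[i] <- n
      out$accuracy[i] <- if (n > 0) sum(ok[sel]) / n else 0
    }
  }
  out
}

#' Occupancy-weighted mean running speed per spatial bin
#'
#' Means are per 2 cm bin within each epoch, weighted by dwell time.  By
#' default sub-floor-speed samples are retained (this is a behavioral
#' map, and reward-zone slowing is the signal of interest); set
#' `speed_floor` to restrict to running periods.  Also returns the
#' reward-zone (390-400 cm) versus main-hallway (100-200 cm) speed
#' contrast used to test anticipatory slowing.
#'
#' @param trace a behavior trace.
#' @param epochs named list of trial ranges; `NULL` treats the whole trace
#'   as one epoch.
#' @param bin_cm spatial bin width, cm.
#' @param speed_floor cm/s; samples slower than this are dropped (0 keeps
#'   everything).
#' @return list with `by_bin` (data.frame epoch, bin_center, speed) and
#'   `contrast` (named vector per epoch: hallway mean minus reward-zone
#'   mean, cm/s; positive = anticipatory slowing).
#' @export
speed_by_position <- function(trace, epochs = NULL, bin_cm = 2,
                              speed_floor = 0) {
  L <- attr(trace, "track_length") %||% 400
  if (nrow(trace) == 0) stop("empty trace")
  if (is.null(epochs)) epochs <- list(all = range(trace$trial))
  nb <- ceiling(L / bin_cm)
  bin <- pmin(nb, floor(trace$position / bin_cm) + 1L)
  rows <- list(); contrast <- c()
  for (nm in names(epochs)) {
    r <- epochs[[nm]]
    sel <- trace$trial >= r[1] & trace$trial <= r[2] &
      trace$speed >= speed_floor
    if (!any(sel)) stop("empty epoch: ", nm)
    m <- tapply(trace$speed[sel], factor(bin[sel], levels = seq_len(nb)),
                mean)
    centers <- (seq_len(nb) - 0.5) * bin_cm
    rows[[nm]] <- data.frame(epoch = nm, bin_center = centers,
                             speed = as.numeric(m))
    hall <- centers > 100 & centers <= 200
    rew <- centers > L - 10 & centers <= L
    contrast[nm] <- mean(m[hall], na.rm = TRUE) - mean(m[rew], na.rm = TRUE)
  }
  list(by_bin = do.call(rbind, rows), contrast = contrast)
}
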