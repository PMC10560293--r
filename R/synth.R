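# Synthetic-session generators.  These emulate the statistical structure of
# head-fixed VR Neuropixels sessions (spatially tuned MEC cells, a transient
# post-ketamine "decoherence" state, remapping), monosynaptically connected
# spike-train pairs, open-field CA1 calcium sessions, and LFP traces.  Every
# generator returns ground truth alongside the data so downstream stages can
# be tested as recovery problems.

#' Configuration for synthetic sessions
#'
#' Defaults reproduce the study conditions the pipeline assumes: a 400 cm
#' looped VR track, 300 trials split into baseline (1-50), control injection
#' (51-100), ketamine (101-290) and visual gain-change (291-300) epochs,
#' excitatory cells with one or more Gaussian spatial fields, high-rate
#' (>15 Hz) interneurons, and a ketamine effect consisting of a transient
#' spatially untuned state (tuning flattened to its mean, rates multiplied by
#' `rate_gain`) starting `onset_delay_min` after the injection, followed by
#' remapping (permuted field centers) when `remap` is `TRUE`.
#'
#' @param n_cells number of units.
#' @param frac_interneuron fraction of units given >15 Hz mean rates.
#' @param track_length VR track length, cm.
#' @param n_trials trials per session.
#' @param epochs named list of `c(first, last)` trial ranges; must partition
#'   `1:n_trials` without overlap.
#' @param mean_speed,speed_sd running-speed model, cm/s (AR(1) fluctuations
#'   around a position-dependent profile).
#' @param reward_slow multiplicative slowing in the reward zone (390-400 cm)
#'   on pre-ketamine trials; mice stop slowing there after ketamine.
#' @param ketamine_speed_factor overall speed multiplier in the ketamine
#'   epoch.
#' @param peak_rate_range,baseline_rate excitatory tuning parameters, Hz.
#' @param field_width_range spatial field SD range, cm.
#' @param max_fields maximum number of fields per excitatory cell.
#' @param interneuron_rate_range interneuron mean rates, Hz (> 15).
#' @param onset_delay_min minutes between ketamine injection and decoherence
#'   onset (must fall in the 2-15 min detection gate to be recoverable).
#' @param rate_gain firing-rate multiplier during the decoherence state.
#' @param decoherence_min duration of the decoherence state, minutes; 0
#'   disables it.
#' @param remap permute excitatory field centers after the decoherence state.
#' @param fs behavior sampling rate, Hz.
#' @param seed master seed; fully determines every output.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_cells = 40, frac_interneuron = 0.1,
                         track_length = 400, n_trials = 300,
                         epochs = NULL,
                         mean_speed = 30, speed_sd = 5, reward_slow = 0.5,
                         ketamine_speed_factor = 0.8,
                         peak_rate_range = c(3, 10), baseline_rate = 0.5,
                         field_width_range = c(8, 20), max_fields = 3,
                         interneuron_rate_range = c(18, 30),
                         onset_delay_min = 4, rate_gain = 1.5,
                         decoherence_min = 18.6, remap = TRUE,
                         fs = 50, seed = 1) {
  if (is.null(epochs)) {
    epochs <- default_epochs(n_trials)
  }
  cfg <- list(n_cells = n_cells, frac_interneuron = frac_interneuron,
              track_length = track_length, n_trials = n_trials,
              epochs = epochs, mean_speed = mean_speed, speed_sd = speed_sd,
              reward_slow = reward_slow,
              ketamine_speed_factor = ketamine_speed_factor,
              peak_rate_range = peak_rate_range,
              baseline_rate = baseline_rate,
              field_width_range = field_width_range, max_fields = max_fields,
              interneuron_rate_range = interneuron_rate_range,
              onset_delay_min = onset_delay_min, rate_gain = rate_gain,
              decoherence_min = decoherence_min, remap = remap,
              fs = fs, seed = seed)
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

# Default epoch layout; shrinks proportionally for short test sessions.
default_epochs <- function(n_trials) {
  if (n_trials >= 300) {
    list(baseline = c(1, 50), control = c(51, 100),
         ketamine = c(101, n_trials - 10), gain = c(n_trials - 9, n_trials))
  } else {
    b <- max(2L, round(n_trials / 6))
    g <- max(2L, round(n_trials / 30))
    list(baseline = c(1, b), control = c(b + 1, 2 * b),
         ketamine = c(2 * b + 1, n_trials - g),
         gain = c(n_trials - g + 1, n_trials))
  }
}

validate_synth_config <- function(cfg) {
  covered <- sort(unlist(lapply(cfg$epochs, function(r) seq(r[1], r[2]))))
  if (!identical(as.integer(covered), seq_len(cfg$n_trials))) {
    stop("epochs must partition 1..n_trials without overlap")
  }
  if (any(vapply(cfg$epochs, function(r) r[2] < r[1], logical(1)))) {
    stop("zero- or negative-duration epoch")
  }
  rates <- c(cfg$peak_rate_range, cfg$baseline_rate,
             cfg$interneuron_rate_range, cfg$rate_gain)
  if (any(rates < 0)) stop("all rates must be >= 0")
  if (cfg$decoherence_min < 0) stop("decoherence_min must be >= 0")
  invisible(cfg)
}

#' @export
print.synth_config <- function(x, ...) {
  cat("synth_config:", x$n_cells, "cells,", x$n_trials, "trials,",
      x$track_length, "cm track, seed", x$seed, "\n")
  invisible(x)
}

epoch_of_trial <- function(epochs, trial) {
  lab <- rep(NA_character_, length(trial))
  for (nm in names(epochs)) {
    r <- epochs[[nm]]
    lab[trial >= r[1] & trial <= r[2]] <- nm
  }
  lab
}

# Draw per-cell tuning parameters.  Interneurons get a high, weakly
# modulated rate; excitatory cells get 1..max_fields Gaussian fields.
draw_tuning <- function(cfg) {
  n_int <- round(cfg$n_cells * cfg$frac_interneuron)
  is_int <- seq_len(cfg$n_cells) <= n_int
  cells <- vector("list", cfg$n_cells)
  for (i in seq_len(cfg$n_cells)) {
    if (is_int[i]) {
      base <- stats::runif(1, cfg$interneuron_rate_range[1],
                           cfg$interneuron_rate_range[2])
      cells[[i]] <- list(interneuron = TRUE, baseline = base,
                         centers = stats::runif(1, 0, cfg$track_length),
                         widths = 40, peaks = 0.1 * base)
    } else {
      nf <- sample.int(cfg$max_fields, 1)
      cells[[i]] <- list(
        interneuron = FALSE, baseline = cfg$baseline_rate,
        centers = stats::runif(nf, 0, cfg$track_length),
        widths = stats::runif(nf, cfg$field_width_range[1],
                              cfg$field_width_range[2]),
        peaks = stats::runif(nf, cfg$peak_rate_range[1],
                             cfg$peak_rate_range[2]))
    }
  }
  cells
}

# Evaluate one cell's tuning (Hz) at positions x on the circular track.
eval_tuning <- function(cell, x, track_length) {
  r <- rep(cell$baseline, length(x))
  for (f in seq_along(cell$centers)) {
    d <- circular_distance(x, cell$centers[f], track_length)
    r <- r + cell$peaks[f] * exp(-d^2 / (2 * cell$widths[f]^2))
  }
  r
}

#' Simulate a virtual-reality electrophysiology session
#'
#' Generates a 50 Hz behavior trace (position on a looped track, running
#' speed with reward-zone slowing, licks concentrated near the reward tower
#' before ketamine and dispersed after), inhomogeneous-Poisson spike trains
#' from per-cell spatial tuning gated by running speed (spiking suppressed
#' below 2 cm/s so the analysis-side speed filter is exercised), injection
#' times at the trial 50/100 boundaries, and the configured ketamine effect.
#'
#' @param config a [synth_config()].
#' @return list with `session` (class `vr_session`: `spikes` list of per-cell
#'   spike-time vectors in seconds, `behavior` data.frame, `lick_times`,
#'   `injections`, `epochs`, `config`) and `truth` (per-cell tuning used
#'   before and after the state, the decoherence interval in seconds, the
#'   remap permutation, interneuron flags).
#' @export
simulate_vr_session <- function(config) {
  validate_synth_config(config)
  cfg <- config
  set.seed(derive_seed(cfg$seed, "vr_behavior"))
  dt <- 1 / cfg$fs
  L <- cfg$track_length
  ket_first <- cfg$epochs$ketamine[1]

  # --- behavior: step the animal until n_trials laps are complete ---------
  cap <- ceiling(cfg$n_trials * L / (cfg$mean_speed * 0.4) * cfg$fs)
  pos <- numeric(cap); spd <- numeric(cap); trl <- integer(cap)
  p <- 0; tr <- 1L; i <- 0L
  ar <- exp(-dt / 0.5)                       # 0.5 s speed-fluctuation memory
  innov_sd <- cfg$speed_sd * sqrt(1 - ar^2)
  eps <- 0
  noise <- stats::rnorm(cap)
  while (tr <= cfg$n_trials && i < cap) {
    i <- i + 1L
    target <- cfg$mean_speed
    if (tr >= ket_first) target <- target * cfg$ketamine_speed_factor
    if (tr < ket_first && p >= L - 10) target <- target * cfg$reward_slow
    eps <- ar * eps + innov_sd * noise[i]
    v <- max(0, target + eps)
    pos[i] <- p; spd[i] <- v; trl[i] <- tr
    p <- p + v * dt
    if (p >= L) { p <- p - L; tr <- tr + 1L }
  }
  n <- i
  behavior <- data.frame(time = (seq_len(n) - 1L) * dt, position = pos[seq_len(n)],
                         trial = trl[seq_len(n)], speed = spd[seq_len(n)])
  behavior$epoch <- epoch_of_trial(cfg$epochs, behavior$trial)

  trial_start <- behavior$time[!duplicated(behavior$trial)]
  names(trial_start) <- unique(behavior$trial)
  control_inj <- if (cfg$n_trials > cfg$epochs$baseline[2])
    trial_start[as.character(cfg$epochs$baseline[2] + 1L)] else NA_real_
  ketamine_inj <- if (cfg$n_trials >= ket_first)
    trial_start[as.character(ket_first)] else NA_real_

  # --- licks --------------------------------------------------------------
  set.seed(derive_seed(cfg$seed, "vr_licks"))
  lick_times <- numeric(0)
  for (t_i in seq_len(cfg$n_trials)) {
    idx <- which(behavior$trial == t_i)
    if (!length(idx)) next
    post_ket <- t_i >= ket_first && t_i <= cfg$epochs$ketamine[2]
    n_lick <- stats::rpois(1, if (post_ket) 4 else 8)
    if (n_lick == 0) next
    if (post_ket) {
      w <- rep(1, length(idx))
    } else {
      w <- exp(-circular_distance(behavior$position[idx], L, L)^2 / (2 * 15^2)) + 1e-6
    }
    pick <- sample(idx, n_lick, replace = TRUE, prob = w)
    lick_times <- c(lick_times, behavior$time[pick])
  }
  lick_times <- sort(lick_times)

  # --- ketamine state timing ----------------------------------------------
  deco <- c(NA_real_, NA_real_)
  if (!is.na(ketamine_inj) && cfg$decoherence_min > 0) {
    deco <- ketamine_inj + cfg$onset_delay_min * 60 +
      c(0, cfg$decoherence_min * 60)
    deco[2] <- min(deco[2], behavior$time[n])
  }

  # --- spikes -------------------------------------------------------------
  set.seed(derive_seed(cfg$seed, "vr_tuning"))
  cells <- draw_tuning(cfg)
  perm <- seq_len(cfg$n_cells)
  cells_post <- cells
  if (cfg$remap && !is.na(deco[1])) {
    exc <- which(!vapply(cells, `[[`, logical(1), "interneuron"))
    if (length(exc) > 1) {
      set.seed(derive_seed(cfg$seed, "vr_remap"))
      shift <- stats::runif(length(exc), 0.25 * L, 0.75 * L)
      for (k in seq_along(exc)) {
        i <- exc[k]
        cells_post[[i]]$centers <- (cells[[i]]$centers + shift[k]) %% L
      }
    }
  }

  set.seed(derive_seed(cfg$seed, "vr_spikes"))
  in_deco <- !is.na(deco[1]) & behavior$time >= deco[1] & behavior$time < deco[2]
  post_deco <- !is.na(deco[1]) & behavior$time >= deco[2]
  gate <- behavior$speed >= 2
  spikes <- vector("list", cfg$n_cells)
  for (ci in seq_len(cfg$n_cells)) {
    lam <- eval_tuning(cells[[ci]], behavior$position, L)
    if (any(post_deco) && cfg$remap) {
      lam[post_deco] <- eval_tuning(cells_post[[ci]],
                                    behavior$position[post_deco], L)
    }
    if (any(in_deco)) {
      flat <- mean(eval_tuning(cells[[ci]],
                               seq(1, L, by = 2) - 1, L))
      lam[in_deco] <- flat * cfg$rate_gain
    }
    lam[!gate] <- 0
    counts <- stats::rpois(n, lam * dt)
    idx <- rep.int(seq_len(n), counts)
    if (length(idx)) {
      st <- behavior$time[idx] + stats::runif(length(idx), 0, dt)
      spikes[[ci]] <- sort(st)
    } else spikes[[ci]] <- numeric(0)
  }

  bin_centers <- seq(1, L, by = 2)
  tuning_pre <- t(vapply(cells, eval_tuning, numeric(length(bin_centers)),
                         x = bin_centers, track_length = L))
  tuning_post <- t(vapply(cells_post, eval_tuning,
                          numeric(length(bin_centers)),
                          x = bin_centers, track_length = L))

  session <- structure(list(
    spikes = spikes, behavior = behavior, lick_times = lick_times,
    injections = list(control = unname(control_inj),
                      ketamine = unname(ketamine_inj)),
    epochs = cfg$epochs, track_length = L, fs = cfg$fs, config = cfg),
    class = "vr_session")
  truth <- list(
    tuning_pre = tuning_pre, tuning_post = tuning_post,
    bin_centers = bin_centers,
    decoherence = deco, rate_gain = cfg$rate_gain,
    interneuron = vapply(cells, `[[`, logical(1), "interneuron"),
    cells = cells, cells_post = cells_post)
  list(session = session, truth = truth)
}

#' @export
print.vr_session <- function(x, ...) {
  cat("vr_session:", length(x$spikes), "cells,",
      max(x$behavior$trial), "trials,",
      sprintf("%.1f min", max(x$behavior$time) / 60), "\n")
  invisible(x)
}

#' Simulate spike-train pairs with known monosynaptic coupling
#'
#' Independent homogeneous Poisson trains plus a generative coupling: for an
#' excitatory pair each presynaptic spike adds a postsynaptic spike at a
#' 1-3 ms lag with probability `efficacy`; for an inhibitory pair each
#' presynaptic spike deletes postsynaptic spikes in the 1-5 ms window with
#' probability `efficacy`.
#'
#' @param n_pairs number of pairs (cells come in independent pre/post pairs).
#' @param efficacy scalar or per-pair vector in `[0, 1]`; 0 means no true
#'   coupling (null pairs).
#' @param sign "excitatory" or "inhibitory", scalar or per-pair.
#' @param rate_pre,rate_post background rates, Hz.
#' @param duration_s session length, s.
#' @param seed integer seed.
#' @return list with `spikes` (length `2 * n_pairs`; pair k is cells
#'   `2k - 1` (pre) and `2k` (post)) and `pairs` data.frame of ground truth.
#' @export
simulate_connected_pairs <- function(n_pairs = 10, efficacy = 0.3,
                                     sign = "excitatory",
                                     rate_pre = 5, rate_post = 5,
                                     duration_s = 600, seed = 1) {
  efficacy <- rep_len(efficacy, n_pairs)
  sign <- rep_len(sign, n_pairs)
  if (any(efficacy < 0 | efficacy > 1)) stop("efficacy must lie in [0, 1]")
  set.seed(derive_seed(seed, "pairs"))
  spikes <- vector("list", 2L * n_pairs)
  for (k in seq_len(n_pairs)) {
    pre <- sort(stats::runif(stats::rpois(1, rate_pre * duration_s),
                             0, duration_s))
    post <- sort(stats::runif(stats::rpois(1, rate_post * duration_s),
                              0, duration_s))
    if (efficacy[k] > 0 && length(pre)) {
      if (sign[k] == "excitatory") {
        drive <- pre[stats::runif(length(pre)) < efficacy[k]]
        add <- drive + stats::runif(length(drive), 0.001, 0.003)
        post <- sort(c(post, add))
      } else {
        drive <- pre[stats::runif(length(pre)) < efficacy[k]]
        if (length(drive) && length(post)) {
          kill <- logical(length(post))
          for (s in drive) {
            kill <- kill | (post > s + 0.001 & post <= s + 0.005)
          }
          post <- post[!kill]
        }
      }
    }
    spikes[[2L * k - 1L]] <- pre
    spikes[[2L * k]] <- post
  }
  pairs <- data.frame(pre = 2L * seq_len(n_pairs) - 1L,
                      post = 2L * seq_len(n_pairs),
                      sign = sign, efficacy = efficacy)
  list(spikes = spikes, pairs = pairs, duration_s = duration_s)
}

#' Simulate an open-field calcium-imaging session
#'
#' A smooth random-walk trajectory confined to a circular arena; place cells
#' emit calcium events from 2D Gaussian fields, non-place cells emit
#' spatially uniform events.  The "ketamine day" option lowers the event
#' rate by `ketamine_rate_factor` and decouples events from position while
#' keeping rates positive, emulating the suppression and loss of spatial
#' tuning seen under the drug.  Deconvolved-style traces are returned (event
#' amplitudes plus small Gaussian noise) so the binarization step is
#' exercised end to end.
#'
#' @param n_cells cells imaged.
#' @param frac_place fraction with a true place field.
#' @param duration_s session length, s.
#' @param fs imaging frame rate, Hz.
#' @param arena_diameter cm.
#' @param field_sd place-field SD, cm.
#' @param peak_event_rate place-field peak event rate, Hz.  The default
#'   keeps place-cell mean event rates comfortably above the 0.1 Hz
#'   classification floor, which in the recorded data sits near the 5th
#'   percentile of the rate distribution.
#' @param baseline_event_rate out-of-field / non-place event rate, Hz.
#' @param ketamine simulate the drug session.
#' @param ketamine_rate_factor multiplier on event rates under ketamine.
#' @param seed integer seed (trajectory and event noise).
#' @param cell_seed seed for the cell population (place flags, field
#'   centers); defaults to `seed`.  Reusing `cell_seed` across calls with
#'   different `seed`s emulates the same imaged cells tracked over
#'   multiple sessions.
#' @return list with `session` (class `calcium_session`: `traces` cells x
#'   frames, `events` binary matrix, `position` frames x 2 cm, `speed`,
#'   `fs`, `arena_diameter`) and `truth` (place flags, field centers).
#' @export
simulate_openfield_calcium <- function(n_cells = 30, frac_place = 0.6,
                                       duration_s = 1200, fs = 15,
                                       arena_diameter = 36, field_sd = 4,
                                       peak_event_rate = 2.5,
                                       baseline_event_rate = 0.25,
                                       ketamine = FALSE,
                                       ketamine_rate_factor = 0.4,
                                       seed = 1, cell_seed = NULL) {
  set.seed(derive_seed(seed, "calcium_traj"))
  n <- round(duration_s * fs)
  dt <- 1 / fs
  R <- arena_diameter / 2
  # OU velocity, reflected at the wall
  vx <- vy <- 0; x <- y <- 0
  ar <- exp(-dt / 1.0); sv <- 8 * sqrt(1 - ar^2)
  X <- numeric(n); Y <- numeric(n)
  nx <- stats::rnorm(n); ny <- stats::rnorm(n)
  for (i in seq_len(n)) {
    vx <- ar * vx + sv * nx[i]; vy <- ar * vy + sv * ny[i]
    x2 <- x + vx * dt; y2 <- y + vy * dt
    if (sqrt(x2^2 + y2^2) > R - 0.5) { vx <- -vx; vy <- -vy
      x2 <- x + vx * dt; y2 <- y + vy * dt }
    x <- x2; y <- y2; X[i] <- x; Y[i] <- y
  }
  speed <- c(0, sqrt(diff(X)^2 + diff(Y)^2) * fs)
  speed[1] <- speed[2]

  set.seed(derive_seed(cell_seed %||% seed, "calcium_cells"))
  n_place <- round(n_cells * frac_place)
  is_place <- seq_len(n_cells) <= n_place
  th <- stats::runif(n_cells, 0, 2 * pi)
  rr <- sqrt(stats::runif(n_cells)) * (R - field_sd)
  cx <- rr * cos(th); cy <- rr * sin(th)
  if (any(sqrt(cx^2 + cy^2) > R)) stop("field center outside arena")

  set.seed(derive_seed(seed, "calcium_events"))
  rate_mult <- if (ketamine) ketamine_rate_factor else 1
  events <- matrix(0L, n_cells, n)
  traces <- matrix(0, n_cells, n)
  for (ci in seq_len(n_cells)) {
    if (is_place[ci] && !ketamine) {
      d2 <- (X - cx[ci])^2 + (Y - cy[ci])^2
      lam <- baseline_event_rate / 5 +
        peak_event_rate * exp(-d2 / (2 * field_sd^2))
    } else if (is_place[ci]) {
      # drug day: rate positive but decoupled from position
      lam <- rep(mean(baseline_event_rate / 5 + peak_event_rate *
                        2 * pi * field_sd^2 / (pi * R^2)), n)
    } else {
      lam <- rep(baseline_event_rate, n)
    }
    lam <- lam * rate_mult
    ev <- stats::rpois(n, lam * dt) > 0
    events[ci, ] <- as.integer(ev)
    amp <- stats::runif(sum(ev), 8, 12)
    traces[ci, ev] <- amp
    traces[ci, ] <- traces[ci, ] + abs(stats::rnorm(n, 0, 0.05))
  }

  session <- structure(list(
    traces = traces, events = events,
    position = cbind(x = X, y = Y), speed = speed, fs = fs,
    arena_diameter = arena_diameter,
    label = if (ketamine) "ketamine" else "baseline"),
    class = "calcium_session")
  truth <- list(is_place = is_place & !ketamine,
                centers = cbind(cx, cy), field_sd = field_sd,
                ketamine = ketamine)
  list(session = session, truth = truth)
}

#' Simulate a local field potential trace
#'
#' Sum of a theta-band (8 Hz) sinusoid, a fast-gamma-band (80 Hz) sinusoid
#' and white noise, with piecewise-constant amplitudes per epoch so band
#' power changes can be recovered against ground truth.
#'
#' @param segments data.frame with columns `start_s`, `end_s`, `theta_amp`,
#'   `gamma_amp` (amplitudes in uV).
#' @param noise_sd white-noise SD, uV.
#' @param fs sampling rate, Hz (2.5 kHz as recorded).
#' @param seed integer seed.
#' @return list of class `lfp_trace`: `samples`, `fs`, `time`, `truth`.
#' @export
simulate_lfp <- function(segments, noise_sd = 1, fs = 2500, seed = 1) {
  stopifnot(all(c("start_s", "end_s", "theta_amp", "gamma_amp") %in%
                  names(segments)))
  set.seed(derive_seed(seed, "lfp"))
  t_end <- max(segments$end_s)
  tt <- seq(0, t_end - 1 / fs, by = 1 / fs)
  theta_a <- gamma_a <- numeric(length(tt))
  for (r in seq_len(nrow(segments))) {
    idx <- tt >= segments$start_s[r] & tt < segments$end_s[r]
    theta_a[idx] <- segments$theta_amp[r]
    gamma_a[idx] <- segments$gamma_amp[r]
  }
  x <- theta_a * sin(2 * pi * 8 * tt) + gamma_a * sin(2 * pi * 80 * tt) +
    stats::rnorm(length(tt), 0, noise_sd)
  structure(list(samples = x, fs = fs, time = tt, truth = segments),
            class = "lfp_trace")
}
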