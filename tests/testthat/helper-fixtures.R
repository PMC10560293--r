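# Fixtures built in code and cached for the test run.

.fixture_env <- new.env()

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# A hand-built behavior trace: constant speed, integer frames, wrap at L.
make_ramp_trace <- function(speed_cms = 10, n_laps = 1, L = 400, fs = 50) {
  t_total <- n_laps * L / speed_cms
  tt <- seq(0, t_total, by = 1 / fs)
  preprocess_position(tt, speed_cms * tt, track_length = L, fs = fs)
}

# A minimal trace data.frame with the behavior_trace contract, bypassing
# resampling (for exact-arithmetic map tests).
raw_trace <- function(time, position, trial, speed, L = 400, fs = 50,
                      lick_times = NULL) {
  out <- data.frame(time = time, position = position, trial = trial,
                    speed = speed)
  attr(out, "track_length") <- L
  attr(out, "fs") <- fs
  attr(out, "lick_times") <- lick_times
  class(out) <- c("behavior_trace", "data.frame")
  out
}

# Hand-built spatial_rate_map from a rate matrix (occupancy 1 s per bin).
make_map <- function(rate, occupancy = NULL, bin_cm = 2) {
  if (is.null(occupancy)) occupancy <- matrix(1, nrow(rate), ncol(rate))
  counts <- rate * occupancy
  structure(list(rate = rate, occupancy = occupancy, counts = counts,
                 bin_cm = bin_cm,
                 bin_centers = (seq_len(ncol(rate)) - 0.5) * bin_cm,
                 track_length = ncol(rate) * bin_cm),
            class = "spatial_rate_map")
}

# Small VR session shared across integration tests (about 40 trials).
small_session <- function() {
  fixture("small_session", function() {
    cfg <- synth_config(n_cells = 12, n_trials = 42, frac_interneuron = 0.15,
                        onset_delay_min = 2.5, decoherence_min = 2,
                        rate_gain = 1.8, seed = 11)
    simulate_vr_session(cfg)
  })
}
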