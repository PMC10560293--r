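test_that("an identical seed reproduces the session bit for bit", {
  cfg <- synth_config(n_cells = 6, n_trials = 18, seed = 3)
  a <- simulate_vr_session(cfg)
  b <- simulate_vr_session(cfg)
  expect_identical(a$session$spikes, b$session$spikes)
  expect_identical(a$session$behavior, b$session$behavior)
  expect_identical(a$session$lick_times, b$session$lick_times)
  c2 <- simulate_vr_session(synth_config(n_cells = 6, n_trials = 18, seed = 4))
  expect_false(identical(a$session$spikes, c2$session$spikes))
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(n_trials = 20,
                            epochs = list(a = c(1, 10), b = c(10, 20))),
               "partition")
  expect_error(synth_config(baseline_rate = -1), "rates")
  expect_error(synth_config(decoherence_min = -5), "decoherence")
  expect_error(simulate_connected_pairs(efficacy = 1.2), "efficacy")
})

test_that("spike counts match the configured intensity (rate conservation)", {
  res <- fixture("null_session", function() {
    simulate_vr_session(synth_config(n_cells = 10, n_trials = 30,
                                     frac_interneuron = 0,
                                     rate_gain = 1, decoherence_min = 0,
                                     remap = FALSE, seed = 21))
  })
  beh <- res$session$behavior
  dt <- 1 / res$session$fs
  gate <- beh$speed >= 2
  bin <- pmin(200, floor(beh$position / 2) + 1)
  for (ci in seq_along(res$session$spikes)) {
    lam <- res$truth$tuning_pre[ci, bin]
    expected <- sum(lam[gate]) * dt
    observed <- length(res$session$spikes[[ci]])
    expect_lt(abs(observed - expected),
              3 * sqrt(expected) + 0.02 * expected)
  }
})

test_that("a null perturbation leaves ketamine-epoch tuning at baseline", {
  res <- fixture("null_session", function() {
    simulate_vr_session(synth_config(n_cells = 10, n_trials = 30,
                                     frac_interneuron = 0,
                                     rate_gain = 1, decoherence_min = 0,
                                     remap = FALSE, seed = 21))
  })
  tr <- ketamap:::as_behavior_trace(res$session)
  ep <- res$session$epochs
  cors <- vapply(res$session$spikes, function(spk) {
    m <- compute_rate_map(spk, tr)
    a <- tuning_curve(m, seq(ep$baseline[1], ep$control[2]))
    b <- tuning_curve(m, seq(ep$ketamine[1], ep$ketamine[2]))
    ok <- !is.na(a) & !is.na(b)
    cor(a[ok], b[ok])
  }, numeric(1))
  expect_gt(median(cors), 0.7)
})

test_that("the decoherence state multiplies rates by the configured gain", {
  res <- fixture("gain_session", function() {
    simulate_vr_session(synth_config(n_cells = 20, n_trials = 80,
                                     frac_interneuron = 0,
                                     peak_rate_range = c(5, 10),
                                     onset_delay_min = 3,
                                     decoherence_min = 10, rate_gain = 1.5,
                                     remap = FALSE, seed = 31))
  })
  deco <- res$truth$decoherence
  expect_false(any(is.na(deco)))
  beh <- res$session$behavior
  dt <- 1 / res$session$fs
  in_win <- beh$time >= deco[1] & beh$time < deco[2] & beh$speed >= 2
  gated_s <- sum(in_win) * dt
  flat <- rowMeans(res$truth$tuning_pre)
  n_obs <- sum(vapply(res$session$spikes, function(s)
    sum(s >= deco[1] & s < deco[2]), numeric(1)))
  n_exp <- sum(flat) * 1.5 * gated_s
  expect_lt(abs(n_obs - n_exp), 4 * sqrt(n_exp))
  # and the empirical window rate sits well above the baseline rate
  ctrl_win <- beh$time < deco[1] - 60
  r_base <- sum(vapply(res$session$spikes, function(s)
    sum(s < deco[1] - 60), numeric(1))) / (sum(ctrl_win) * dt)
  expect_gt((n_obs / gated_s) / r_base, 1.2)
})

test_that("connected-pair construction concentrates CCG mass at 1-3 ms", {
  sim <- simulate_connected_pairs(n_pairs = 1, efficacy = 1, rate_pre = 5,
                                  rate_post = 0.2, duration_s = 300, seed = 5)
  cc <- spike_ccg(sim$spikes[[1]], sim$spikes[[2]], window_ms = 10)
  lag <- cc$lag_ms
  mass_13 <- sum(cc$counts[lag >= 1 & lag < 3])
  expect_gt(mass_13 / sum(cc$counts), 0.8)
  expect_gt(mass_13, 0.9 * length(sim$spikes[[1]]))
})

test_that("open-field calcium sessions have in-arena trajectories and truth", {
  res <- simulate_openfield_calcium(n_cells = 8, duration_s = 120, seed = 6)
  s <- res$session
  R <- s$arena_diameter / 2
  expect_true(all(sqrt(s$position[, 1]^2 + s$position[, 2]^2) <= R + 1e-9))
  expect_equal(dim(s$events), dim(s$traces))
  expect_true(all(s$events %in% c(0L, 1L)))
  # drug day lowers the event rate but does not silence cells
  k <- simulate_openfield_calcium(n_cells = 8, duration_s = 120,
                                  ketamine = TRUE, seed = 6)
  expect_lt(mean(k$session$events), mean(s$events))
  expect_gt(mean(k$session$events), 0)
})

test_that("the LFP generator realises the requested band amplitudes", {
  seg <- data.frame(start_s = c(0, 30), end_s = c(30, 60),
                    theta_amp = c(1, 2), gamma_amp = c(0.5, 0.5))
  lfp <- simulate_lfp(seg, noise_sd = 0.1, seed = 7)
  expect_equal(length(lfp$samples), 60 * 2500)
  # crude amplitude check via RMS: sin has RMS a/sqrt(2)
  rms1 <- sqrt(mean(lfp$samples[1:(30 * 2500)]^2))
  rms2 <- sqrt(mean(lfp$samples[(30 * 2500 + 1):(60 * 2500)]^2))
  expect_lt(abs(rms1 - sqrt(1^2 / 2 + 0.5^2 / 2 + 0.1^2)), 0.05)
  expect_lt(abs(rms2 - sqrt(2^2 / 2 + 0.5^2 / 2 + 0.1^2)), 0.05)
})
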