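test_that("event binarization applies the 3-SD rule and scale invariance", {
  tr <- rep(0, 1000); tr[500] <- 1
  tr <- tr + rnorm(1000, 0, 0.001)
  ev <- binarize_events(rbind(tr))
  expect_equal(sum(ev), 1)
  expect_equal(which(ev[1, ] == 1), 500)
  # scaling the trace leaves events unchanged
  expect_equal(unname(binarize_events(rbind(42 * tr))), unname(ev))
  # Gaussian noise: event rate near the 3-sigma tail mass
  set.seed(1)
  g <- rnorm(200000)
  rate <- mean(binarize_events(rbind(g)))
  expect_lt(abs(rate - pnorm(-3)), 4e-4)
})

test_that("2D rate maps bin, mask and smooth correctly", {
  # stay 1 s in one location with 1 event: that bin reads 1 event/s
  n <- 15
  pos <- cbind(rep(5, n), rep(5, n))
  ev <- c(1L, rep(0L, n - 1))
  m <- rate_map_2d(ev, pos, speed = rep(5, n), fs = 15)
  ix <- floor((5 + 18) / 1.75) + 1
  expect_equal(m$rate[ix, ix], 1)
  expect_equal(m$occupancy[ix, ix], 1)
  expect_true(all(is.na(m$rate[1, 1])))   # corner is outside the arena

  # uniform events over a uniform trajectory give a flat smoothed map
  res <- simulate_openfield_calcium(n_cells = 2, frac_place = 0,
                                    duration_s = 1200,
                                    baseline_event_rate = 2, seed = 2)
  s <- res$session
  m2 <- rate_map_2d(s$events[1, ], s$position, s$speed, s$fs)
  v <- m2$smoothed[!is.na(m2$smoothed) & !is.na(m2$occupancy) &
                     m2$occupancy > 0.5]
  expect_lt(sd(v) / mean(v), 0.5)
  # smoothing approximately conserves event mass over valid bins
  raw_mass <- sum(m2$rate * m2$occupancy, na.rm = TRUE)
  sm_mass <- sum(m2$smoothed * m2$occupancy, na.rm = TRUE)
  expect_lt(abs(sm_mass - raw_mass) / raw_mass, 0.1)
})

test_that("place-cell test separates tuned from uniform cells", {
  res <- fixture("calcium_bsl", function()
    simulate_openfield_calcium(n_cells = 10, frac_place = 0.5,
                               duration_s = 600, field_sd = 3,
                               peak_event_rate = 2, seed = 3))
  s <- res$session
  pc <- place_cell_test(s$events[1, ], s$position, s$speed, s$fs,
                        n_shuffles = 300, seed = 4)
  expect_true(pc$is_place_cell)        # true place cell, high rate
  expect_gt(pc$si, pc$threshold)
  # uniform cells are rejected in >= 90% of seeds
  rejected <- vapply(1:10, function(sd_) {
    u <- simulate_openfield_calcium(n_cells = 1, frac_place = 0,
                                    duration_s = 300,
                                    baseline_event_rate = 0.5, seed = sd_)
    !place_cell_test(u$session$events[1, ], u$session$position,
                     u$session$speed, u$session$fs,
                     n_shuffles = 200, seed = sd_)$is_place_cell
  }, logical(1))
  expect_gte(mean(rejected), 0.9)
})

test_that("the event-rate floor rejects sparse cells with perfect fields", {
  res <- fixture("calcium_bsl", function()
    simulate_openfield_calcium(n_cells = 10, frac_place = 0.5,
                               duration_s = 600, field_sd = 3,
                               peak_event_rate = 2, seed = 3))
  s <- res$session
  ev <- s$events[1, ]
  frames <- which(ev == 1)
  keep <- sort(sample(frames, round(0.04 * 600)))  # thin to < 0.1 Hz
  ev2 <- integer(length(ev)); ev2[keep] <- 1L
  pc <- place_cell_test(ev2, s$position, s$speed, s$fs, n_shuffles = 200,
                        seed = 5)
  expect_lt(pc$mean_rate, 0.1)
  expect_false(pc$is_place_cell)
})

test_that("position-matched downsampling preserves identical sessions", {
  res <- fixture("calcium_bsl", function()
    simulate_openfield_calcium(n_cells = 10, frac_place = 0.5,
                               duration_s = 600, field_sd = 3,
                               peak_event_rate = 2, seed = 3))
  s <- res$session
  out <- position_matched_downsample(s$events[1, ], s$position, s$speed,
                                     s$events[1, ], s$position, s$speed,
                                     fs = s$fs, n_iter = 5, seed = 6)
  # identical sessions: nothing is dropped, metrics match the full data
  full <- rate_map_2d(s$events[1, ], s$position, s$speed, s$fs)
  full_rate <- sum(full$rate * full$occupancy, na.rm = TRUE) /
    sum(full$occupancy, na.rm = TRUE)
  expect_equal(out$metrics["a", "mean_rate"], out$metrics["b", "mean_rate"])
  expect_lt(abs(out$metrics["a", "mean_rate"] - full_rate) / full_rate, 0.02)
  expect_gt(out$spatial_corr, 0.999)

  # duplicated-occupancy session downsamples back to the original
  ev_d <- rep(s$events[1, ], each = 2)
  pos_d <- s$position[rep(seq_len(nrow(s$position)), each = 2), ]
  spd_d <- rep(s$speed, each = 2)
  out2 <- position_matched_downsample(s$events[1, ], s$position, s$speed,
                                      ev_d, pos_d, spd_d,
                                      fs = s$fs, n_iter = 10, seed = 7)
  expect_lt(abs(out2$metrics["b", "mean_rate"] -
                  out2$metrics["a", "mean_rate"]) /
              out2$metrics["a", "mean_rate"], 0.1)
  expect_error(
    position_matched_downsample(s$events[1, ], s$position + 100, s$speed,
                                s$events[1, ], s$position, s$speed,
                                fs = s$fs),
    "occupancy")
})

test_that("session spatial correlation behaves on toys and null maps", {
  res <- fixture("calcium_bsl", function()
    simulate_openfield_calcium(n_cells = 10, frac_place = 0.5,
                               duration_s = 600, field_sd = 3,
                               peak_event_rate = 2, seed = 3))
  s <- res$session
  m <- rate_map_2d(s$events[1, ], s$position, s$speed, s$fs)
  expect_equal(session_spatial_correlation(m, m), 1)
  # a rotated asymmetric map decorrelates and matches brute-force Pearson
  m90 <- m
  m90$smoothed <- t(m$smoothed[, rev(seq_len(ncol(m$smoothed)))])
  r <- session_spatial_correlation(m, m90)
  ok <- !is.na(m$smoothed) & !is.na(m90$smoothed)
  expect_equal(r, cor(m$smoothed[ok], m90$smoothed[ok]))
  expect_lt(r, 0.99)
  # independent uniform cells: correlations centered on zero (single
  # pairs are noisy because smoothing leaves few independent bins)
  null_r <- vapply(8:12, function(sd_) {
    r2 <- simulate_openfield_calcium(n_cells = 2, frac_place = 0,
                                     duration_s = 900,
                                     baseline_event_rate = 1, seed = sd_)
    ma <- rate_map_2d(r2$session$events[1, ], r2$session$position,
                      r2$session$speed, r2$session$fs)
    mb <- rate_map_2d(r2$session$events[2, ], r2$session$position,
                      r2$session$speed, r2$session$fs)
    session_spatial_correlation(ma, mb)
  }, numeric(1))
  expect_lt(abs(mean(null_r)), 0.25)
})
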