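test_that("rate map arithmetic: count over dwell, speed filter applied", {
  # 25 frames (0.5 s at 50 Hz) parked-but-running at 99 cm (bin 50)
  tr <- raw_trace(time = seq(0, by = 0.02, length.out = 25),
                  position = rep(99, 25), trial = rep(1L, 25),
                  speed = rep(10, 25))
  m <- compute_rate_map(c(0.1), tr)
  expect_equal(m$occupancy[1, 50], 0.5)
  expect_equal(m$rate[1, 50], 2)
  expect_true(all(is.na(m$rate[1, -50])))

  # spikes emitted only below the speed floor leave an empty map
  tr2 <- raw_trace(time = seq(0, by = 0.02, length.out = 100),
                   position = seq(0, 99, length.out = 100),
                   trial = rep(1L, 100),
                   speed = rep(c(1, 10), each = 50))
  m2 <- compute_rate_map(c(0.3, 0.5), tr2)
  expect_equal(sum(m2$counts), 0)
})

test_that("homogeneous Poisson firing gives a flat map at the true rate", {
  set.seed(42)
  tr <- make_ramp_trace(speed_cms = 20, n_laps = 40)
  dur <- max(tr$time)
  spk <- sort(runif(rpois(1, 4 * dur), 0, dur))
  m <- compute_rate_map(spk, tr)
  tc <- tuning_curve(m)
  expect_lt(abs(mean(tc, na.rm = TRUE) - 4), 0.2)
  expect_lt(sd(tc, na.rm = TRUE), 1.5)
})

test_that("spatial information matches the Skaggs formula on toys", {
  # two equal-occupancy bins, rates (2, 0): 0.5 * 2 * log2(2/1) = 1 bit/s
  expect_equal(spatial_information(c(2, 0), c(1, 1)), 1.0)
  # uniform rate, uniform occupancy
  expect_equal(spatial_information(rep(3, 10), rep(1, 10)), 0)
  # silent cell
  expect_equal(spatial_information(rep(0, 10), rep(1, 10)), 0)
  # doubling rates doubles bits/s at fixed shape
  set.seed(1)
  r <- rgamma(50, 2); p <- rgamma(50, 1)
  expect_equal(spatial_information(2 * r, p),
               2 * spatial_information(r, p))
  # invariant to a joint permutation of bins
  perm <- sample(50)
  expect_equal(spatial_information(r[perm], p[perm]),
               spatial_information(r, p))
  expect_gte(spatial_information(r, p), 0)
})

test_that("stability scores follow the neighbor-correlation rule", {
  # identical tuning on every trial
  tun <- c(rep(0, 20), 1:10, 10:1, rep(0, 150))
  m <- make_map(matrix(rep(tun, 5), 5, byrow = TRUE))
  expect_equal(stability_score(m), rep(1, 5))

  # 3 trials A, A, B: scores (1, (1 + c)/2, c) with c = cor(A, B)
  set.seed(7)
  A <- rgamma(200, 2); B <- rgamma(200, 2)
  m3 <- make_map(rbind(A, A, B))
  s3 <- stability_score(m3, smooth_sd_cm = 0)   # disable smoothing: exact
  cAB <- cor(A / max(A), B / max(B))
  expect_equal(s3, c(1, (1 + cAB) / 2, cAB))
  expect_true(all(s3 >= -1 & s3 <= 1))

  # independent noise trials: mean stability near 0
  set.seed(8)
  mn <- make_map(matrix(rgamma(30 * 200, 2), 30, 200))
  expect_lt(abs(mean(stability_score(mn), na.rm = TRUE)), 0.1)

  # neighbor structure by brute force on 4 trials
  set.seed(9)
  R <- matrix(rgamma(4 * 100, 2), 4, 100)
  s4 <- stability_score(make_map(R), smooth_sd_cm = 0)
  norm <- R / apply(R, 1, max)
  cc <- function(i, j) cor(norm[i, ], norm[j, ])
  expect_equal(s4[2], mean(c(cc(1, 2), cc(2, 3))))
  expect_equal(s4[3], mean(c(cc(2, 3), cc(3, 4))))
})

test_that("crest factor closed forms and invariances hold", {
  expect_equal(crest_factor(rep(2.5, 200)), 1)
  one <- rep(0, 200); one[37] <- 5
  expect_equal(crest_factor(one), sqrt(200))
  expect_equal(crest_factor(c(3, 4, 0, 0)), 1.6)
  set.seed(2)
  x <- rgamma(200, 1)
  expect_equal(crest_factor(3.7 * x), crest_factor(x))
  expect_gte(crest_factor(x), 1)
  expect_error(crest_factor(rep(0, 10)), "all-zero")
})

test_that("cell classification applies the rate, stability, SI and gain rules", {
  set.seed(3)
  n_tr <- 30
  epochs <- list(baseline = c(1, 10), control = c(11, 20),
                 gain = c(26, 30))
  tun <- function(peak, center, w = 4) {
    x <- numeric(200); d <- pmin(abs(seq_len(200) - center), 200 - abs(seq_len(200) - center))
    peak * exp(-d^2 / (2 * w^2))
  }
  noisy_map <- function(base_tun, gain_tun = NULL) {
    r <- t(vapply(seq_len(n_tr), function(i) {
      tt <- if (!is.null(gain_tun) && i >= 26) gain_tun else base_tun
      pmax(0, tt + rnorm(200, 0, 0.05 * max(tt, 1)))
    }, numeric(200)))
    make_map(r)
  }
  maps <- list(
    noisy_map(rep(20, 200)),                        # interneuron, 20 Hz
    noisy_map(tun(8, 60)),                          # stable, gain-insensitive
    noisy_map(tun(60, 100, 2), tun(60, 160, 2)),    # grid-like: SI > 3, remaps under gain
    make_map(matrix(rgamma(n_tr * 200, 0.5, 1), n_tr, 200))  # unstable
  )
  cl <- classify_cells(maps, epochs)
  expect_equal(cl$class[1], "interneuron")
  expect_equal(cl$class[2], "spatial")
  expect_gt(cl$gain_r[2], 0.2)
  expect_equal(cl$class[3], "putative_grid")
  expect_lt(cl$gain_r[3], 0.2)
  expect_gt(cl$baseline_si[3], 3)
  expect_equal(cl$class[4], "other")
  # grid class needs gain trials; others still computed
  cl2 <- classify_cells(maps, list(baseline = c(1, 10)))
  expect_false(any(cl2$class == "putative_grid"))
  expect_equal(cl2$class[1], "interneuron")
  expect_equal(cl2$class[3], "spatial")
})

test_that("field width uses the shuffle threshold and half-height rule", {
  # triangular field: base 20 cm (10 bins), peak 10 Hz -> half-height 10 cm
  tri <- numeric(200)
  tri[96:100] <- seq(2, 10, by = 2)
  tri[101:105] <- seq(8, 0, by = -2)
  m <- make_map(matrix(rep(tri, 20), 20, byrow = TRUE))
  fw <- field_width(m, n_shuffles = 200, seed = 4)
  expect_false(is.na(fw$width_cm))
  expect_lt(abs(fw$width_cm - 10), 2.1)

  # flat map: no detectable field
  flat <- make_map(matrix(3, 20, 200))
  expect_true(is.na(field_width(flat, n_shuffles = 100, seed = 4)$width_cm))

  # two fields with half-height widths 8 and 14 cm: the wider one wins
  two <- numeric(200)
  two[40:48] <- c(2, 4, 6, 8, 8, 8, 6, 4, 2)          # plateau ~ 8 cm wide
  d <- pmin(abs(seq_len(200) - 140), 200 - abs(seq_len(200) - 140))
  two <- two + 10 * exp(-d^2 / (2 * 3^2))             # FWHM = 2.355*3 bins ~ 14 cm
  m2 <- make_map(matrix(rep(two, 20), 20, byrow = TRUE))
  fw2 <- field_width(m2, n_shuffles = 200, seed = 4)
  expect_lt(abs(fw2$width_cm - 14), 2.1)
})
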