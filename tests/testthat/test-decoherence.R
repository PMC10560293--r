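test_that("temporal rate matrix bins and conserves rate mass", {
  trm <- temporal_rate_matrix(list(c(0.55)), 0, 2, bin_s = 0.1,
                              smoothing_sd = 0)
  expect_equal(sum(trm$rates > 0), 1)
  expect_equal(max(trm$rates), 10)       # 1 spike / 0.1 s
  expect_equal(trm$times[which.max(trm$rates[1, ])], 0.55)

  set.seed(1)
  spk <- list(sort(runif(500, 0, 100)), sort(runif(50, 0, 100)))
  trm2 <- temporal_rate_matrix(spk, 0, 100, bin_s = 0.05, smoothing_sd = 0.3)
  for (i in 1:2) {
    expect_lt(abs(sum(trm2$rates[i, ]) * trm2$bin_s - length(spk[[i]])),
              0.5)   # kernel normalisation: mass within edge losses
  }
  # near-constant train: smoothing leaves the rate near the true rate
  reg <- list(seq(0.005, 100, by = 0.1))
  trm3 <- temporal_rate_matrix(reg, 0, 100, bin_s = 0.1, smoothing_sd = 0.5)
  mid <- trm3$rates[1, 100:900]
  expect_true(all(abs(mid - 10) < 0.5))
})

test_that("DBSCAN separates two blobs from background noise", {
  set.seed(2)
  x <- rbind(matrix(rnorm(400, 0, 0.3), ncol = 2),
             matrix(rnorm(400, 8, 0.3), ncol = 2),
             cbind(runif(30, -20, 20), runif(30, -20, 20)))
  lab <- dbscan_cluster(x, eps = 1, min_pts = 10)
  expect_equal(length(setdiff(unique(lab), 0L)), 2)
  expect_equal(length(unique(lab[1:200])), 1)
  expect_equal(length(unique(lab[201:400])), 1)
  expect_true(lab[1] != lab[201])
  expect_gt(sum(lab[401:430] == 0L), 20)   # scattered points mostly noise
  # higher-dimension fallback agrees on the same data embedded in 3D
  lab3 <- dbscan_cluster(cbind(x, 0), eps = 1, min_pts = 10)
  expect_equal(lab3, lab)
})

test_that("two disjoint population states yield two major clusters", {
  set.seed(3)
  n_half <- 600
  r1 <- rbind(matrix(rpois(10 * n_half, 8), 10), matrix(0, 10, n_half))
  r2 <- rbind(matrix(0, 10, n_half), matrix(rpois(10 * n_half, 8), 10))
  trm <- structure(list(rates = cbind(r1, r2) * 1.0,
                        times = (seq_len(2 * n_half) - 0.5) * 0.5,
                        bin_s = 0.5), class = "temporal_rate_matrix")
  cl <- embed_and_cluster(trm, min_samples = 30, seed = 4)
  major <- table(cl$labels[cl$labels > 0])
  major <- major[major > 100]
  expect_equal(length(major), 2)
  first <- cl$labels[1:n_half]; second <- cl$labels[n_half + 1:n_half]
  expect_gt(mean(first[first > 0] == as.integer(names(major)[1]) |
                   first[first > 0] == as.integer(names(major)[2])), 0.9)
  expect_false(names(which.max(table(first[first > 0]))) ==
                 names(which.max(table(second[second > 0]))))

  # relabeling cells leaves the time-bin partition essentially unchanged
  perm <- sample(10)
  trmp <- trm; trmp$rates <- trm$rates[perm, ]
  clp <- embed_and_cluster(trmp, min_samples = 30, seed = 4)
  same <- outer(cl$labels, cl$labels, "==")
  samep <- outer(clp$labels, clp$labels, "==")
  rand <- mean(same == samep)
  expect_gt(rand, 0.9)
})

test_that("constant population activity collapses to a single cluster", {
  trm <- structure(list(rates = matrix(5, 4, 500),
                        times = (seq_len(500) - 0.5) * 0.5, bin_s = 0.5),
                   class = "temporal_rate_matrix")
  expect_warning(cl <- embed_and_cluster(trm, seed = 1), "constant")
  expect_lte(length(setdiff(unique(cl$labels), 0L)), 1)
})

test_that("the decoherence gate enforces onset and duration rules", {
  times <- (seq_len(3000) - 0.5) * 0.5      # 25 min of 0.5 s bins
  inj <- 120
  lab <- rep(1L, 3000)
  # qualifying state: cluster 2 from 360 s to 600 s (4-8 min post injection)
  state <- times >= 360 & times < 600
  lab[state] <- 2L
  p <- identify_decoherence_period(lab, inj, times = times)
  expect_equal(p$cluster_id, 2L)
  expect_lt(abs(p$start_s - 360), 1)
  expect_lt(abs(p$end_s - 600), 1)

  # a state starting 20 min post injection is rejected by the 2-15 min gate
  lab2 <- rep(0L, 3000)
  lab2[times >= inj + 1200 & times < inj + 1350] <- 2L
  expect_null(identify_decoherence_period(lab2, inj, times = times))

  # too-short states are rejected
  lab3 <- rep(0L, 3000)
  lab3[times >= 360 & times < 400] <- 2L
  expect_null(identify_decoherence_period(lab3, inj, times = times))

  # gaps below 5 s are merged into one run
  lab4 <- rep(0L, 3000)
  run <- times >= 360 & times < 600 & !(times >= 420 & times < 423)
  lab4[run] <- 2L
  p4 <- identify_decoherence_period(lab4, inj, times = times)
  expect_false(is.null(p4))
  expect_lt(abs(p4$end_s - 600), 1)
})

test_that("interval Jaccard behaves at the edges", {
  expect_equal(interval_jaccard(c(0, 10), c(0, 10)), 1)
  expect_equal(interval_jaccard(c(0, 10), c(10, 20)), 0)
  expect_equal(interval_jaccard(c(0, 10), c(5, 10)), 0.5)
})
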