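test_that("LGN criteria reproduce hand-computed burst sets", {
  # 3 tight spikes after 150 ms of silence: one burst
  tt <- c(0.350, 0.500, 0.503, 0.506)
  b <- detect_bursts(tt, "lgn")
  expect_length(b, 1)
  expect_equal(b[[1]]$spike_times, c(0.500, 0.503, 0.506))
  expect_equal(b[[1]]$cardinal_time, 0.500)
  expect_equal(b[[1]]$isis, c(3, 3))
  # regular 10 ms spacing: ISI > 4 ms, no bursts
  expect_length(detect_bursts(seq(0, 1, by = 0.010), "lgn"), 0)
  # silence requirement: 50 ms of silence is not enough
  expect_length(detect_bursts(c(0.450, 0.500, 0.503), "lgn"), 0)
  # first spike of a recording counts as following infinite silence
  expect_length(detect_bursts(c(0.0, 0.003), "lgn"), 1)
  expect_error(detect_bursts(c(0.2, 0.1), "lgn"), "ascending")
})

test_that("PGN criteria reproduce hand-computed burst sets", {
  # worked example: 6 spikes within 55 ms after 80 ms of silence form one
  # burst; the 40 ms gap to the next spike terminates it (ISI > 30 ms)
  tt <- c(0.020, 0.100 + c(0, 15, 25, 32, 40, 55, 95, 120) / 1000)
  b <- detect_bursts(tt, "pgn")
  expect_length(b, 1)
  expect_length(b[[1]]$spike_times, 6)
  expect_equal(b[[1]]$cardinal_time, 0.100)
  # only 4 spikes: no burst
  expect_length(detect_bursts(c(0.020, 0.100, 0.120, 0.140, 0.160), "pgn"), 0)
  # 5 spikes but spread beyond 70 ms: no burst
  expect_length(detect_bursts(0.1 + c(0, 25, 50, 75, 100) / 1000, "pgn"), 0)
  # burst terminates at ISI > 30 ms: trailing spike excluded
  tt2 <- c(0.020, 0.100 + c(0, 10, 20, 30, 40, 90) / 1000)
  b2 <- detect_bursts(tt2, "pgn")
  expect_length(b2, 1)
  expect_length(b2[[1]]$spike_times, 5)
})

test_that("detection matches an independent brute-force scan on Poisson trains", {
  set.seed(31)
  tt <- sort(runif(2000, 0, 100))          # 20 spikes/s over 100 s
  for (crit in c("lgn", "pgn")) {
    got <- detect_bursts(tt, crit)
    ref <- oracle_bursts(tt, crit)
    expect_equal(length(got), length(ref))
    expect_equal(lapply(got, function(b) b$spike_times), ref)
  }
})

test_that("detected bursts are disjoint and detection is idempotent", {
  set.seed(32)
  tt <- sort(runif(3000, 0, 60))
  b <- detect_bursts(tt, "pgn")
  if (length(b) >= 2) {
    ends <- vapply(b, function(x) max(x$spike_times), 0)
    starts <- vapply(b, function(x) min(x$spike_times), 0)
    expect_true(all(starts[-1] > ends[-length(ends)]))
  }
  # re-running on the burst spikes with the required silences reinstated
  spikes2 <- unlist(lapply(seq_along(b), function(i)
    b[[i]]$spike_times - b[[i]]$spike_times[1] + (i - 1) * 1))
  b2 <- detect_bursts(spikes2, "pgn")
  expect_equal(length(b2), length(b))
  expect_equal(lapply(b2, function(x) diff(x$spike_times)),
               lapply(b, function(x) diff(x$spike_times)))
})

test_that("ISI curves preserve shape without overshoot", {
  expect_equal(isi_curve(c(10, 10, 10, 10))$values, rep(10, 21))
  u <- isi_curve(c(20, 10, 5, 10, 20))$values
  expect_length(u, 21)
  expect_equal(u[1], 20)
  expect_equal(u[21], 20)
  expect_equal(which.min(u), 11)
  # bounded by the raw ISI range for arbitrary bursts (no overshoot),
  # like a reference piecewise-linear interpolant
  set.seed(33)
  for (i in 1:20) {
    isis <- runif(sample(2:10, 1), 1, 30)
    v <- isi_curve(isis)$values
    lin <- approx(seq_along(isis), isis, n = 21)$y
    expect_gte(min(v), min(isis) - 1e-9)
    expect_lte(max(v), max(isis) + 1e-9)
    expect_gte(min(lin), min(isis) - 1e-9)   # reference behaves likewise
    expect_equal(v[c(1, 21)], isis[c(1, length(isis))])
  }
  # single-ISI burst: constant curve, flagged
  one <- isi_curve(5)
  expect_true(one$constant)
  expect_equal(one$values, rep(5, 21))
})

test_that("well-separated synthetic curve families cluster perfectly", {
  set.seed(34)
  u_curves <- lapply(1:100, function(i)
    isi_curve(c(20, 12, 6, 4, 6, 12, 20) + rnorm(7, 0, 0.5)))
  inc_curves <- lapply(1:100, function(i)
    isi_curve(sort(c(1.5, 2.2, 2.9, 3.6) + rnorm(4, 0, 0.1))))
  cl <- cluster_bursts(c(u_curves, inc_curves), max_clusters = 5)
  expect_equal(cl$n_clusters, 2)
  expect_length(unique(cl$assignments[1:100]), 1)
  expect_length(unique(cl$assignments[101:200]), 1)
  expect_false(cl$assignments[1] == cl$assignments[101])
  u <- u_shaped_clusters(cl)
  expect_equal(sum(u), 1)
  expect_equal(unique(cl$assignments[1:100]), which(u))
  # identical curves collapse to one cluster
  same <- lapply(1:30, function(i) isi_curve(c(5, 5, 5)))
  expect_equal(cluster_bursts(same)$n_clusters, 1)
})

test_that("cluster means equal the means of their members", {
  set.seed(35)
  curves <- lapply(1:60, function(i)
    isi_curve(runif(sample(3:8, 1), 2, 25)))
  cl <- cluster_bursts(curves, max_clusters = 3)
  X <- do.call(rbind, lapply(curves, function(cv) cv$values))
  for (g in seq_len(cl$n_clusters))
    expect_equal(cl$cluster_means[g, ],
                 colMeans(X[cl$assignments == g, , drop = FALSE]))
})

test_that("autocorrelogram width behaves as specified", {
  # periodic train, period 30 ms, window 40 ms: an isolated side peak whose
  # 5%-width is the bin itself (2 bins when lags straddle a bin edge)
  tt <- seq(0, 10, by = 0.030)
  w <- autocorr_width(tt, bin_ms = 1, max_lag_ms = 40)
  expect_lte(w, 2)
  expect_gte(w, 1)
  # brute-force correlogram equality on a random train
  set.seed(36)
  tt2 <- sort(runif(500, 0, 20))
  lags <- unlist(lapply(seq_along(tt2), function(i) {
    d <- tt2 - tt2[i]
    d[d > 0 & d < 0.1]
  })) * 1000
  counts_ref <- tabulate(floor(lags) + 1, nbins = 100)
  got <- burstrf:::.pair_lags_ms(tt2, 100)
  expect_equal(tabulate(floor(got) + 1, nbins = 100), counts_ref)
})

test_that("PGN trains give wider autocorrelograms than LGN trains", {
  stim <- make_gaussian_noise(c(4, 4), 3000, seed = 37)
  lin <- gaussian_blob_filter(5, c(4, 4), c(2, 2))
  wid <- sapply(c("pgn_u_shaped", "lgn_decelerating"), function(p) {
    nrn <- ln_neuron(lin, base_rate = 4, gain = 60, burst = p)
    rec <- simulate_response(nrn, stim, n_repeats = 1, seed = 38)
    autocorr_width(rec$repeats[[1]], bin_ms = 1, max_lag_ms = 100)
  })
  expect_gt(wid["pgn_u_shaped"], wid["lgn_decelerating"])
})

test_that("spike classification matches a brute-force frame-index oracle", {
  stim <- make_gaussian_noise(c(4, 4), 3000, seed = 39)
  nrn <- ln_neuron(gaussian_blob_filter(5, c(4, 4), c(2, 2)),
                   base_rate = 5, gain = 60, burst = "pgn_u_shaped")
  rec <- simulate_response(nrn, stim, n_repeats = 1, seed = 40)
  tt <- rec$repeats[[1]]
  bursts <- detect_bursts(tt, "pgn")
  cl <- classify_spikes(tt, bursts, 0.020)
  expect_equal(nrow(cl), length(tt))
  expect_equal(sum(cl$label == "cardinal"), length(bursts))
  # oracle: floor-division frame offsets, computed independently
  for (b in bursts) {
    off_ref <- floor(b$spike_times / 0.020) - floor(b$spike_times[1] / 0.020)
    idx <- cl$time %in% b$spike_times
    expect_equal(cl$frame_offset[idx], as.integer(off_ref))
  }
  lab_ref <- table(factor(unlist(lapply(bursts, function(b) {
    o <- floor(b$spike_times / 0.020) - floor(b$spike_times[1] / 0.020)
    l <- ifelse(o == 0, "group_I", ifelse(o == 1, "group_II",
         ifelse(o == 2, "group_III", "later")))
    l[1] <- "cardinal"
    l
  })), levels = c("cardinal", "group_I", "group_II", "group_III", "later")))
  expect_equal(as.vector(table(factor(cl$label[cl$label != "tonic"],
    levels = names(lab_ref)))), as.vector(lab_ref))
  # tonic-only train
  cl0 <- classify_spikes(c(0.1, 0.5, 0.9), list(), 0.020)
  expect_true(all(cl0$label == "tonic"))
})

test_that("shift-correlation table is cosine-normalized with unit self-correlation", {
  set.seed(41)
  stas <- list(I_shift0 = subunit_filter(array(rnorm(40), c(5, 2, 4))),
               II_shift0 = subunit_filter(array(rnorm(40), c(5, 2, 4))))
  tab <- shift_correlation(stas)
  expect_equal(tab$correlation[tab$group == "I" & tab$shift == 0], 1.0)
  expect_lt(abs(tab$correlation[tab$group == "II"]), 3 / sqrt(40) * 2)
  bad <- list(I_shift0 = stas$I_shift0,
              II_shift0 = subunit_filter(array(1, c(2, 2, 2))))
  expect_error(shift_correlation(bad), "mismatch")
})
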