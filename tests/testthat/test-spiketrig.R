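test_that("ensemble rows are the lagged stimulus windows ending at the spike frame", {
  stim <- make_gaussian_noise(c(4, 4), 20, seed = 51)
  # one spike in (1-based) frame 9, lag 5: window is frames 5..9
  rec <- spike_record(list(8.5 * 0.020), 20, 0.020)
  ens <- build_ensemble(stim, rec, lag_frames = 5, spike_policy = "all")
  expect_equal(dim(ens$matrix), c(1, 80))
  w <- ens$matrix[1, ]
  dim(w) <- c(5, 4, 4)
  for (l in 1:5) expect_equal(w[l, , ], stim$frames[9 - l + 1, , ],
                              ignore_attr = TRUE)
  # spike in the first frame with lag 5 is excluded
  rec0 <- spike_record(list(0.010), 20, 0.020)
  expect_error(build_ensemble(stim, rec0, 5, "all"), "no eligible spikes")
})

test_that("ensemble row means vanish for a stimulus-blind neuron", {
  stim <- make_gaussian_noise(c(3, 3), 6000, seed = 52)
  set.seed(53)
  rec <- spike_record(list(sort(runif(3000, 0.1, 6000 * 0.020 - 0.001))),
                      6000, 0.020)
  ens <- build_ensemble(stim, rec, 4, "all")
  mu <- colMeans(ens$matrix)
  expect_lt(max(abs(mu)), 4 * 0.33 / sqrt(3000))
})

test_that("the STA is the ensemble mean and recovers the true filter", {
  # identical rows reproduce themselves
  stim <- make_gaussian_noise(c(2, 2), 50, seed = 54)
  rec <- spike_record(list(c(9.5, 19.5, 29.5) * 0.020), 50, 0.020)
  ens <- build_ensemble(stim, rec, 3, "all")
  ens$matrix <- ens$matrix[c(1, 1, 1), ]
  sta <- compute_sta(ens)
  expect_equal(as.numeric(sta), ens$matrix[1, ], ignore_attr = TRUE)
  expect_equal(attr(sta, "kind"), "STA")
  # parameter recovery on a linear cell (>= 50 spikes/dimension)
  stim2 <- fx_stim_small()
  lin <- fx_lin_filter()
  nrn <- ln_neuron(lin, base_rate = 2, gain = 250, burst = "none")
  rec2 <- simulate_response(nrn, stim2, n_repeats = 4, seed = 55)
  ens2 <- build_ensemble(stim2, rec2, 5, "all")
  expect_gt(nrow(ens2$matrix) / 80, 50)
  expect_gt(cosine_similarity(compute_sta(ens2), lin), 0.95)
  # time-shuffled spikes kill the STA
  set.seed(56)
  shuf <- lapply(rec2$repeats, function(tt) sort(runif(length(tt), 0.12,
                 4096 * 0.020 - 0.001)))
  ens3 <- build_ensemble(stim2, spike_record(shuf, 4096, 0.020), 5, "all")
  nulls <- replicate(20, {
    s <- lapply(rec2$repeats, function(tt) sort(runif(length(tt), 0.12,
                4096 * 0.020 - 0.001)))
    e <- build_ensemble(stim2, spike_record(s, 4096, 0.020), 5, "all")
    sqrt(sum(compute_sta(e)^2))
  })
  expect_lt(sqrt(sum(compute_sta(ens3)^2)), max(nulls) * 1.5)
  expect_lt(sqrt(sum(compute_sta(ens3)^2)),
            sqrt(sum(compute_sta(ens2)^2)) / 3)
})

test_that("STC covariance matches a brute-force outer-product oracle", {
  stim <- make_gaussian_noise(c(3, 3), 200, seed = 57)
  set.seed(58)
  rec <- spike_record(list(sort(runif(40, 0.05, 200 * 0.020 - 0.001))),
                      200, 0.020)
  ens <- build_ensemble(stim, rec, 2, "all")
  sta <- compute_sta(ens)
  stc <- compute_stc(ens, sta)
  # oracle: center, project, accumulate outer products row by row
  X <- ens$matrix
  mu <- colMeans(X)
  u <- as.numeric(sta); u <- u / sqrt(sum(u^2))
  C <- matrix(0, 18, 18)
  for (i in seq_len(nrow(X))) {
    r <- X[i, ] - mu
    r <- r - sum(r * u) * u
    C <- C + outer(r, r)
  }
  C <- C / (nrow(X) - 1)
  ee <- eigen(C, symmetric = TRUE)
  expect_equal(stc$eigenvalues, ee$values[1:17], tolerance = 1e-10)
})

test_that("STC eigenvectors are orthonormal and orthogonal to the STA", {
  stim <- fx_stim_small()
  rec <- fx_two_subunit_rec()
  ens <- build_ensemble(stim, rec, 5, "all")
  sta <- compute_sta(ens)
  stc <- compute_stc(ens, sta)
  u <- as.numeric(sta) / sqrt(sum(as.numeric(sta)^2))
  V <- stc$eigenvectors
  expect_lt(max(abs(crossprod(V, u))), 1e-8)
  G <- crossprod(V)
  expect_lt(max(abs(G - diag(ncol(V)))), 1e-8)
  expect_true(all(diff(stc$eigenvalues) <= 1e-12))
})

test_that("a null ensemble has a structureless spectrum; an energy cell does not", {
  stim <- make_gaussian_noise(c(3, 3), 8192, seed = 59)
  set.seed(60)
  rec0 <- spike_record(list(sort(runif(4000, 0.1, 8192 * 0.020 - 0.001))),
                       8192, 0.020)
  ens0 <- build_ensemble(stim, rec0, 4, "all")
  stc0 <- compute_stc(ens0)
  # flat within Marchenko-Pastur-type spread around the stimulus variance
  expect_lt(stc0$eigenvalues[1] / stc0$eigenvalues[35], 1.6)
  expect_equal(median(stc0$eigenvalues), 0.33^2, tolerance = 0.05)
  # quadratic-subunit cell: top eigenvector aligns with the true subunit
  q <- gaussian_blob_filter(4, c(3, 3), c(2, 2), sd_space = 0.8)
  nrn <- ln_neuron(quad_filter = q, base_rate = 2, quad_gain = 500,
                   burst = "none")
  rec1 <- simulate_response(nrn, stim, n_repeats = 2, seed = 61)
  ens1 <- build_ensemble(stim, rec1, 4, "all")
  expect_gt(nrow(ens1$matrix) / 36, 50)
  stc1 <- compute_stc(ens1)
  expect_gt(abs(cosine_similarity(stc_filter(stc1, 1), q)), 0.9)
})

test_that("spike-policy STAs of a bursting LN cell agree (cardinal vs tonic vs mixed)", {
  stim <- make_gaussian_noise(c(3, 3), 8192, seed = 62)
  lin <- gaussian_blob_filter(4, c(3, 3), c(2, 2), sd_space = 0.8)
  nrn <- ln_neuron(lin, base_rate = 4, gain = 60, burst = "pgn_u_shaped",
                   burst_threshold = 0.9)
  rec <- suppressWarnings(simulate_response(nrn, stim, n_repeats = 8, seed = 63))
  stas <- lapply(c("cardinal_plus_tonic", "tonic_only", "cardinal_only"),
                 function(p) compute_sta(build_ensemble(stim, rec, 4, p)))
  for (i in 1:2) for (j in (i + 1):3)
    expect_gt(cosine_similarity(stas[[i]], stas[[j]]), 0.9)
})

test_that("bootstrap significance finds the quadratic subunit and nothing else", {
  stim <- make_gaussian_noise(c(4, 4), 8192, seed = 64)
  q <- gaussian_blob_filter(5, c(4, 4), c(2, 3), peak_lag = 2)
  nrn <- ln_neuron(quad_filter = q, base_rate = 2, quad_gain = 250,
                   burst = "none")
  rec <- simulate_response(nrn, stim, n_repeats = 1, seed = 65)
  bs <- bootstrap_significance(stim, rec, 5, n_boot = 200,
                               spike_policy = "all", seed = 66)
  expect_equal(length(bs$significant_indices), 1)
  expect_equal(bs$significant_indices, 1L)
  expect_gt(abs(cosine_similarity(bs$significant_filters[[1]], q)), 0.8)
  expect_length(bs$ci_lower, 79)
  expect_true(all(bs$ci_upper >= bs$ci_lower))
  # degenerate bound: alpha = 1 makes every rank an exceedance
  bs1 <- bootstrap_significance(stim, rec, 5, n_boot = 100, alpha = 1,
                                spike_policy = "all", seed = 67)
  expect_length(bs1$exceedance_indices, 79)
  # guard: recording must exceed 10 lag windows
  tiny <- make_gaussian_noise(c(2, 2), 30, seed = 68)
  expect_error(bootstrap_significance(tiny,
    spike_record(list(c(0.1, 0.2)), 30, 0.020), 5, 100, spike_policy = "all"),
    "refusing")
})

test_that("the most non-significant subunit hugs the null median", {
  stim <- make_gaussian_noise(c(3, 3), 4096, seed = 69)
  set.seed(70)
  rec <- spike_record(list(sort(runif(2000, 0.1, 4096 * 0.020 - 0.001))),
                      4096, 0.020)
  bs <- bootstrap_significance(stim, rec, 4, n_boot = 150,
                               spike_policy = "all", seed = 71)
  f <- most_nonsignificant(bs)
  r <- attr(f, "rank")
  expect_false(r %in% bs$significant_indices)
  expect_equal(bs$eigenvalues[r], bs$null_median[r],
               tolerance = 0.02)
})

test_that("sparse-noise ON/OFF maps separate bright and dark responses", {
  gs <- c(4, 4)
  sp <- make_sparse_noise(gs, n_visits = 30, contrast = 1, seed = 72)
  # bright-only cell at pixel (2,2): positive blob filter, half-rectified
  on_only <- gaussian_blob_filter(2, gs, c(2, 2), sd_space = 0.6, peak_lag = 1)
  nrn <- ln_neuron(on_only, base_rate = 0.2, gain = 400, burst = "none")
  rec <- simulate_response(nrn, sp, n_repeats = 6, seed = 73)
  maps <- sparse_sta(sp, rec, lag_frames = 2)
  m_on <- spatial_map(maps$sta_on, maps$peak_lag)
  expect_equal(which.max(m_on), 2 + (2 - 1) * 4)   # pixel (2,2), column-major
  expect_lt(max(spatial_map(maps$sta_off, maps$peak_lag)) / max(m_on), 0.35)
  expect_lt(maps$overlap_percent, 40)
  # sign-blind (energy) cell at one pixel: ON and OFF maps coincide
  qd <- on_only
  nrn2 <- ln_neuron(quad_filter = qd, base_rate = 0.2, quad_gain = 600,
                    burst = "none")
  rec2 <- simulate_response(nrn2, sp, n_repeats = 6, seed = 74)
  maps2 <- sparse_sta(sp, rec2, lag_frames = 2)
  expect_gt(maps2$overlap_percent, 85)
  # gaussian stimulus is rejected
  expect_error(sparse_sta(fx_stim_small(), rec, 2), "sparse")
})

test_that("displaced ON/OFF Gaussians overlap as the analytic inner product predicts", {
  gs <- c(8, 8)
  # ON input centred at (4,4), OFF input displaced by one pixel to (4,5)
  on_f <- gaussian_blob_filter(2, gs, c(4, 4), sd_space = 1.0, peak_lag = 1)
  off_f <- gaussian_blob_filter(2, gs, c(4, 5), sd_space = 1.0, peak_lag = 1)
  nrn <- ln_neuron(on_f, off_filter = off_f, base_rate = 0.3,
                   gain = 300, off_gain = 300, burst = "none")
  sp <- make_sparse_noise(gs, n_visits = 20, contrast = 1, seed = 75)
  rec <- simulate_response(nrn, sp, n_repeats = 4, seed = 76)
  maps <- sparse_sta(sp, rec, lag_frames = 2)
  analytic <- 100 * exp(-1 / (4 * 1.0^2))  # unit-offset Gaussian inner product
  expect_equal(maps$overlap_percent, analytic, tolerance = 0.10)
})
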