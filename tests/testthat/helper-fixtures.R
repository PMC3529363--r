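# Shared fixtures, built once per test session.
.fx <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fx)) assign(name, force(expr), envir = .fx)
  get(name, envir = .fx)
}

# small Gaussian-noise movie shared by several files
fx_stim_small <- function() fixture("stim_small",
  make_gaussian_noise(c(4, 4), 4096, 0.020, 0.33, seed = 101))

fx_lin_filter <- function() fixture("lin_filter",
  gaussian_blob_filter(5, c(4, 4), c(2, 2), sd_space = 0.9, peak_lag = 2))

fx_quad_filter <- function() fixture("quad_filter",
  gaussian_blob_filter(5, c(4, 4), c(3, 3), sd_space = 0.9, peak_lag = 2))

# linear + quadratic two-subunit cell on the shared movie, 8 repeats
fx_two_subunit_rec <- function() fixture("two_subunit_rec", {
  nrn <- ln_neuron(fx_lin_filter(), fx_quad_filter(), base_rate = 4,
                   gain = 150, quad_gain = 400, burst = "none")
  simulate_response(nrn, fx_stim_small(), n_repeats = 8, seed = 102)
})

# independent brute-force burst scan, written against the rule text only
oracle_bursts <- function(tt, criteria) {
  par <- if (criteria == "lgn")
    list(sil = 0.100, isi = 0.004, min = 2, win = Inf)
  else list(sil = 0.070, isi = 0.030, min = 5, win = 0.070)
  n <- length(tt)
  out <- list()
  used_until <- -Inf
  for (i in seq_len(n)) {
    if (tt[i] <= used_until) next
    sil <- if (i == 1) Inf else tt[i] - tt[i - 1]
    if (sil < par$sil) next
    j <- i
    while (j < n && tt[j + 1] - tt[j] <= par$isi) j <- j + 1
    run <- tt[i:j]
    if (length(run) >= 2 &&
        sum(run - run[1] <= par$win) >= par$min) {
      out[[length(out) + 1L]] <- run
      used_until <- tt[j]
    }
  }
  out
}
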