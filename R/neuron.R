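#' Spatiotemporal Gaussian-blob filter
#'
#' Convenience constructor for ground-truth subunits: a spatial Gaussian blob
#' (optionally two blobs of opposite sign) multiplied by a biphasic temporal
#' kernel, normalized to unit Euclidean norm. Lag 1 is the frame coincident
#' with the spike; higher lags reach further back in time.
#'
#' @param n_lags number of stimulus frames the filter spans.
#' @param grid_shape `c(rows, cols)`.
#' @param center `c(row, col)` of the (first) blob centre, in pixels.
#' @param sd_space spatial standard deviation of the blob, in pixels.
#' @param peak_lag lag index at which the temporal kernel peaks.
#' @param polarity +1 for an ON (bright-preferring) blob, -1 for OFF.
#' @param center2,polarity2 optional second blob (e.g. a flanking subregion).
#'
#' @return numeric array `n_lags x rows x cols` of class `subunit_filter`
#'   with `kind = "model"`, unit norm.
#' @export
gaussian_blob_filter <- function(n_lags, grid_shape, center,
                                 sd_space = 1.0, peak_lag = 3, polarity = 1,
                                 center2 = NULL, polarity2 = -1) {
  rows <- grid_shape[1L]; cols <- grid_shape[2L]
  blob <- function(ctr, pol) {
    pol * exp(-0.5 * (outer((seq_len(rows) - ctr[1L])^2,
                            (seq_len(cols) - ctr[2L])^2, "+")) / sd_space^2)
  }
  sp <- blob(center, polarity)
  if (!is.null(center2)) sp <- sp + blob(center2, polarity2)
  lag <- seq_len(n_lags)
  tk <- exp(-0.5 * ((lag - peak_lag) / 0.9)^2) -
    0.35 * exp(-0.5 * ((lag - peak_lag - 1.6) / 1.1)^2)
  w <- array(0, dim = c(n_lags, rows, cols))
  for (l in lag) w[l, , ] <- tk[l] * sp
  subunit_filter(w / sqrt(sum(w^2)), kind = "model")
}

#' Burst firing profiles
#'
#' Templates of within-burst interspike intervals (ISIs, ms), the jitter of
#' each ISI and the silence required before a burst can begin. LGN relay
#' cells fire short decelerating bursts (successive ISIs grow, each <= 4 ms);
#' PGN reticular cells fire long accelerating-then-decelerating bursts
#' (U-shaped ISI sequence, 5+ spikes over 70-100 ms).
#'
#' @param profile `"lgn_decelerating"`, `"pgn_u_shaped"` or `"none"`.
#' @return list with `isi_template_ms`, `jitter_sd_ms`,
#'   `refractory_silence_ms` and `post_gap_ms` (tonic suppression after the
#'   last burst spike, keeping detected and inserted bursts congruent),
#'   or `NULL` for `"none"`.
#' @export
burst_profile <- function(profile = c("none", "lgn_decelerating", "pgn_u_shaped")) {
  profile <- match.arg(profile)
  switch(profile,
    none = NULL,
    lgn_decelerating = list(name = "lgn_decelerating",
                            isi_template_ms = c(1.5, 2.0, 2.7, 3.4),
                            jitter_sd_ms = 0.12,
                            refractory_silence_ms = 100,
                            post_gap_ms = 31),
    pgn_u_shaped = list(name = "pgn_u_shaped",
                        isi_template_ms = c(20, 13, 7, 3.5, 7, 13, 20),
                        jitter_sd_ms = 0.6,
                        refractory_silence_ms = 70,
                        post_gap_ms = 31))
}

#' Ground-truth linear-nonlinear neuron
#'
#' Defines a simulated neuron with a first-order (linear) subunit and
#' optionally a second-order (quadratic, energy-model) subunit, a parametric
#' output nonlinearity and a burst-firing profile. Used to validate every
#' recovery stage of the package by construction.
#'
#' The firing rate at frame t is
#' `base_rate + gain * max(s_L, 0) + off_gain * max(-s_OFF, 0) +
#' quad_gain * s_Q^2`, where `s_L`, `s_OFF` and `s_Q` are the projections
#' of the trailing stimulus window on the respective filters. The linear
#' (ON) and `off_filter` (OFF) channels are half-rectified with opposite
#' preferred sign, emulating convergent ON- and OFF-center relay input;
#' the quadratic channel is full-wave (energy-model) like.
#'
#' @param linear_filter `subunit_filter` array (lags x rows x cols) or NULL.
#' @param quad_filter optional second-order subunit of the same shape.
#' @param off_filter optional half-rectified dark-preferring channel
#'   (stored with positive weights; drives firing when its projection is
#'   negative).
#' @param base_rate spontaneous rate, spikes/s.
#' @param gain rate gain per unit of (rectified) linear drive, spikes/s.
#' @param quad_gain rate gain per unit of squared quadratic drive, spikes/s.
#' @param off_gain rate gain of the OFF channel, spikes/s.
#' @param burst `"none"`, `"lgn_decelerating"` or `"pgn_u_shaped"`, or a list
#'   as returned by [burst_profile()].
#' @param burst_threshold z-score of the drive above which a burst is
#'   initiated (given sufficient preceding silence).
#'
#' @return an object of class `ln_neuron`.
#' @export
ln_neuron <- function(linear_filter = NULL, quad_filter = NULL,
                      off_filter = NULL,
                      base_rate = 5, gain = 150, quad_gain = 250,
                      off_gain = 150,
                      burst = "none", burst_threshold = 1.3) {
  if (is.null(linear_filter) && is.null(quad_filter) && is.null(off_filter))
    stop("at least one filter is required")
  unitize <- function(w) {
    if (is.null(w)) return(NULL)
    nrm <- sqrt(sum(w^2))
    if (nrm > 0) w / nrm else w
  }
  if (is.character(burst)) burst <- burst_profile(burst)
  structure(list(linear_filter = unitize(linear_filter),
                 quad_filter = unitize(quad_filter),
                 off_filter = unitize(off_filter),
                 base_rate = base_rate, gain = gain, quad_gain = quad_gain,
                 off_gain = off_gain,
                 burst = burst, burst_threshold = burst_threshold),
            class = "ln_neuron")
}

#' @export
print.ln_neuron <- function(x, ...) {
  cat(sprintf("<ln_neuron> linear:%s quad:%s base %.1f sp/s, bursts: %s\n",
              if (is.null(x$linear_filter)) "no" else "yes",
              if (is.null(x$quad_filter)) "no" else "yes",
              x$base_rate,
              if (is.null(x$burst)) "none" else x$burst$name))
  invisible(x)
}

# Per-frame drive of a filter, with zero padding before stimulus onset
# (screen at mean luminance). Lag 1 = coincident frame.
.frame_drive <- function(stimulus, filter) {
  if (is.null(filter)) return(NULL)
  nf <- dim(stimulus$frames)[1L]
  fm <- matrix(stimulus$frames, nrow = nf)
  dims <- dim(filter)
  stopifnot(dims[2L] == dim(stimulus$frames)[2L],
            dims[3L] == dim(stimulus$frames)[3L])
  n_lags <- dims[1L]
  if (n_lags > nf) stop("filter spans more lags than the stimulus has frames")
  drive <- numeric(nf)
  wl <- matrix(filter, nrow = n_lags)   # n_lags x pixels
  for (l in seq_len(n_lags)) {
    contrib <- fm %*% wl[l, ]
    drive[l:nf] <- drive[l:nf] + contrib[seq_len(nf - l + 1L)]
  }
  drive
}

#' Simulate spike responses of a ground-truth neuron
#'
#' Forward model that the recovery stages must invert. Per frame, the drive
#' of each filter is passed through the neuron's output nonlinearity to an
#' instantaneous rate; tonic spikes are drawn as an inhomogeneous Poisson
#' process at 1 ms resolution. When the (standardized) drive exceeds the
#' neuron's burst threshold and the preceding silence exceeds the profile's
#' refractory requirement, an all-or-none burst is inserted by sampling the
#' ISI template with jitter; tonic firing is suppressed for the duration of
#' the burst plus a short gap. The jittered ISI sequence is re-sorted to
#' preserve the template's shape (monotone for LGN, U-shaped for PGN).
#'
#' @param neuron an [ln_neuron()].
#' @param stimulus a `stim_movie`.
#' @param n_repeats number of repeats of the (frozen) stimulus.
#' @param seed integer seed.
#' @param dt spike discretization step in seconds (default 0.001).
#'
#' @return a `spike_record`: list with `repeats` (list of ascending spike
#'   times in seconds), `labels` (list of data frames with per-spike `label`
#'   `"tonic"`/`"cardinal"`/`"burst"` and `group` = stimulus-frame offset
#'   from the cardinal spike, NA for tonic), `n_frames`, `frame_duration`. The
#'   attribute `"insertions"` logs every inserted burst (repeat, cardinal
#'   time, frame, spike count).
#' @export
simulate_response <- function(neuron, stimulus, n_repeats = 1L, seed = 1L,
                              dt = 0.001) {
  stopifnot(inherits(neuron, "ln_neuron"), inherits(stimulus, "stim_movie"))
  old <- .seed_state(seed)
  on.exit(.restore_seed(old))
  nf <- dim(stimulus$frames)[1L]
  fd <- stimulus$frame_duration
  dl <- .frame_drive(stimulus, neuron$linear_filter)
  dq <- .frame_drive(stimulus, neuron$quad_filter)
  doff <- .frame_drive(stimulus, neuron$off_filter)
  rate <- rep(neuron$base_rate, nf)
  if (!is.null(dl)) rate <- rate + neuron$gain * pmax(dl, 0)
  if (!is.null(dq)) rate <- rate + neuron$quad_gain * dq^2
  if (!is.null(doff)) rate <- rate + neuron$off_gain * pmax(-doff, 0)
  # drive used for burst triggering, standardized
  bdrive <- if (!is.null(dl)) dl else if (!is.null(dq)) dq^2 else rep(0, nf)
  sdb <- stats::sd(bdrive)
  bz <- if (is.na(sdb) || sdb == 0) rep(0, nf) else
    (bdrive - mean(bdrive)) / sdb
  total_t <- nf * fd
  n_ms <- floor(total_t / dt)
  prof <- neuron$burst
  repeats <- vector("list", n_repeats)
  labels <- vector("list", n_repeats)
  ins <- list()
  truncated <- FALSE
  for (r in seq_len(n_repeats)) {
    p_tonic <- rate[pmin(floor(((seq_len(n_ms) - 0.5) * dt) / fd) + 1L, nf)] * dt
    u <- stats::runif(n_ms)
    times <- numeric(0); lab <- character(0); grp <- integer(0)
    last_spike <- -Inf
    i <- 1L
    while (i <= n_ms) {
      t_i <- (i - 0.5) * dt
      f_i <- min(floor(t_i / fd) + 1L, nf)
      if (!is.null(prof) &&
          bz[f_i] > neuron$burst_threshold &&
          (t_i - last_spike) * 1000 >= prof$refractory_silence_ms) {
        isis <- prof$isi_template_ms +
          stats::rnorm(length(prof$isi_template_ms), 0, prof$jitter_sd_ms)
        isis <- pmax(isis, 0.5)
        isis <- .shape_sort(isis, prof$name)
        bt <- t_i + c(0, cumsum(isis)) / 1000
        keep <- bt < total_t
        if (!all(keep)) { truncated <- TRUE; bt <- bt[keep] }
        if (length(bt)) {
          g <- floor(bt / fd) - floor(bt[1L] / fd)
          times <- c(times, bt)
          lab <- c(lab, c("cardinal", rep("burst", length(bt) - 1L)))
          grp <- c(grp, as.integer(g))
          last_spike <- bt[length(bt)]
          ins[[length(ins) + 1L]] <- data.frame(
            rep = r, t_cardinal = bt[1L],
            frame = floor(bt[1L] / fd) + 1L, n_spikes = length(bt))
          i <- ceiling((last_spike + prof$post_gap_ms / 1000) / dt) + 1L
          next
        }
      }
      if (u[i] < p_tonic[i]) {
        times <- c(times, t_i)
        lab <- c(lab, "tonic"); grp <- c(grp, NA_integer_)
        last_spike <- t_i
      }
      i <- i + 1L
    }
    repeats[[r]] <- times
    labels[[r]] <- data.frame(time = times, label = lab, group = grp)
  }
  if (truncated)
    warning("burst template extended past stimulus end; burst truncated")
  rec <- structure(list(repeats = repeats, labels = labels,
                        n_frames = nf, frame_duration = fd,
                        stimulus_kind = stimulus$kind),
                   class = "spike_record")
  attr(rec, "insertions") <- if (length(ins)) do.call(rbind, ins) else
    data.frame(rep = integer(0), t_cardinal = numeric(0),
               frame = integer(0), n_spikes = integer(0))
  rec
}

# Re-impose the template's shape on a jittered ISI sequence: decelerating
# bursts stay monotone increasing; U-shaped bursts decrease then increase.
.shape_sort <- function(isis, name) {
  if (name == "lgn_decelerating") return(sort(isis))
  if (name == "pgn_u_shaped") {
    k <- ceiling(length(isis) / 2)
    c(sort(isis[seq_len(k)], decreasing = TRUE),
      sort(isis[-seq_len(k)]))
  } else isis
}

#' Construct a spike record from raw spike times
#'
#' @param repeats list of numeric vectors of ascending spike times (s), one
#'   per stimulus repeat (a single numeric vector is accepted).
#' @param n_frames,frame_duration geometry of the paired stimulus.
#' @return a `spike_record`.
#' @export
spike_record <- function(repeats, n_frames, frame_duration) {
  if (is.numeric(repeats)) repeats <- list(repeats)
  for (r in repeats) {
    if (is.unsorted(r, strictly = TRUE))
      stop("spike times must be strictly ascending within a repeat")
  }
  structure(list(repeats = repeats, labels = NULL,
                 n_frames = n_frames, frame_duration = frame_duration,
                 stimulus_kind = NA_character_),
            class = "spike_record")
}

#' @export
print.spike_record <- function(x, ...) {
  cat(sprintf("<spike_record> %d repeat(s), %s spikes, %d frames x %.1f ms\n",
              length(x$repeats), sum(lengths(x$repeats)),
              x$n_frames, 1000 * x$frame_duration))
  invisible(x)
}
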