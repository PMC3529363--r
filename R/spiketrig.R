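# Lagged design matrix: row f holds the stimulus window ending at frame f,
# columns ordered so that as.numeric(array(lags x rows x cols)) matches
# (lags contiguous within each pixel, pixels column-major).
.lagged_design <- function(stimulus, lag_frames) {
  nf <- dim(stimulus$frames)[1L]
  npix <- prod(dim(stimulus$frames)[2:3])
  fm <- matrix(stimulus$frames, nrow = nf)
  D <- matrix(NA_real_, nf, lag_frames * npix)
  for (l in seq_len(lag_frames)) {
    cols <- seq(l, by = lag_frames, length.out = npix)
    D[l:nf, cols] <- fm[seq_len(nf - l + 1L), ]
  }
  D
}

# Ensemble from explicit trigger times (seconds); frames with incomplete
# windows are excluded.
.times_ensemble <- function(stimulus, times, lag_frames) {
  fd <- stimulus$frame_duration
  nf <- dim(stimulus$frames)[1L]
  f <- floor(times / fd) + 1L
  f <- f[f >= lag_frames & f <= nf]
  D <- .lagged_design(stimulus, lag_frames)
  structure(list(matrix = D[f, , drop = FALSE], frames = f,
                 lag_frames = as.integer(lag_frames),
                 frame_duration = fd,
                 grid_shape = dim(stimulus$frames)[2:3],
                 spike_policy = "explicit"),
            class = "spike_ensemble")
}

.policy_labels <- list(
  cardinal_plus_tonic = c("tonic", "cardinal"),
  tonic_only = "tonic",
  cardinal_only = "cardinal")

#' Build the spike-triggered stimulus ensemble
#'
#' Each row of the ensemble is the stimulus window of `lag_frames` frames
#' ending with the frame that contains one spike (lag 1 = coincident
#' frame). Because later spikes of a burst are driven by the stimulus that
#' triggered the cardinal spike, the default policy uses tonic spikes plus
#' only the cardinal spike of each burst; this avoids temporal blurring of
#' the receptive field.
#'
#' @param stimulus a `stim_movie`.
#' @param spike_record a `spike_record`; spikes are pooled across repeats.
#' @param lag_frames window length in frames (default 6, covering 0-120 ms
#'   at 20 ms/frame).
#' @param spike_policy `"cardinal_plus_tonic"` (default), `"tonic_only"`,
#'   `"cardinal_only"` or `"all"`.
#' @param classification optional per-repeat list of data frames from
#'   [classify_spikes()]; required for policies other than `"all"` when the
#'   record carries no labels of its own.
#' @return a `spike_ensemble`: list with `matrix`
#'   (`n_spikes x (lags*rows*cols)`), `frames`, `lag_frames`,
#'   `frame_duration`, `grid_shape`, `spike_policy`.
#' @export
build_ensemble <- function(stimulus, spike_record, lag_frames = 6L,
                           spike_policy = c("cardinal_plus_tonic",
                                            "tonic_only", "cardinal_only",
                                            "all"),
                           classification = NULL) {
  spike_policy <- match.arg(spike_policy)
  if (lag_frames < 1L) stop("'lag_frames' must be >= 1")
  times <- .policy_times(spike_record, spike_policy, classification)
  ens <- .times_ensemble(stimulus, times, lag_frames)
  if (!nrow(ens$matrix)) stop("no eligible spikes for the ensemble")
  ens$spike_policy <- spike_policy
  ens
}

.policy_times <- function(spike_record, spike_policy, classification = NULL) {
  if (spike_policy == "all") return(sort(unlist(spike_record$repeats)))
  keep <- .policy_labels[[spike_policy]]
  if (!is.null(classification)) {
    if (is.data.frame(classification)) classification <- list(classification)
    # classify_spikes labels: map group_* / later to burst membership
    times <- lapply(classification, function(cl)
      cl$time[cl$label %in% keep])
  } else if (!is.null(spike_record$labels)) {
    times <- lapply(spike_record$labels, function(lb)
      lb$time[lb$label %in% keep])
  } else {
    stop("spike-policy filtering needs labels or a 'classification'")
  }
  sort(unlist(times))
}

#' Spike-triggered average
#'
#' The column-wise mean of the spike-triggered stimulus ensemble, reshaped
#' to a spatiotemporal filter. This is the first-order receptive-field
#' subunit, in stimulus contrast units.
#'
#' @param ensemble a `spike_ensemble` from [build_ensemble()].
#' @return a `subunit_filter` of kind `"STA"`.
#' @export
compute_sta <- function(ensemble) {
  if (!nrow(ensemble$matrix)) stop("empty ensemble")
  w <- colMeans(ensemble$matrix)
  dim(w) <- c(ensemble$lag_frames, ensemble$grid_shape)
  subunit_filter(w, kind = "STA")
}

#' Spike-triggered covariance analysis
#'
#' Rows of the ensemble are centred on the ensemble mean and the STA
#' direction is projected out; the eigen-decomposition of the resulting
#' covariance matrix (1/(n-1) normalization) recovers second-order
#' subunits. The zero eigenvalue created by the projection is dropped, so
#' D-1 eigenvalues are returned in descending order.
#'
#' @param ensemble a `spike_ensemble`.
#' @param sta optional STA to project out; computed from the ensemble when
#'   omitted. A zero-norm STA skips the projection with a warning.
#' @return an `stc_result`: `eigenvalues` (length D-1, descending),
#'   `eigenvectors` (D x (D-1)), plus geometry fields. Use [stc_filter()]
#'   to extract an eigenvector as a `subunit_filter`.
#' @export
compute_stc <- function(ensemble, sta = NULL) {
  X <- ensemble$matrix
  D <- ncol(X)
  if (nrow(X) < D)
    warning("fewer ensemble rows than stimulus dimensions; spectrum is noisy")
  if (is.null(sta)) sta <- compute_sta(ensemble)
  sv <- as.numeric(sta)
  n_drop <- 0L
  Xc <- sweep(X, 2L, colMeans(X))
  nrm <- sqrt(sum(sv^2))
  if (nrm > 0) {
    u <- sv / nrm
    Xc <- Xc - (Xc %*% u) %*% t(u)
    n_drop <- 1L
  } else {
    warning("zero-norm STA; projection skipped")
  }
  C <- crossprod(Xc) / (nrow(X) - 1L)
  ee <- eigen(C, symmetric = TRUE)
  keep <- seq_len(D - n_drop)
  structure(list(eigenvalues = ee$values[keep],
                 eigenvectors = ee$vectors[, keep, drop = FALSE],
                 ci_lower = NULL, ci_upper = NULL, null_median = NULL,
                 significant_indices = integer(0),
                 significant_filters = list(),
                 lag_frames = ensemble$lag_frames,
                 grid_shape = ensemble$grid_shape),
            class = "stc_result")
}

#' Extract an STC eigenvector as a spatiotemporal filter
#' @param stc an `stc_result`.
#' @param k rank of the eigenvector (1 = largest eigenvalue).
#' @return a unit-norm `subunit_filter` of kind `"STC_k"`.
#' @export
stc_filter <- function(stc, k = 1L) {
  w <- stc$eigenvectors[, k]
  dim(w) <- c(stc$lag_frames, stc$grid_shape)
  subunit_filter(w, kind = sprintf("STC_%d", k),
                 eigenvalue = stc$eigenvalues[k],
                 significant = if (length(stc$significant_indices))
                   k %in% stc$significant_indices else NULL,
                 rank = as.integer(k))
}

#' @export
print.stc_result <- function(x, ...) {
  cat(sprintf("<stc_result> %d eigenvalues", length(x$eigenvalues)))
  if (length(x$significant_indices))
    cat(sprintf(", significant ranks: %s",
                paste(x$significant_indices, collapse = ", ")))
  else if (!is.null(x$ci_lower)) cat(", no significant subunit")
  cat("\n")
  invisible(x)
}

#' Nested-bootstrap significance of STC eigenvalues
#'
#' Surrogate spike trains are made by circularly rotating all spike times
#' by a uniform random offset of at least the lag window, which preserves
#' the spike-train statistics exactly while destroying stimulus alignment.
#' Each surrogate is run through the full STA-projection + STC pipeline.
#'
#' Two complementary tests are reported. (1) Per-rank bounds: the `alpha`
#' and `1 - alpha` quantiles of the surrogate eigenvalues at each rank
#' (`ci_lower`, `ci_upper`), with `exceedance_indices` listing real
#' eigenvalues outside their rank's band. This descriptive test is
#' calibrated rank-wise (expected `2 * alpha * D` exceedances on a
#' stimulus-blind cell) and draws the familiar spectrum-with-bounds plot.
#' (2) The nested test that defines `significant_indices`: the extreme
#' remaining real eigenvalue (largest, or smallest for suppressive
#' subunits) is compared with the matching extreme of the surrogate
#' remainder; if it falls outside, its eigenvector is projected out of the
#' real and surrogate ensembles and the remainder is re-tested, until no
#' further subunit is added. This sequential form controls the
#' family-wise error at about `2 * alpha` per cell, so the subunits it
#' returns are the ones safe to carry into LN models.
#'
#' @inheritParams build_ensemble
#' @param n_boot number of surrogates (>= 100; default 1000).
#' @param alpha per-tail significance level (default 0.01).
#' @param seed integer seed for the surrogate offsets.
#' @return an `stc_result` with `eigenvalues`, `eigenvectors` (first
#'   pass), `ci_lower`, `ci_upper`, `null_median` per rank,
#'   `exceedance_indices`, `significant_indices` and
#'   `significant_filters`.
#' @export
bootstrap_significance <- function(stimulus, spike_record, lag_frames = 6L,
                                   n_boot = 1000L, alpha = 0.01,
                                   spike_policy = "cardinal_plus_tonic",
                                   classification = NULL, seed = 1L) {
  if (n_boot < 100L) stop("'n_boot' must be >= 100")
  nf <- dim(stimulus$frames)[1L]
  if (nf < 10L * lag_frames)
    stop("recording shorter than 10 lag windows; refusing")
  old <- .seed_state(seed)
  on.exit(.restore_seed(old))
  times <- .policy_times(spike_record, spike_policy, classification)
  fd <- stimulus$frame_duration
  f_real <- floor(times / fd) + 1L
  f_real <- f_real[f_real <= nf]
  Dmat <- .lagged_design(stimulus, lag_frames)
  D <- ncol(Dmat)
  offsets <- sample(seq.int(lag_frames, nf - lag_frames), n_boot,
                    replace = TRUE)
  spectrum <- function(frames, extra = NULL, vectors = TRUE) {
    frames <- frames[frames >= lag_frames]
    X <- Dmat[frames, , drop = FALSE]
    mu <- colMeans(X)
    Xc <- sweep(X, 2L, mu)
    P <- mu / sqrt(sum(mu^2))
    if (!is.null(extra)) P <- qr.Q(qr(cbind(P, extra)))
    P <- as.matrix(P)
    Xc <- Xc - (Xc %*% P) %*% t(P)
    ee <- eigen(crossprod(Xc) / (nrow(X) - 1L), symmetric = TRUE,
                only.values = !vectors)
    keep <- seq_len(D - ncol(P))
    list(values = ee$values[keep],
         vectors = if (vectors) ee$vectors[, keep, drop = FALSE])
  }
  surrogate_frames <- lapply(offsets, function(o) (f_real + o - 1L) %% nf + 1L)
  # first pass: full spectra, per-rank bounds
  real1 <- spectrum(f_real)
  null1 <- vapply(surrogate_frames,
                  function(fr) spectrum(fr, vectors = FALSE)$values,
                  numeric(length(real1$values)))
  lo <- apply(null1, 1L, stats::quantile, probs = alpha, names = FALSE)
  hi <- apply(null1, 1L, stats::quantile, probs = 1 - alpha, names = FALSE)
  med <- apply(null1, 1L, stats::median)
  exceed <- which(real1$values > hi | real1$values < lo)
  # nested sequential test on the extreme remaining eigenvalue
  extra <- NULL
  sig_filters <- list()
  real <- real1
  null_top <- null1[1L, ]
  null_bot <- null1[nrow(null1), ]
  repeat {
    m <- length(real$values)
    top_hi <- stats::quantile(null_top, 1 - alpha, names = FALSE)
    bot_lo <- stats::quantile(null_bot, alpha, names = FALSE)
    pick <- if (real$values[1L] > top_hi) 1L
            else if (real$values[m] < bot_lo) m
            else break
    sig_filters[[length(sig_filters) + 1L]] <-
      list(vector = real$vectors[, pick], eigenvalue = real$values[pick])
    extra <- cbind(extra, real$vectors[, pick])
    if (ncol(extra) >= D - 2L) break
    real <- spectrum(f_real, extra)
    nullk <- vapply(surrogate_frames, function(fr)
      range(spectrum(fr, extra, vectors = FALSE)$values), numeric(2L))
    null_bot <- nullk[1L, ]; null_top <- nullk[2L, ]
  }
  # map significant vectors to first-pass ranks
  sig_idx <- integer(0)
  filters <- list()
  gs <- dim(stimulus$frames)[2:3]
  for (sf in sig_filters) {
    r <- which.max(abs(crossprod(real1$vectors, sf$vector)))
    sig_idx <- c(sig_idx, r)
    w <- sf$vector
    dim(w) <- c(lag_frames, gs)
    filters[[length(filters) + 1L]] <-
      subunit_filter(w, kind = sprintf("STC_%d", length(filters) + 1L),
                     eigenvalue = sf$eigenvalue, significant = TRUE,
                     rank = r)
  }
  structure(list(eigenvalues = real1$values,
                 eigenvectors = real1$vectors,
                 ci_lower = lo, ci_upper = hi, null_median = med,
                 exceedance_indices = exceed,
                 significant_indices = sort(unique(sig_idx)),
                 significant_filters = filters,
                 lag_frames = as.integer(lag_frames),
                 grid_shape = gs),
            class = "stc_result")
}

#' Most non-significant STC subunit
#'
#' The eigenvector whose eigenvalue is closest to the median of its rank's
#' null distribution. Such a subunit carries no stimulus information by
#' construction and serves as the finite-sampling bias reference for the
#' mutual-information estimates.
#'
#' @param stc an `stc_result` from [bootstrap_significance()].
#' @return a `subunit_filter`.
#' @export
most_nonsignificant <- function(stc) {
  if (is.null(stc$null_median))
    stop("requires an stc_result with bootstrap bounds")
  cand <- setdiff(seq_along(stc$eigenvalues), stc$significant_indices)
  r <- cand[which.min(abs(stc$eigenvalues[cand] - stc$null_median[cand]))]
  stc_filter(stc, r)
}

#' ON and OFF receptive-field maps from sparse noise
#'
#' Separate spike-triggered averages of only the bright flashes (STA_ON)
#' and only the dark flashes (STA_OFF). Both maps are stored as response
#' strength per pixel (dark maps are not sign-flipped). The spatial overlap
#' of the two maps is the normalized dot product at their common peak lag,
#' in percent.
#'
#' @param stimulus a sparse `stim_movie`.
#' @param spike_record a `spike_record`.
#' @param lag_frames window length in frames.
#' @return list of class `on_off_maps`: `sta_on`, `sta_off`
#'   (`subunit_filter`s), `overlap_percent`, `peak_lag`.
#' @export
sparse_sta <- function(stimulus, spike_record, lag_frames = 4L) {
  if (stimulus$kind != "sparse") stop("'stimulus' must be sparse noise")
  times <- sort(unlist(spike_record$repeats))
  ens <- .times_ensemble(stimulus, times, lag_frames)
  if (!nrow(ens$matrix)) stop("no eligible spikes")
  on <- colMeans(pmax(ens$matrix, 0))
  off <- colMeans(pmax(-ens$matrix, 0))
  gs <- ens$grid_shape
  dim(on) <- c(lag_frames, gs); dim(off) <- c(lag_frames, gs)
  pwr <- vapply(seq_len(lag_frames),
                function(l) sum(on[l, , ]^2) + sum(off[l, , ]^2), 0)
  pl <- which.max(pwr)
  a <- as.numeric(on[pl, , ]); b <- as.numeric(off[pl, , ])
  overlap <- if (sum(a^2) == 0 || sum(b^2) == 0) NA_real_ else
    100 * sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
  structure(list(sta_on = subunit_filter(on, kind = "STA_ON"),
                 sta_off = subunit_filter(off, kind = "STA_OFF"),
                 overlap_percent = overlap, peak_lag = pl),
            class = "on_off_maps")
}

#' @export
print.on_off_maps <- function(x, ...) {
  cat(sprintf("<on_off_maps> overlap %.1f%% at lag %d\n",
              x$overlap_percent, x$peak_lag))
  invisible(x)
}
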