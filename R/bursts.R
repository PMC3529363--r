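#' Detect bursts in a spike train
#'
#' Interval-based burst detection with the standard criteria for the two
#' thalamic nuclei. LGN relay-cell bursts are two or more spikes, each
#' spaced at most 4 ms apart, following at least 100 ms of silence. PGN
#' reticular-cell bursts require at least 5 spikes within the first 70 ms
#' (anchored at the cardinal spike), spikes spaced at most 30 ms apart,
#' following at least 70 ms of silence; the burst terminates when an
#' interspike interval exceeds 30 ms. The first spike of a recording counts
#' as following infinite silence.
#'
#' @param spike_times ascending spike times in seconds.
#' @param criteria `"lgn"` or `"pgn"`.
#' @return list of `burst_event` objects, each with `spike_times`,
#'   `cardinal_time` (first spike), `isis` (ms) and `criteria`.
#' @export
detect_bursts <- function(spike_times, criteria = c("lgn", "pgn")) {
  criteria <- match.arg(criteria)
  if (is.unsorted(spike_times, strictly = TRUE))
    stop("'spike_times' must be strictly ascending")
  n <- length(spike_times)
  if (n < 2L) return(list())
  par <- switch(criteria,
    lgn = list(silence = 0.100, max_isi = 0.004, min_spikes = 2L, window = NULL),
    pgn = list(silence = 0.070, max_isi = 0.030, min_spikes = 5L, window = 0.070))
  isi <- diff(spike_times)
  bursts <- list()
  i <- 1L
  while (i <= n) {
    sil <- if (i == 1L) Inf else spike_times[i] - spike_times[i - 1L]
    if (sil >= par$silence && i < n && isi[i] <= par$max_isi) {
      j <- i
      while (j < n && isi[j] <= par$max_isi) j <- j + 1L
      run <- spike_times[i:j]
      ok <- if (is.null(par$window)) {
        length(run) >= par$min_spikes
      } else {
        sum(run - run[1L] <= par$window) >= par$min_spikes
      }
      if (ok) {
        bursts[[length(bursts) + 1L]] <- structure(
          list(spike_times = run, cardinal_time = run[1L],
               isis = 1000 * diff(run), criteria = criteria),
          class = "burst_event")
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  bursts
}

#' @export
print.burst_event <- function(x, ...) {
  cat(sprintf("<burst_event:%s> %d spikes at %.3f s, %.1f ms long\n",
              x$criteria, length(x$spike_times), x$cardinal_time,
              1000 * diff(range(x$spike_times))))
  invisible(x)
}

#' Tabulate detected bursts
#' @param bursts list of `burst_event`s.
#' @param cell_id optional identifier column.
#' @return data frame with `cell_id`, `t_cardinal_s`, `n_spikes`,
#'   `duration_ms`, `criteria`.
#' @export
burst_table <- function(bursts, cell_id = NA_character_) {
  if (!length(bursts))
    return(data.frame(cell_id = character(0), t_cardinal_s = numeric(0),
                      n_spikes = integer(0), duration_ms = numeric(0),
                      criteria = character(0)))
  data.frame(
    cell_id = cell_id,
    t_cardinal_s = vapply(bursts, function(b) b$cardinal_time, 0),
    n_spikes = vapply(bursts, function(b) length(b$spike_times), 0L),
    duration_ms = vapply(bursts, function(b) 1000 * diff(range(b$spike_times)), 0),
    criteria = vapply(bursts, function(b) b$criteria, ""))
}

#' Resample a burst's ISI sequence to a fixed 21-point curve
#'
#' Bursts of different spike counts are made comparable by upsampling their
#' ISI sequence to 21 points on a uniform normalized index with
#' shape-preserving (monotonicity-preserving piecewise-cubic, PCHIP)
#' interpolation, so each burst becomes a point in a 21-dimensional space
#' without overshoot artifacts.
#'
#' @param burst a `burst_event` (or a numeric vector of ISIs in ms).
#' @return list of class `isi_curve`: `values` (21 ms values),
#'   `n_source_spikes`, `constant` (TRUE when the burst had a single ISI).
#' @export
isi_curve <- function(burst) {
  isis <- if (inherits(burst, "burst_event")) burst$isis else as.numeric(burst)
  if (!length(isis) || any(isis <= 0)) stop("burst must have positive ISIs")
  n <- length(isis)
  if (n == 1L) {
    return(structure(list(values = rep(isis, 21L), n_source_spikes = 2L,
                          constant = TRUE), class = "isi_curve"))
  }
  xi <- seq_len(n)
  x <- seq(1, n, length.out = 21L)
  vals <- if (n == 2L) stats::approx(xi, isis, x)$y
          else pracma::pchip(xi, isis, x)
  structure(list(values = vals, n_source_spikes = n + 1L, constant = FALSE),
            class = "isi_curve")
}

#' Cluster burst ISI curves with a Gaussian mixture
#'
#' Each burst is a point in the 21-dimensional ISI-curve space; clusters are
#' found with a Gaussian mixture model whose number of components (up to
#' `max_clusters`) is selected by BIC. The U-shaped cluster mean is the
#' signature of PGN reticular bursts; monotone increasing means are typical
#' of LGN relay bursts.
#'
#' @param curves list of `isi_curve`s (or a numeric matrix, one row each).
#' @param max_clusters maximum number of mixture components.
#' @return list of class `burst_clusters`: `assignments`, `cluster_means`
#'   (matrix, one 21-point row per cluster), `n_clusters`, `model_score`
#'   (BIC of the selected model).
#' @importFrom mclust Mclust mclustBIC
#' @export
cluster_bursts <- function(curves, max_clusters = 6L) {
  X <- if (is.matrix(curves)) curves else
    do.call(rbind, lapply(curves, function(cv) cv$values))
  if (nrow(X) < 2L) stop("need at least 2 curves to cluster")
  if (nrow(X) < max_clusters) {
    warning("fewer curves than 'max_clusters'; reducing")
    max_clusters <- nrow(X)
  }
  if (all(apply(X, 2L, function(cc) diff(range(cc)) == 0))) {
    return(structure(list(assignments = rep(1L, nrow(X)),
                          cluster_means = matrix(colMeans(X), nrow = 1L),
                          n_clusters = 1L, model_score = NA_real_),
                     class = "burst_clusters"))
  }
  # Bayesian regularization: curves of k-ISI bursts lie on k-dimensional
  # manifolds of the 21-D space, so unregularized component covariances can
  # be singular and EM fails for G > 1.
  sc <- stats::cov(X)
  sc <- sc + diag(mean(diag(sc)) * 1e-2, ncol(sc))
  fit <- suppressWarnings(
    mclust::Mclust(X, G = seq_len(max_clusters),
                   prior = mclust::priorControl(scale = sc),
                   verbose = FALSE))
  cl <- fit$classification
  k <- fit$G
  means <- t(vapply(seq_len(k), function(g) colMeans(X[cl == g, , drop = FALSE]),
                    numeric(ncol(X))))
  structure(list(assignments = as.integer(cl), cluster_means = means,
                 n_clusters = as.integer(k), model_score = fit$bic),
            class = "burst_clusters")
}

#' @export
print.burst_clusters <- function(x, ...) {
  cat(sprintf("<burst_clusters> %d clusters over %d bursts (BIC %.1f)\n",
              x$n_clusters, length(x$assignments), x$model_score))
  invisible(x)
}

#' Identify U-shaped cluster means
#'
#' A 21-point cluster mean is U-shaped when its central value is smaller
#' than both endpoints (spike rate accelerates then decelerates).
#'
#' @param clusters a `burst_clusters` object.
#' @return logical vector, one entry per cluster.
#' @export
u_shaped_clusters <- function(clusters) {
  apply(clusters$cluster_means, 1L, function(m) {
    ctr <- m[11L]
    ctr < m[1L] && ctr < m[21L]
  })
}

#' Index of the reticular-signature (most U-shaped) cluster
#'
#' Among U-shaped cluster means, the one with the deepest central dip
#' (smallest ratio of the central value to the mean of the endpoints) is
#' the signature of PGN accelerating-decelerating bursts.
#'
#' @param clusters a `burst_clusters` object.
#' @return cluster index, or `NA_integer_` when no mean is U-shaped.
#' @export
pgn_signature_cluster <- function(clusters) {
  u <- u_shaped_clusters(clusters)
  if (!any(u)) return(NA_integer_)
  m <- clusters$cluster_means
  depth <- ifelse(u, m[, 11L] / ((m[, 1L] + m[, 21L]) / 2), Inf)
  which.min(depth)
}

#' Width of the spike-train autocorrelogram at 5% of peak height
#'
#' The autocorrelogram (zero-lag bin excluded) is computed at `bin_ms`
#' resolution to +/- `max_lag_ms`; the width is the full extent of the
#' contiguous region, containing the peak bin, whose counts exceed 5% of
#' the peak. When that region reaches the zero-lag bin it spans both signs
#' of the symmetric correlogram. Long PGN bursts give wide correlograms;
#' brief LGN bursts give narrow ones.
#'
#' @param spike_times ascending seconds.
#' @param bin_ms bin width, ms (default 1).
#' @param max_lag_ms maximum lag, ms (default 100).
#' @param threshold fraction of the peak defining the width (default 0.05).
#' @return width in ms.
#' @export
autocorr_width <- function(spike_times, bin_ms = 1, max_lag_ms = 100,
                           threshold = 0.05) {
  if (length(spike_times) < 2L) stop("need at least 2 spikes")
  lags_ms <- .pair_lags_ms(spike_times, max_lag_ms)
  if (!length(lags_ms)) stop("empty correlogram within 'max_lag_ms'")
  nb <- ceiling(max_lag_ms / bin_ms)
  # positive-lag bins; the correlogram is symmetric
  counts <- tabulate(pmin(floor(lags_ms / bin_ms) + 1L, nb), nbins = nb)
  peak_bin <- which.max(counts)
  above <- counts > threshold * counts[peak_bin]
  l <- peak_bin
  while (l > 1L && above[l - 1L]) l <- l - 1L
  r <- peak_bin
  while (r < nb && above[r + 1L]) r <- r + 1L
  if (l == 1L) 2 * r * bin_ms else (r - l + 1L) * bin_ms
}

# All positive pairwise spike-time differences below max_lag_ms (exclusive
# of exact zero-lag pairs), in ms; two-pointer scan, O(n * pairs-in-window).
.pair_lags_ms <- function(spike_times, max_lag_ms) {
  n <- length(spike_times)
  maxs <- max_lag_ms / 1000
  out <- vector("list", n)
  j <- 1L
  for (i in seq_len(n)) {
    k <- i + 1L
    while (k <= n && spike_times[k] - spike_times[i] < maxs) k <- k + 1L
    if (k > i + 1L)
      out[[i]] <- (spike_times[(i + 1L):(k - 1L)] - spike_times[i]) * 1000
  }
  unlist(out)
}

#' Classify spikes relative to burst structure and the stimulus clock
#'
#' Burst spikes are grouped by the index of the stimulus frame containing
#' them, relative to the frame containing the burst's cardinal (first)
#' spike: the cardinal spike and any other spikes in its frame are Group I
#' (labels `"cardinal"` / `"group_I"`), spikes in the next frame Group II,
#' then Group III, and `"later"` beyond that. Spikes outside bursts are
#' `"tonic"`.
#'
#' @param spike_times ascending seconds.
#' @param bursts list of `burst_event`s from [detect_bursts()].
#' @param frame_duration stimulus frame length in seconds.
#' @return data frame with `time`, `label`, `burst_id` (NA for tonic) and
#'   `frame_offset` (frames since the cardinal spike's frame; NA for tonic).
#' @export
classify_spikes <- function(spike_times, bursts, frame_duration) {
  lab <- rep("tonic", length(spike_times))
  bid <- rep(NA_integer_, length(spike_times))
  off <- rep(NA_integer_, length(spike_times))
  for (b in seq_along(bursts)) {
    bt <- bursts[[b]]$spike_times
    idx <- match(bt, spike_times)
    if (anyNA(idx)) idx <- findInterval(bt, spike_times)
    f0 <- floor(bt[1L] / frame_duration)
    o <- as.integer(floor(bt / frame_duration) - f0)
    l <- ifelse(o == 0L, "group_I",
         ifelse(o == 1L, "group_II",
         ifelse(o == 2L, "group_III", "later")))
    l[1L] <- "cardinal"
    lab[idx] <- l; bid[idx] <- b; off[idx] <- o
  }
  data.frame(time = spike_times, label = lab, burst_id = bid,
             frame_offset = off)
}

#' STAs for burst spike groups at compensatory temporal shifts
#'
#' For each burst, one spike is taken from each group (I, II, III: first,
#' second, third stimulus frame of the burst) and an STA is formed with the
#' triggering window advanced by 0, 1 or 2 frames. If every spike of a
#' burst is initiated by the stimulus preceding the cardinal spike, the
#' Group II STA at Shift 1 and Group III STA at Shift 2 should match the
#' Group I STA at Shift 0.
#'
#' @param stimulus a `stim_movie`.
#' @param classification data frame from [classify_spikes()], or a list of
#'   such data frames (one per repeat of a frozen stimulus; spikes pooled).
#' @param lag_frames number of stimulus frames per STA window.
#' @param shifts integer temporal advances (frames) to evaluate.
#' @return named list of `subunit_filter` arrays, names `"<group>_shift<s>"`
#'   for groups `I`, `II`, `III`.
#' @export
group_shift_stas <- function(stimulus, classification, lag_frames = 6L,
                             shifts = 0:2) {
  if (is.data.frame(classification)) classification <- list(classification)
  fd <- stimulus$frame_duration
  groups <- list(I = c("cardinal"), II = "group_II", III = "group_III")
  out <- list()
  for (g in names(groups)) {
    # one spike per group per burst: first spike of that group in each burst
    tms <- unlist(lapply(classification, function(cl) {
      rows <- cl[cl$label %in% groups[[g]], , drop = FALSE]
      rows$time[!duplicated(rows$burst_id)]
    }))
    for (s in shifts) {
      sh <- tms - s * fd
      ens <- .times_ensemble(stimulus, sh[sh >= 0], lag_frames)
      out[[sprintf("%s_shift%d", g, s)]] <-
        if (nrow(ens$matrix)) compute_sta(ens) else NULL
    }
  }
  out
}

#' Correlation table of group/shift STAs against Group I / Shift 0
#'
#' Normalized dot products (cosine similarity, self-correlation = 1) of
#' each group/shift STA with the Group I Shift-0 STA.
#'
#' @param stas named list as returned by [group_shift_stas()].
#' @param reference name of the reference STA (default `"I_shift0"`).
#' @return data frame with `group`, `shift`, `correlation`.
#' @export
shift_correlation <- function(stas, reference = "I_shift0") {
  ref <- stas[[reference]]
  if (is.null(ref)) stop("reference STA missing")
  rv <- as.numeric(ref)
  res <- lapply(names(stas), function(nm) {
    a <- stas[[nm]]
    if (is.null(a)) return(NULL)
    if (length(a) != length(rv)) stop("STA shape mismatch")
    parts <- strsplit(nm, "_shift")[[1L]]
    data.frame(group = parts[1L], shift = as.integer(parts[2L]),
               correlation = sum(as.numeric(a) * rv) /
                 (sqrt(sum(as.numeric(a)^2)) * sqrt(sum(rv^2))))
  })
  do.call(rbind, res)
}
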