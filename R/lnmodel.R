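#' Filter output: projection of the stimulus on a subunit
#'
#' Per-frame dot product between the trailing stimulus window and the
#' filter, divided by the absolute global maximum over the series, so +1
#' (-1) marks maximal spatiotemporal similarity for stimuli of the same
#' (reverse) sign. Frames before the first complete window are NA.
#'
#' @param stimulus a `stim_movie`.
#' @param filter a `subunit_filter`.
#' @param normalize divide by the absolute global maximum (default TRUE).
#' @return list of class `filter_output`: `values` (length `n_frames`),
#'   `norm_constant`, `kind`.
#' @export
filter_output <- function(stimulus, filter, normalize = TRUE) {
  if (all(filter == 0)) stop("all-zero filter")
  v <- .frame_drive(stimulus, filter)
  L <- dim(filter)[1L]
  if (L > 1L) v[seq_len(L - 1L)] <- NA_real_
  nc <- max(abs(v), na.rm = TRUE)
  if (normalize && nc > 0) v <- v / nc
  structure(list(values = v, norm_constant = nc,
                 kind = attr(filter, "kind")),
            class = "filter_output")
}

#' Peri-stimulus time histogram
#'
#' Per-frame spike counts for each repeat of a frozen stimulus and their
#' across-repeat mean.
#'
#' @param spike_record a `spike_record`.
#' @param n_frames,frame_duration stimulus geometry; defaults taken from
#'   the record.
#' @return list of class `psth`: `rate` (mean spikes per frame bin),
#'   `counts` (repeats x frames matrix), `n_repeats`, `frame_duration`.
#' @export
compute_psth <- function(spike_record, n_frames = spike_record$n_frames,
                         frame_duration = spike_record$frame_duration) {
  R <- length(spike_record$repeats)
  counts <- t(vapply(spike_record$repeats, function(tt)
    tabulate(pmin(floor(tt / frame_duration) + 1L, n_frames),
             nbins = n_frames), numeric(n_frames)))
  structure(list(rate = colMeans(counts), counts = counts,
                 n_repeats = R, frame_duration = frame_duration),
            class = "psth")
}

#' Estimate a 1D response nonlinearity
#'
#' The mean PSTH rate is taken over all frames whose filter output falls in
#' each of `n_bins` equal bins spanning [-1, 1]. Empty bins are flagged
#' (NA rate), never silently interpolated.
#'
#' @param output a `filter_output`.
#' @param psth a `psth`.
#' @param n_bins number of bins (>= 2).
#' @param frames optional frame indices to use (training subset).
#' @return list of class `nonlin1d`: `bin_edges`, `mean_rate`, `occupancy`,
#'   `n_bins`.
#' @export
estimate_nonlinearity_1d <- function(output, psth, n_bins = 10L,
                                     frames = NULL) {
  if (n_bins < 2L) stop("'n_bins' must be >= 2")
  x <- output$values; y <- psth$rate
  if (length(x) != length(y)) stop("output and PSTH length differ")
  if (is.null(frames)) frames <- seq_along(x)
  frames <- frames[!is.na(x[frames])]
  edges <- seq(-1, 1, length.out = n_bins + 1L)
  b <- .bin_index(x[frames], edges)
  mean_rate <- rep(NA_real_, n_bins)
  occ <- tabulate(b, nbins = n_bins)
  agg <- tapply(y[frames], b, mean)
  mean_rate[as.integer(names(agg))] <- agg
  structure(list(bin_edges = edges, mean_rate = mean_rate,
                 occupancy = occ, n_bins = as.integer(n_bins)),
            class = "nonlin1d")
}

#' Estimate a joint 2D response nonlinearity
#'
#' Mean PSTH rate on a grid of bins over the outputs of two subunits, with
#' occupancy recorded; empty cells are NA.
#'
#' @param out_a,out_b `filter_output`s of the two subunits.
#' @param psth a `psth`.
#' @param n_bins bins per axis (scalar or length-2).
#' @param frames optional frame subset.
#' @return list of class `nonlin2d`: `bin_edges_x`, `bin_edges_y`,
#'   `mean_rate` (matrix), `occupancy` (matrix).
#' @export
estimate_nonlinearity_2d <- function(out_a, out_b, psth, n_bins = 10L,
                                     frames = NULL) {
  if (any(n_bins < 2L)) stop("'n_bins' must be >= 2")
  nb <- rep(as.integer(n_bins), length.out = 2L)
  x <- out_a$values; y <- out_b$values; z <- psth$rate
  if (is.null(frames)) frames <- seq_along(x)
  frames <- frames[!is.na(x[frames]) & !is.na(y[frames])]
  ex <- seq(-1, 1, length.out = nb[1L] + 1L)
  ey <- seq(-1, 1, length.out = nb[2L] + 1L)
  bx <- .bin_index(x[frames], ex)
  by <- .bin_index(y[frames], ey)
  cell <- (by - 1L) * nb[1L] + bx
  occ <- matrix(tabulate(cell, nbins = prod(nb)), nb[1L], nb[2L])
  mr <- matrix(NA_real_, nb[1L], nb[2L])
  agg <- tapply(z[frames], cell, mean)
  mr[as.integer(names(agg))] <- agg
  structure(list(bin_edges_x = ex, bin_edges_y = ey,
                 mean_rate = mr, occupancy = occ),
            class = "nonlin2d")
}

.bin_index <- function(x, edges) {
  x <- pmin(pmax(x, edges[1L]), edges[length(edges)])
  findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
}

.predict_nl1 <- function(nl, x) {
  b <- .bin_index(x, nl$bin_edges)
  filled <- which(!is.na(nl$mean_rate))
  if (!length(filled)) stop("nonlinearity has no occupied bin")
  # nearest-occupied-bin fallback for empty bins
  lookup <- vapply(seq_len(nl$n_bins), function(i)
    filled[which.min(abs(filled - i))], 0L)
  out <- nl$mean_rate[lookup[b]]
  out[is.na(x)] <- NA_real_
  out
}

.predict_nl2 <- function(nl, x, y) {
  nbx <- length(nl$bin_edges_x) - 1L
  nby <- length(nl$bin_edges_y) - 1L
  bx <- .bin_index(x, nl$bin_edges_x)
  by <- .bin_index(y, nl$bin_edges_y)
  filled <- which(!is.na(nl$mean_rate), arr.ind = TRUE)
  if (!nrow(filled)) stop("nonlinearity has no occupied cell")
  out <- nl$mean_rate[cbind(bx, by)]
  miss <- which(is.na(out) & !is.na(x) & !is.na(y))
  for (i in miss) {
    d2 <- (filled[, 1L] - bx[i])^2 + (filled[, 2L] - by[i])^2
    k <- which.min(d2)
    out[i] <- nl$mean_rate[filled[k, 1L], filled[k, 2L]]
  }
  out[is.na(x) | is.na(y)] <- NA_real_
  out
}

#' Cross-validated choice of the nonlinearity bin count
#'
#' Fits the nonlinearity on the training frames for an increasing number of
#' bins (starting at `start`, step `step`) and evaluates prediction on the
#' test frames; the search halts when adding bins reduces rather than
#' improves test-set explained variance, returning the last improving
#' count.
#'
#' @param outputs a `filter_output` or list of two (joint nonlinearity).
#' @param psth a `psth`.
#' @param train_frames,test_frames disjoint frame index vectors.
#' @param start,step,max_bins search grid (defaults 4, 2, 30).
#' @return chosen bin count.
#' @export
optimize_bins <- function(outputs, psth, train_frames, test_frames,
                          start = 4L, step = 2L, max_bins = 30L) {
  if (length(intersect(train_frames, test_frames)))
    stop("train and test frames overlap")
  single <- inherits(outputs, "filter_output")
  score <- function(nb) {
    if (single) {
      nl <- estimate_nonlinearity_1d(outputs, psth, nb, train_frames)
      m <- .predict_nl1(nl, outputs$values[test_frames])
    } else {
      nl <- estimate_nonlinearity_2d(outputs[[1L]], outputs[[2L]], psth, nb,
                                     train_frames)
      m <- .predict_nl2(nl, outputs[[1L]]$values[test_frames],
                        outputs[[2L]]$values[test_frames])
    }
    d <- psth$rate[test_frames]
    ok <- !is.na(m)
    1 - sum((d[ok] - m[ok])^2) / sum((d[ok] - mean(d[ok]))^2)
  }
  best <- start
  best_ev <- score(start)
  nb <- start + step
  while (nb <= max_bins) {
    ev <- score(nb)
    if (ev <= best_ev) break
    best <- nb; best_ev <- ev
    nb <- nb + step
  }
  best
}

#' Fit a linear-nonlinear (LN) cascade model
#'
#' The central model fit of the package. The recording is split into a
#' training half and a test half (contiguous, with a guard gap of one lag
#' window to avoid leakage across the stimulus window). Filters (STA and,
#' for 2D models, an STC subunit) are estimated from spikes in the training
#' half; the filter outputs are binned and the response nonlinearity is the
#' mean training PSTH rate per bin, with the bin count chosen by
#' cross-validation; prediction on the held-out half is scored with
#' bias-corrected explained variance.
#'
#' @param stimulus a `stim_movie` (frozen noise sequence).
#' @param spike_record a `spike_record` with one or more repeats.
#' @param dims 1 (STA only) or 2 (STA + one STC subunit).
#' @param stc_rank which STC eigenvector to pair with the STA (default 1).
#' @param filters optional list of pre-estimated `subunit_filter`s (length
#'   `dims`), bypassing filter estimation.
#' @param lag_frames stimulus window length in frames.
#' @param n_bins nonlinearity bin count; chosen by [optimize_bins()] when
#'   NULL.
#' @param spike_policy spike selection for filter estimation (see
#'   [build_ensemble()]); `"all"` when the record carries no labels.
#' @param classification optional [classify_spikes()] output for the policy.
#'
#' @return an object of class `ln_model` with components `filters`,
#'   `nonlinearity`, `outputs`, `n_bins`, `n_free_params` (occupied bins),
#'   `prediction` (rate per frame, spikes/frame), `train_frames`,
#'   `test_frames`, `psth` and `evaluation` (test-set
#'   [explained_variance_corrected()] and
#'   [explained_variance_signal_power()]).
#' @seealso [predict.ln_model()], [summary.ln_model()]
#' @export
ln_model <- function(stimulus, spike_record, dims = 1L, stc_rank = 1L,
                     filters = NULL, lag_frames = 6L, n_bins = NULL,
                     spike_policy = "all", classification = NULL) {
  stopifnot(dims %in% c(1L, 2L))
  nf <- dim(stimulus$frames)[1L]
  half <- floor(nf / 2)
  train_frames <- seq.int(lag_frames, half)
  test_frames <- seq.int(half + lag_frames + 1L, nf)
  psth <- compute_psth(spike_record, nf, stimulus$frame_duration)

  if (is.null(filters)) {
    ens <- build_ensemble(stimulus, spike_record, lag_frames,
                          spike_policy = spike_policy,
                          classification = classification)
    keep <- ens$frames <= half
    ens$matrix <- ens$matrix[keep, , drop = FALSE]
    ens$frames <- ens$frames[keep]
    sta <- compute_sta(ens)
    filters <- list(sta)
    if (dims == 2L) {
      stc <- compute_stc(ens, sta)
      filters[[2L]] <- stc_filter(stc, stc_rank)
    }
  }
  outputs <- lapply(filters, function(f) filter_output(stimulus, f))

  if (is.null(n_bins)) {
    n_bins <- optimize_bins(if (dims == 1L) outputs[[1L]] else outputs,
                            psth, train_frames, test_frames)
  }
  if (dims == 1L) {
    nl <- estimate_nonlinearity_1d(outputs[[1L]], psth, n_bins, train_frames)
    pred <- .predict_nl1(nl, outputs[[1L]]$values)
    n_free <- sum(!is.na(nl$mean_rate))
  } else {
    # cap per-axis bins so expected training occupancy stays >= 10 frames
    cap <- max(2L, floor(sqrt(length(train_frames) / 10)))
    nb2 <- min(n_bins, cap)
    nl <- estimate_nonlinearity_2d(outputs[[1L]], outputs[[2L]], psth, nb2,
                                   train_frames)
    pred <- .predict_nl2(nl, outputs[[1L]]$values, outputs[[2L]]$values)
    n_free <- sum(!is.na(nl$mean_rate))
  }
  ev <- explained_variance_corrected(psth, pred, n_free, test_frames)
  ev_sp <- tryCatch(
    explained_variance_signal_power(psth, pred, test_frames),
    error = function(e) NA_real_)
  structure(list(filters = filters, nonlinearity = nl, outputs = outputs,
                 dims = dims, n_bins = n_bins, n_free_params = n_free,
                 prediction = pred, train_frames = train_frames,
                 test_frames = test_frames, psth = psth,
                 lag_frames = as.integer(lag_frames),
                 evaluation = list(corrected = ev, signal_power = ev_sp)),
            class = "ln_model")
}

#' @export
print.ln_model <- function(x, ...) {
  cat(sprintf("<ln_model> %dD LN model, %d bins (%d occupied)\n",
              x$dims, x$n_bins, x$n_free_params))
  cat(sprintf("  test-set explained variance (bias-corrected): %.3f\n",
              x$evaluation$corrected$gamma_corrected))
  invisible(x)
}

#' @export
summary.ln_model <- function(object, ...) {
  ev <- object$evaluation
  out <- list(dims = object$dims, n_bins = object$n_bins,
              n_free_params = object$n_free_params,
              gamma_corrected = ev$corrected$gamma_corrected,
              gamma_naive = ev$corrected$gamma_naive,
              gamma_signal_power = ev$signal_power,
              n_test_frames = length(object$test_frames),
              n_repeats = object$psth$n_repeats)
  class(out) <- "summary.ln_model"
  out
}

#' @export
print.summary.ln_model <- function(x, ...) {
  cat(sprintf("%dD LN model: %d bins, %d free parameters\n",
              x$dims, x$n_bins, x$n_free_params))
  cat(sprintf("  explained variance, bias-corrected: %.3f\n", x$gamma_corrected))
  cat(sprintf("  explained variance, naive ratio:    %.3f\n", x$gamma_naive))
  cat(sprintf("  explained variance, signal power:   %.3f\n", x$gamma_signal_power))
  cat(sprintf("  test frames: %d, repeats: %d\n", x$n_test_frames, x$n_repeats))
  invisible(x)
}

#' @export
coef.ln_model <- function(object, ...) object$filters

#' Predict the firing rate from a fitted LN model
#'
#' Filters the stimulus, passes the outputs through the estimated
#' nonlinearity (nearest-occupied-bin fallback for empty bins) and returns
#' the predicted rate in spikes per frame bin.
#'
#' @param object an `ln_model`.
#' @param stimulus optional new `stim_movie`; the training stimulus
#'   prediction is returned when omitted.
#' @param ... unused.
#' @return numeric rate series (NA for frames without a complete window).
#' @export
predict.ln_model <- function(object, stimulus = NULL, ...) {
  if (is.null(stimulus)) return(object$prediction)
  outs <- lapply(seq_along(object$filters), function(i) {
    f <- object$filters[[i]]
    v <- .frame_drive(stimulus, f)
    L <- dim(f)[1L]
    if (L > 1L) v[seq_len(L - 1L)] <- NA_real_
    v / object$outputs[[i]]$norm_constant
  })
  if (object$dims == 1L) .predict_nl1(object$nonlinearity, outs[[1L]])
  else .predict_nl2(object$nonlinearity, outs[[1L]], outs[[2L]])
}

#' @export
residuals.ln_model <- function(object, ...) {
  r <- object$psth$rate - object$prediction
  r[setdiff(seq_along(r), object$test_frames)] <- NA_real_
  r
}

#' @export
fitted.ln_model <- function(object, ...) object$prediction

#' @export
plot.ln_model <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, x$dims + 1L))
  on.exit(graphics::par(op))
  plot(x$filters[[1L]])
  if (x$dims == 1L) {
    ctr <- (x$nonlinearity$bin_edges[-1L] +
              utils::head(x$nonlinearity$bin_edges, -1L)) / 2
    graphics::plot(ctr, x$nonlinearity$mean_rate, type = "b",
                   xlab = "filter output", ylab = "rate (spikes/frame)",
                   main = "response nonlinearity", ...)
  } else {
    plot(x$filters[[2L]])
    graphics::image(x$nonlinearity$mean_rate,
                    col = grDevices::gray.colors(64),
                    main = "joint nonlinearity", axes = FALSE)
  }
  invisible(x)
}
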