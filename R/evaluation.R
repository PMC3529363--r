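#' Bias-corrected explained variance
#'
#' Fraction of the stimulus-driven response variance a model prediction
#' accounts for, corrected for the two finite-data confounds of
#' trial-averaged responses: the uncertainty of the across-repeat mean
#' (through the noise variance of the PSTH) and the number of free
#' parameters of the model. With residual and total sums of squares
#' RSS = sum_i (dbar_i - m_i)^2 and TSS = sum_i (dbar_i - mean(dbar))^2,
#' noise variance of the mean
#' s2 = 1/(R N (R-1)) sum_ij (d_ij - dbar_i)^2 and Ns = N (R - 1),
#' the corrected estimator is
#' \deqn{\gamma = 1 - \frac{RSS/s^2 - (N-n)\,N_s/(N_s-2)}
#'                         {TSS/s^2 - (N-1)\,N_s/(N_s-2)}.}
#' In the noise-free limit (s2 = 0) or with a single repeat the naive
#' ratio 1 - RSS/TSS is returned, flagged.
#'
#' @param psth a `psth` (with per-repeat `counts`), or a repeats x frames
#'   count matrix.
#' @param prediction model rate per frame, same units as the PSTH
#'   (spikes/frame).
#' @param n_free_params number of free model parameters (occupied
#'   nonlinearity bins).
#' @param frames optional frame subset (e.g. the test half); frames with NA
#'   prediction are dropped.
#' @return list of class `variance_explained`: `gamma_corrected`,
#'   `gamma_naive`, `sigma2`, `N`, `R`, `n`, `N_sigma`, `corrected`
#'   (FALSE when the naive fallback was used).
#' @export
explained_variance_corrected <- function(psth, prediction, n_free_params = 0L,
                                         frames = NULL) {
  counts <- if (inherits(psth, "psth")) psth$counts else as.matrix(psth)
  if (is.null(frames)) frames <- seq_len(ncol(counts))
  frames <- frames[!is.na(prediction[frames])]
  d <- counts[, frames, drop = FALSE]
  m <- prediction[frames]
  dbar <- colMeans(d)
  N <- length(frames); R <- nrow(d); n <- n_free_params
  TSS <- sum((dbar - mean(dbar))^2)
  if (TSS == 0) stop("response variance is zero; explained variance undefined")
  RSS <- sum((dbar - m)^2)
  naive <- 1 - RSS / TSS
  if (R < 2L) {
    return(structure(list(gamma_corrected = naive, gamma_naive = naive,
                          sigma2 = NA_real_, N = N, R = R, n = n,
                          N_sigma = NA_real_, corrected = FALSE),
                     class = "variance_explained"))
  }
  sigma2 <- sum(sweep(d, 2L, dbar)^2) / (R * N * (R - 1))
  Ns <- N * (R - 1)
  if (sigma2 == 0) {
    return(structure(list(gamma_corrected = naive, gamma_naive = naive,
                          sigma2 = 0, N = N, R = R, n = n, N_sigma = Ns,
                          corrected = FALSE),
                     class = "variance_explained"))
  }
  corr <- Ns / (Ns - 2)
  gamma <- 1 - (RSS / sigma2 - (N - n) * corr) /
               (TSS / sigma2 - (N - 1) * corr)
  structure(list(gamma_corrected = gamma, gamma_naive = naive,
                 sigma2 = sigma2, N = N, R = R, n = n, N_sigma = Ns,
                 corrected = TRUE),
            class = "variance_explained")
}

#' @export
print.variance_explained <- function(x, ...) {
  cat(sprintf("explained variance: %.3f (bias-corrected%s), naive %.3f; N=%d R=%d n=%d\n",
              x$gamma_corrected, if (x$corrected) "" else " fallback",
              x$gamma_naive, x$N, x$R, x$n))
  invisible(x)
}

#' Explained variance by the signal-power method
#'
#' Extrapolates the stimulus-locked ("signal") power of the response from
#' the across-repeat structure: with per-repeat power P(x) = Var_t(x),
#' signal power is (R P(dbar) - mean_j P(d_j)) / (R - 1). The same
#' extrapolation applied to the per-repeat residuals d_j - m gives the
#' unexplained signal power, and the explained fraction is one minus their
#' ratio. No free-parameter correction is applied.
#'
#' @inheritParams explained_variance_corrected
#' @return explained fraction (scalar).
#' @export
explained_variance_signal_power <- function(psth, prediction, frames = NULL) {
  counts <- if (inherits(psth, "psth")) psth$counts else as.matrix(psth)
  if (is.null(frames)) frames <- seq_len(ncol(counts))
  frames <- frames[!is.na(prediction[frames])]
  d <- counts[, frames, drop = FALSE]
  m <- prediction[frames]
  R <- nrow(d)
  if (R < 2L) stop("signal-power estimate requires >= 2 repeats")
  pw <- function(x) mean((x - mean(x))^2)
  sig <- (R * pw(colMeans(d)) - mean(apply(d, 1L, pw))) / (R - 1)
  if (sig <= 0) stop("non-positive signal-power estimate")
  e <- sweep(d, 2L, m)
  res <- (R * pw(colMeans(e)) - mean(apply(e, 1L, pw))) / (R - 1)
  1 - res / sig
}

# KL divergence (bits) between the spike-conditional and prior
# distributions of a filter output, binned at bin_sigma * sd(prior).
# Prior-empty bins inside the support are merged with their neighbours.
.kl_filter_output <- function(x, w, bin_sigma) {
  s <- stats::sd(x)
  if (s == 0) return(0)
  bw <- bin_sigma * s
  edges <- seq(min(x) - bw / 2, max(x) + bw, by = bw)
  b <- findInterval(x, edges, all.inside = TRUE)
  nb <- length(edges) - 1L
  prior <- tabulate(b, nbins = nb)
  spike <- vapply(seq_len(nb), function(i) sum(w[b == i]), 0)
  grp <- cumsum(prior > 0)          # merge leading/empty bins forward
  grp[grp == 0L] <- 1L
  pp <- tapply(prior, grp, sum); ps <- tapply(spike, grp, sum)
  pp <- pp / sum(pp); ps <- ps / sum(ps)
  ok <- ps > 0
  sum(ps[ok] * log2(ps[ok] / pp[ok]))
}

.kl_filter_output_2d <- function(x, y, w, bin_sigma) {
  if (stats::sd(x) == 0) return(.kl_filter_output(y, w, bin_sigma))
  if (stats::sd(y) == 0) return(.kl_filter_output(x, w, bin_sigma))
  bx <- bin_sigma * stats::sd(x); by <- bin_sigma * stats::sd(y)
  ex <- seq(min(x) - bx / 2, max(x) + bx, by = bx)
  ey <- seq(min(y) - by / 2, max(y) + by, by = by)
  ix <- findInterval(x, ex, all.inside = TRUE)
  iy <- findInterval(y, ey, all.inside = TRUE)
  cell <- (iy - 1L) * (length(ex) - 1L) + ix
  nb <- (length(ex) - 1L) * (length(ey) - 1L)
  prior <- tabulate(cell, nbins = nb)
  spike <- vapply(seq_len(nb), function(i) sum(w[cell == i]), 0)
  pp <- prior / sum(prior); ps <- spike / sum(spike)
  ok <- ps > 0                       # spike support is a subset of the prior
  sum(ps[ok] * log2(ps[ok] / pp[ok]))
}

#' Mutual information carried by one subunit (bits/spike)
#'
#' Kullback-Leibler divergence between the distribution of the subunit's
#' filter output over the whole stimulus (prior) and its distribution in
#' the frames preceding spikes (spike-conditional), D(spike || prior).
#' The divergence is evaluated on a grid of bin sizes expressed as
#' multiples of the prior's standard deviation; finite-sampling bias is
#' estimated as the same quantity for the most non-significant subunit's
#' output and subtracted. The reported value is the mean over the stable
#' bin-size range (0.15-0.4 sigma); the statistical error is the standard
#' deviation over that range. Bias-corrected values may be slightly
#' negative and are reported as-is.
#'
#' @param output a `filter_output` (or numeric vector of outputs).
#' @param spike_counts spikes per frame (e.g. `colSums(psth$counts)`), or a
#'   vector of spike frame indices via `frames = TRUE` semantics (integer
#'   vector of frame indices also accepted: detected by name).
#' @param nonsig_output output of the most non-significant subunit (same
#'   form), used as the bias reference; NULL skips bias subtraction.
#' @param bin_grid bin sizes in units of the prior SD (default
#'   `seq(0.025, 1, by = 0.025)`).
#' @param stable_range bin-size window averaged for the final estimate.
#' @return list of class `info_result`: `value`, `error`, `grid`,
#'   `raw`, `bias`, `corrected` (per bin size).
#' @export
mutual_info_1d <- function(output, spike_counts, nonsig_output = NULL,
                           bin_grid = seq(0.025, 1, by = 0.025),
                           stable_range = c(0.15, 0.4)) {
  x <- if (inherits(output, "filter_output")) output$values else output
  ok <- !is.na(x)
  x <- x[ok]; w <- spike_counts[ok]
  if (sum(w) < 1) stop("no spikes")
  raw <- vapply(bin_grid, function(bs) .kl_filter_output(x, w, bs), 0)
  bias <- if (is.null(nonsig_output)) rep(0, length(bin_grid)) else {
    xn <- if (inherits(nonsig_output, "filter_output"))
      nonsig_output$values else nonsig_output
    xn <- xn[ok]
    vapply(bin_grid, function(bs) .kl_filter_output(xn, w, bs), 0)
  }
  corrected <- raw - bias
  st <- bin_grid >= stable_range[1L] & bin_grid <= stable_range[2L]
  structure(list(value = mean(corrected[st]), error = stats::sd(corrected[st]),
                 grid = bin_grid, raw = raw, bias = bias,
                 corrected = corrected),
            class = "info_result")
}

#' Joint mutual information of two subunits (bits/spike)
#'
#' Two-dimensional Kullback-Leibler divergence between the joint prior and
#' spike-conditional distributions of two filter outputs. The 2D
#' finite-sampling bias is estimated as the difference between the joint
#' information of the first output with the most non-significant subunit
#' and the 1D information of the first output alone, and subtracted.
#'
#' @param out_a,out_b the two `filter_output`s (STA and STC subunit).
#' @inheritParams mutual_info_1d
#' @return an `info_result` (see [mutual_info_1d()]).
#' @export
mutual_info_2d <- function(out_a, out_b, spike_counts, nonsig_output = NULL,
                           bin_grid = seq(0.025, 1, by = 0.025),
                           stable_range = c(0.15, 0.4)) {
  xa <- if (inherits(out_a, "filter_output")) out_a$values else out_a
  xb <- if (inherits(out_b, "filter_output")) out_b$values else out_b
  ok <- !is.na(xa) & !is.na(xb)
  xa <- xa[ok]; xb <- xb[ok]; w <- spike_counts[ok]
  if (sum(w) < 1) stop("no spikes")
  raw <- vapply(bin_grid, function(bs) .kl_filter_output_2d(xa, xb, w, bs), 0)
  bias <- if (is.null(nonsig_output)) rep(0, length(bin_grid)) else {
    xn <- if (inherits(nonsig_output, "filter_output"))
      nonsig_output$values else nonsig_output
    xn <- xn[ok]
    vapply(bin_grid, function(bs)
      .kl_filter_output_2d(xa, xn, w, bs) - .kl_filter_output(xa, w, bs), 0)
  }
  corrected <- raw - bias
  st <- bin_grid >= stable_range[1L] & bin_grid <= stable_range[2L]
  structure(list(value = mean(corrected[st]), error = stats::sd(corrected[st]),
                 grid = bin_grid, raw = raw, bias = bias,
                 corrected = corrected),
            class = "info_result")
}

#' @export
print.info_result <- function(x, ...) {
  cat(sprintf("mutual information: %.3f +/- %.3f bits/spike\n",
              x$value, x$error))
  invisible(x)
}

#' Synergy index of a subunit pair
#'
#' Joint information minus the sum of the single-subunit informations.
#' Positive values indicate synergy, zero independent contributions,
#' negative redundancy.
#'
#' @param i_joint,i_sta,i_stc bias-corrected informations in bits/spike
#'   (`info_result`s or scalars).
#' @return list of class `synergy_index` with `value` (bits/spike).
#' @export
synergy <- function(i_joint, i_sta, i_stc) {
  val <- function(x) if (inherits(x, "info_result")) x$value else x
  structure(list(value = val(i_joint) - (val(i_sta) + val(i_stc))),
            class = "synergy_index")
}

#' @export
print.synergy_index <- function(x, ...) {
  cat(sprintf("synergy: %+.3f bits/spike (%s)\n", x$value,
              if (x$value > 0) "synergistic" else if (x$value < 0)
                "redundant" else "independent"))
  invisible(x)
}
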