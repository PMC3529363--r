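#' Peak dominance ratio of a subunit's spatial map
#'
#' Ratio between the absolute maxima of the opposite-sign (On vs Off)
#' subregions of a spatial map, with the stronger peak in the numerator,
#' so the ratio is always >= 1. Maps with ratio > 2 are classified
#' single-peaked, <= 2 double-peaked. For STC subunits the absolute sign
#' is arbitrary, so the dominant sign is reported as indeterminate.
#'
#' @param map spatial map: a rows x cols matrix, or a `subunit_filter`
#'   (its peak-amplitude lag is used).
#' @param sign_meaningful FALSE for STC maps whose overall sign is
#'   arbitrary.
#' @return list of class `peak_dominance`: `ratio`, `classification`
#'   (`"single_peaked"`/`"double_peaked"`), `dominant_sign`
#'   (`"on"`/`"off"`/`"indeterminate"`), `one_signed` flag (TRUE when the
#'   map lacks one sign entirely and the ratio is against noise level).
#' @export
peak_dominance <- function(map, sign_meaningful = TRUE) {
  if (inherits(map, "subunit_filter") || length(dim(map)) == 3L)
    map <- spatial_map(map)
  if (all(map == 0)) stop("all-zero map; peak dominance undefined")
  pos <- max(c(map[map > 0], 0))
  neg <- max(c(-map[map < 0], 0))
  one_signed <- pos == 0 || neg == 0
  ratio <- if (one_signed) Inf else max(pos, neg) / min(pos, neg)
  structure(list(
    ratio = ratio,
    classification = if (ratio > 2) "single_peaked" else "double_peaked",
    dominant_sign = if (!sign_meaningful || pos == neg) "indeterminate"
                    else if (pos > neg) "on" else "off",
    one_signed = one_signed),
    class = "peak_dominance")
}

#' @export
print.peak_dominance <- function(x, ...) {
  cat(sprintf("peak dominance ratio %.2f (%s, %s)\n",
              x$ratio, x$classification, x$dominant_sign))
  invisible(x)
}

.as_spatial <- function(x) {
  if (inherits(x, "subunit_filter") || length(dim(x)) == 3L)
    spatial_map(x) else as.matrix(x)
}

#' Reconstruct a dense-noise STA from sparse-noise ON/OFF maps
#'
#' Fits the additive model `target = a * STA_ON + b * STA_OFF` (separate
#' coefficients for the bright and dark maps) by minimizing the sum of
#' squared differences with derivative-free simplex descent. Maps are
#' compared as single-lag spatial maps at peak amplitude.
#'
#' @param sta_on,sta_off sparse-noise maps (matrices or `subunit_filter`s).
#' @param target the dense-noise subunit to reconstruct.
#' @return list of class `subunit_recon`: `coefficients` (`a`, `b`),
#'   `model_map`, `residual` (`target - model`), `snr`
#'   (see [snr_map()]).
#' @export
reconstruct_sta <- function(sta_on, sta_off, target) {
  on <- .as_spatial(sta_on); off <- .as_spatial(sta_off)
  tg <- .as_spatial(target)
  if (!all(dim(on) == dim(tg)) || !all(dim(off) == dim(tg)))
    stop("maps must share one shape")
  if (all(on == 0) && all(off == 0)) stop("both ON and OFF maps are zero")
  sse <- function(p) sum((tg - p[1L] * on - p[2L] * off)^2)
  fit <- stats::optim(c(0, 0), sse, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  model <- fit$par[1L] * on + fit$par[2L] * off
  structure(list(coefficients = c(a = fit$par[1L], b = fit$par[2L]),
                 model_map = model, residual = tg - model,
                 snr = snr_map(tg, model)),
            class = "subunit_recon")
}

#' Reconstruct a dense-noise STC subunit from ON/OFF maps
#'
#' Fits the multiplicative model `target = c * STA_ON * STA_OFF`
#' (pixel-wise product). When the ON and OFF supports are disjoint the
#' product map is identically zero and the reconstruction fails
#' informatively (`c` NA, snr at floor).
#'
#' @inheritParams reconstruct_sta
#' @return a `subunit_recon` with coefficient `c`.
#' @export
reconstruct_stc <- function(sta_on, sta_off, target) {
  on <- .as_spatial(sta_on); off <- .as_spatial(sta_off)
  tg <- .as_spatial(target)
  prod_map <- on * off
  if (all(prod_map == 0)) {
    warning("ON and OFF supports are disjoint; product model undefined")
    return(structure(list(coefficients = c(c = NA_real_),
                          model_map = prod_map * 0, residual = tg,
                          snr = 0),
                     class = "subunit_recon"))
  }
  sse <- function(p) sum((tg - p * prod_map)^2)
  # simplex descent started at the closed-form least-squares solution
  # (the model is linear in c, so that start is also the optimum)
  c0 <- sum(tg * prod_map) / sum(prod_map^2)
  fit <- suppressWarnings(
    stats::optim(c0, sse, method = "Nelder-Mead",
                 control = list(reltol = 1e-14, maxit = 2000)))
  model <- fit$par * prod_map
  structure(list(coefficients = c(c = fit$par),
                 model_map = model, residual = tg - model,
                 snr = snr_map(tg, model)),
            class = "subunit_recon")
}

#' @export
print.subunit_recon <- function(x, ...) {
  cat(sprintf("<subunit_recon> coefficients: %s; snr %.2f\n",
              paste(sprintf("%s=%.3g", names(x$coefficients),
                            x$coefficients), collapse = ", "),
              x$snr))
  invisible(x)
}

#' Signal-to-noise ratio of a subunit reconstruction
#'
#' log10 of the ratio of power in the real map over the residual power,
#' `log10(sum(real^2) / sum((real - model)^2))`. A model explaining
#' nothing (model = 0) scores exactly 0; a perfect reconstruction is
#' capped at `cap`.
#'
#' @param real,model matrices of one shape.
#' @param base logarithm base (default 10).
#' @param cap value reported for a zero residual (default 12).
#' @return scalar SNR.
#' @export
snr_map <- function(real, model, base = 10, cap = 12) {
  real <- .as_spatial(real); model <- .as_spatial(model)
  if (!all(dim(real) == dim(model))) stop("shape mismatch")
  resid <- sum((real - model)^2)
  if (resid == 0) return(cap)
  min(log(sum(real^2) / resid, base = base), cap)
}
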