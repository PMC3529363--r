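#' Spatiotemporal subunit filter
#'
#' Wraps a `lags x rows x cols` weight array as a receptive-field subunit.
#' Lag 1 is the stimulus frame coincident with the spike; increasing lags
#' reach further back in time. STA filters are in stimulus contrast units;
#' STC filters are unit-norm eigenvectors.
#'
#' @param weights numeric array `lags x rows x cols`.
#' @param kind one of `"STA"`, `"STC_k"`, `"STA_ON"`, `"STA_OFF"`, `"model"`.
#' @param eigenvalue,significant,rank optional STC metadata.
#' @return the array with class `subunit_filter` and metadata attributes.
#' @export
subunit_filter <- function(weights, kind = "model", eigenvalue = NULL,
                           significant = NULL, rank = NULL) {
  stopifnot(is.numeric(weights), length(dim(weights)) == 3L,
            all(is.finite(weights)))
  structure(weights, class = "subunit_filter", kind = kind,
            eigenvalue = eigenvalue, significant = significant,
            rank = rank)
}

#' @export
print.subunit_filter <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<subunit_filter:%s> %d lags x %dx%d pixels, norm %.3g",
              attr(x, "kind"), d[1L], d[2L], d[3L], sqrt(sum(x^2))))
  if (!is.null(attr(x, "eigenvalue")))
    cat(sprintf(", eigenvalue %.4g%s", attr(x, "eigenvalue"),
                if (isTRUE(attr(x, "significant"))) " (significant)" else ""))
  cat("\n")
  invisible(x)
}

#' Cosine similarity between two filters (or numeric arrays)
#' @param a,b numeric arrays of equal length.
#' @return scalar in [-1, 1].
#' @export
cosine_similarity <- function(a, b) {
  av <- as.numeric(a); bv <- as.numeric(b)
  if (length(av) != length(bv)) stop("shape mismatch")
  sum(av * bv) / (sqrt(sum(av^2)) * sqrt(sum(bv^2)))
}

#' Lag of peak amplitude of a filter
#' @param filter a `subunit_filter` (or lags x rows x cols array).
#' @return integer lag index maximizing the spatial sum of squares.
#' @export
peak_lag <- function(filter) {
  L <- dim(filter)[1L]
  which.max(vapply(seq_len(L), function(l) sum(filter[l, , ]^2), 0))
}

#' Spatial map of a filter at one lag
#' @param filter a `subunit_filter`.
#' @param lag lag index; defaults to the peak-amplitude lag.
#' @return rows x cols matrix.
#' @export
spatial_map <- function(filter, lag = NULL) {
  if (is.null(lag)) lag <- peak_lag(filter)
  m <- filter[lag, , ]
  dim(m) <- dim(filter)[2:3]
  m
}

#' @export
plot.subunit_filter <- function(x, lag = NULL, ...) {
  m <- spatial_map(x, lag)
  lim <- max(abs(m))
  graphics::image(t(m[nrow(m):1, , drop = FALSE]), zlim = c(-lim, lim),
                  col = grDevices::hcl.colors(64, "Blue-Red 3"),
                  axes = FALSE, main = attr(x, "kind"), ...)
  invisible(x)
}
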