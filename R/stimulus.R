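#' Spatiotemporal Gaussian white-noise stimulus
#'
#' Generates a checkerboard movie in which the contrast of every square in
#' every frame is drawn independently from a zero-mean Gaussian distribution.
#' Luminance is expressed in contrast units (fraction of the mean luminance),
#' so the standard deviation of the pixel distribution equals the RMS
#' contrast of the display.
#'
#' @param grid_shape integer vector of length 2, `c(rows, cols)` of the
#'   stimulus grid.
#' @param n_frames number of stimulus frames (>= 1).
#' @param frame_duration duration of one frame in seconds (default 0.020).
#' @param rms_contrast RMS contrast as a fraction in (0, 1]; default 0.33.
#' @param seed integer seed making the movie reproducible.
#' @param pixel_size_deg size of one grid square in degrees of visual angle.
#'
#' @return A `stim_movie` object: list with `frames` (array
#'   `n_frames x rows x cols`), `frame_duration`, `grid_shape`,
#'   `pixel_size_deg`, `kind = "gaussian"`, `rms_contrast` and `seed`.
#' @seealso [make_sparse_noise()], [simulate_response()]
#' @export
make_gaussian_noise <- function(grid_shape, n_frames,
                                frame_duration = 0.020,
                                rms_contrast = 0.33,
                                seed = 1L,
                                pixel_size_deg = 1) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2L || any(grid_shape < 1L))
    stop("'grid_shape' must be two positive integers")
  if (n_frames < 1L) stop("'n_frames' must be >= 1")
  if (rms_contrast <= 0 || rms_contrast > 1)
    stop("'rms_contrast' must lie in (0, 1]")
  old <- .seed_state(seed)
  on.exit(.restore_seed(old))
  frames <- array(stats::rnorm(n_frames * prod(grid_shape), 0, rms_contrast),
                  dim = c(n_frames, grid_shape[1L], grid_shape[2L]))
  structure(list(frames = frames,
                 frame_duration = frame_duration,
                 grid_shape = grid_shape,
                 pixel_size_deg = pixel_size_deg,
                 kind = "gaussian",
                 rms_contrast = rms_contrast,
                 seed = as.integer(seed)),
            class = "stim_movie")
}

#' Sparse-noise stimulus (individually flashed bright and dark squares)
#'
#' One square is flashed per frame, bright (+contrast) or dark (-contrast),
#' in pseudorandom order so that every (pixel, sign) combination appears
#' exactly `n_visits` times.
#'
#' @inheritParams make_gaussian_noise
#' @param n_visits number of presentations of each (pixel, sign) pair
#'   (default 16).
#' @param frame_duration flash duration in seconds (default 0.029).
#' @param contrast flash contrast in (0, 1] (default 0.5).
#'
#' @return A `stim_movie` with `kind = "sparse"` and
#'   `rows * cols * 2 * n_visits` frames, each containing exactly one
#'   non-zero pixel.
#' @export
make_sparse_noise <- function(grid_shape, n_visits = 16L,
                              frame_duration = 0.029,
                              contrast = 0.5,
                              seed = 1L,
                              pixel_size_deg = 1) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2L || any(grid_shape < 1L))
    stop("'grid_shape' must be two positive integers")
  if (contrast <= 0 || contrast > 1) stop("'contrast' must lie in (0, 1]")
  if (n_visits < 1L) stop("'n_visits' must be >= 1")
  npix <- prod(grid_shape)
  old <- .seed_state(seed)
  on.exit(.restore_seed(old))
  combos <- rep(seq_len(2L * npix), times = n_visits)   # pixel x sign codes
  order <- sample(combos)
  n_frames <- length(order)
  frames <- array(0, dim = c(n_frames, grid_shape[1L], grid_shape[2L]))
  pix <- (order - 1L) %% npix + 1L
  sgn <- ifelse(order > npix, -1, 1)
  idx <- cbind(seq_len(n_frames),
               (pix - 1L) %% grid_shape[1L] + 1L,
               (pix - 1L) %/% grid_shape[1L] + 1L)
  frames[idx] <- sgn * contrast
  structure(list(frames = frames,
                 frame_duration = frame_duration,
                 grid_shape = grid_shape,
                 pixel_size_deg = pixel_size_deg,
                 kind = "sparse",
                 rms_contrast = contrast,
                 seed = as.integer(seed)),
            class = "stim_movie")
}

#' @export
print.stim_movie <- function(x, ...) {
  cat(sprintf("<stim_movie> %s noise: %d frames of %dx%d, %.1f ms/frame, contrast %.2f\n",
              x$kind, dim(x$frames)[1L], x$grid_shape[1L], x$grid_shape[2L],
              1000 * x$frame_duration, x$rms_contrast))
  invisible(x)
}

#' Number of frames in a stimulus movie
#' @param stimulus a `stim_movie`.
#' @return integer frame count.
#' @export
n_frames <- function(stimulus) dim(stimulus$frames)[1L]

# Local RNG scope: run with a given seed, then restore the caller's stream.
.seed_state <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
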