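#' Write a stimulus + spike-record container
#'
#' Serializes one recording to a plain-text directory: the stimulus frames
#' as a CSV matrix (one row per frame, pixels column-major), stimulus
#' metadata as JSON, and one CSV per repeat of spike times (seconds) with
#' labels when present.
#'
#' @param path directory to create.
#' @param stimulus a `stim_movie`.
#' @param record a `spike_record` (optional).
#' @return invisibly, `path`.
#' @export
write_container <- function(path, stimulus, record = NULL) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  nf <- dim(stimulus$frames)[1L]
  utils::write.table(matrix(stimulus$frames, nrow = nf),
                     file.path(path, "stimulus_frames.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  meta <- list(frame_duration = stimulus$frame_duration,
               grid_shape = stimulus$grid_shape,
               pixel_size_deg = stimulus$pixel_size_deg,
               kind = stimulus$kind,
               rms_contrast = stimulus$rms_contrast,
               seed = stimulus$seed)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             file.path(path, "stimulus_meta.json"))
  if (!is.null(record)) {
    for (r in seq_along(record$repeats)) {
      df <- if (!is.null(record$labels))
        record$labels[[r]]
      else data.frame(time = record$repeats[[r]],
                      label = NA_character_, group = NA_integer_)
      utils::write.csv(df, file.path(path, sprintf("spikes_repeat_%d.csv", r)),
                       row.names = FALSE)
    }
  }
  invisible(path)
}

#' Read a container written by [write_container()]
#'
#' @param path container directory.
#' @return list with `stimulus` (a `stim_movie`) and `record` (a
#'   `spike_record`, or NULL when no spikes were stored).
#' @export
read_container <- function(path) {
  meta <- jsonlite::fromJSON(file.path(path, "stimulus_meta.json"))
  fm <- as.matrix(utils::read.table(file.path(path, "stimulus_frames.csv"),
                                    sep = ","))
  gs <- as.integer(meta$grid_shape)
  stim <- structure(list(
    frames = array(fm, dim = c(nrow(fm), gs[1L], gs[2L])),
    frame_duration = meta$frame_duration, grid_shape = gs,
    pixel_size_deg = meta$pixel_size_deg, kind = meta$kind,
    rms_contrast = meta$rms_contrast, seed = as.integer(meta$seed)),
    class = "stim_movie")
  files <- sort(list.files(path, pattern = "^spikes_repeat_\\d+\\.csv$",
                           full.names = TRUE))
  record <- NULL
  if (length(files)) {
    reps <- lapply(files, function(f) utils::read.csv(f))
    record <- structure(list(
      repeats = lapply(reps, function(d) d$time),
      labels = if (all(vapply(reps, function(d) !all(is.na(d$label)), TRUE)))
        reps else NULL,
      n_frames = nrow(fm), frame_duration = meta$frame_duration,
      stimulus_kind = meta$kind), class = "spike_record")
  }
  list(stimulus = stim, record = record)
}
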