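#' Epoched multichannel data
#'
#' An `epochs` object holds a trials x channels x samples array of epoched
#' multichannel signals together with its sampling rate, epoch time origin,
#' per-trial condition labels and channel names. It is the common currency of
#' the preprocessing, decomposition, decoding and inverse stages.
#'
#' @param data Numeric array, trials x channels x samples.
#' @param fs Sampling rate in Hz.
#' @param tmin_ms Time of the first sample relative to stimulus onset, in ms
#'   (negative for pre-stimulus baseline).
#' @param labels Character vector of per-trial condition labels, recycled if
#'   length 1.
#' @param channel_ids Optional character vector of channel names.
#' @param participant_id Optional participant identifier.
#'
#' @return An object of class `epochs`.
#' @export
#' @examples
#' x <- array(rnorm(4 * 2 * 50), c(4, 2, 50))
#' ep <- epochs(x, fs = 200, tmin_ms = -100,
#'              labels = c("famous", "famous", "scrambled", "scrambled"))
#' ep
epochs <- function(data, fs, tmin_ms = -100, labels = "stim",
                   channel_ids = NULL, participant_id = NA_character_) {
  if (length(dim(data)) != 3) {
    stop("`data` must be a 3-d array (trials x channels x samples)",
         call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    stop("`fs` must be a single positive number", call. = FALSE)
  }
  n_trials <- dim(data)[1]
  n_chan <- dim(data)[2]
  labels <- as.character(labels)
  if (length(labels) == 1) labels <- rep(labels, n_trials)
  if (length(labels) != n_trials) {
    stop("`labels` must have one entry per trial", call. = FALSE)
  }
  if (is.null(channel_ids)) channel_ids <- sprintf("MEG%03d", seq_len(n_chan))
  stopifnot(length(channel_ids) == n_chan)
  structure(
    list(data = data, fs = fs, tmin_ms = tmin_ms, labels = labels,
         channel_ids = as.character(channel_ids),
         participant_id = participant_id),
    class = "epochs"
  )
}

#' @export
print.epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epochs> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  cat(sprintf("  time: %g .. %g ms; labels: %s\n", x$tmin_ms,
              max(epoch_times(x)),
              paste(sprintf("%s (%d)", names(table(x$labels)),
                            table(x$labels)), collapse = ", ")))
  invisible(x)
}

#' Epoch time axis
#'
#' @param x An `epochs` object (or anything with `fs`, `tmin_ms` and a sample
#'   dimension).
#' @return Numeric vector of sample times in ms relative to stimulus onset.
#' @export
epoch_times <- function(x) {
  n <- dim(x$data)[length(dim(x$data))]
  x$tmin_ms + (seq_len(n) - 1) * 1000 / x$fs
}

n_trials <- function(x) dim(x$data)[1]
n_channels <- function(x) dim(x$data)[2]
n_samples <- function(x) dim(x$data)[length(dim(x$data))]

#' Subset epochs by condition label
#'
#' @param x An `epochs` object.
#' @param label Condition label(s) to keep.
#' @return An `epochs` object containing only the matching trials.
#' @export
filter_epochs <- function(x, label) {
  keep <- x$labels %in% label
  if (!any(keep)) stop("no trials with label ", paste(label, collapse = "/"),
                       call. = FALSE)
  epochs(x$data[keep, , , drop = FALSE], x$fs, x$tmin_ms, x$labels[keep],
         x$channel_ids, x$participant_id)
}

#' Trial-averaged evoked response
#'
#' @param x An `epochs` object.
#' @param label Optional condition label to average within.
#' @return A channels x samples matrix of the trial mean.
#' @export
evoked <- function(x, label = NULL) {
  if (!is.null(label)) x <- filter_epochs(x, label)
  apply(x$data, c(2, 3), mean)
}

#' Long-format view of epoched data
#'
#' @param x An `epochs` object.
#' @param ... Unused.
#' @return A tibble with columns `trial`, `channel`, `time_ms`, `label`,
#'   `value`.
#' @export
tidy.epochs <- function(x, ...) {
  d <- dim(x$data)
  tibble::tibble(
    trial = rep(seq_len(d[1]), times = d[2] * d[3]),
    channel = rep(rep(x$channel_ids, each = d[1]), times = d[3]),
    time_ms = rep(epoch_times(x), each = d[1] * d[2]),
    label = rep(x$labels, times = d[2] * d[3]),
    value = as.vector(x$data)
  )
}

#' Write epochs to disk
#'
#' Serialises the numeric payload as RDS next to a small JSON sidecar holding
#' the metadata (sampling rate, epoch origin, labels, channels), so the
#' metadata stays greppable without loading the array.
#'
#' @param x An `epochs` object.
#' @param path Output path (`.rds`); the sidecar gets the extension `.json`.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(x, path) {
  stopifnot(inherits(x, "epochs"))
  saveRDS(x, path)
  meta <- list(fs = x$fs, tmin_ms = x$tmin_ms, labels = x$labels,
               channel_ids = x$channel_ids, participant_id = x$participant_id,
               dim = dim(x$data))
  jsonlite::write_json(meta, paste0(sub("\\.rds$", "", path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read epochs written by [write_epochs()]
#'
#' @param path Path to the `.rds` payload.
#' @return An `epochs` object.
#' @export
read_epochs <- function(path) {
  x <- readRDS(path)
  stopifnot(inherits(x, "epochs"))
  x
}
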