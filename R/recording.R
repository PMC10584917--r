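#' Multichannel EEG recording container
#'
#' A recording holds a channels-by-samples signal matrix, its sampling rate,
#' ordered channel labels, and event markers (sample index of each
#' motor-imagery onset plus its condition label). Sample indices are 0-based
#' throughout the package so that an event at time t seconds sits at sample
#' `round(t * rate)`.
#'
#' @param data Numeric matrix, channels x samples.
#' @param rate Sampling rate in Hz.
#' @param labels Character vector of channel names, one per row of `data`.
#' @param events Data frame with columns `sample` (0-based integer index)
#'   and `condition` (character), or NULL for no events.
#' @return An object of class `"eeg_recording"`.
#' @export
recording <- function(data, rate, labels, events = NULL) {
  data <- as.matrix(data)
  labels <- as.character(labels)
  if (nrow(data) != length(labels)) {
    stop("data must have one row per channel label", call. = FALSE)
  }
  if (is.null(events)) {
    events <- data.frame(sample = integer(0), condition = character(0))
  }
  events <- as.data.frame(events)
  if (!all(c("sample", "condition") %in% names(events))) {
    stop("events needs columns 'sample' and 'condition'", call. = FALSE)
  }
  if (nrow(events) && (any(events$sample < 0) ||
                       any(events$sample >= ncol(data)))) {
    stop("event sample indices must lie within the recording", call. = FALSE)
  }
  rownames(data) <- labels
  structure(
    list(data = data, rate = rate, labels = labels, events = events),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> ", length(x$labels), " channels x ", ncol(x$data),
      " samples @ ", x$rate, " Hz, ", nrow(x$events), " events\n", sep = "")
  invisible(x)
}

#' Epoched EEG data
#'
#' Trials x channels x samples array with per-trial condition labels and
#' free-form metadata (subject, group, session, run).
#'
#' @param data Numeric 3-d array, trials x channels x samples.
#' @param rate Sampling rate in Hz.
#' @param labels Channel names (length = dim 2).
#' @param conditions Per-trial condition labels (length = dim 1).
#' @param meta Named list of annotations carried through the pipeline.
#' @return An object of class `"eeg_epochs"`.
#' @export
epoch_set <- function(data, rate, labels, conditions, meta = list()) {
  stopifnot(length(dim(data)) == 3)
  if (dim(data)[2] != length(labels)) {
    stop("second array dimension must match channel labels", call. = FALSE)
  }
  if (dim(data)[1] != length(conditions)) {
    stop("need one condition label per trial", call. = FALSE)
  }
  structure(
    list(data = data, rate = rate, labels = as.character(labels),
         conditions = as.character(conditions), meta = meta),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat("<eeg_epochs> ", dim(x$data)[1], " trials x ", dim(x$data)[2],
      " channels x ", dim(x$data)[3], " samples @ ", x$rate, " Hz\n",
      sep = "")
  invisible(x)
}

#' Read and write recordings as plain-text array containers
#'
#' A recording is serialized as two files sharing a stem: `<stem>.tsv`
#' (samples x channels, header = channel labels) and `<stem>.json` (rate and
#' events). This keeps recordings diff-able and format-independent.
#'
#' @param rec An `"eeg_recording"`.
#' @param stem Path stem (without extension).
#' @return `write_recording` returns the stem invisibly; `read_recording`
#'   returns an `"eeg_recording"`.
#' @export
write_recording <- function(rec, stem) {
  stopifnot(inherits(rec, "eeg_recording"))
  utils::write.table(
    t(rec$data), paste0(stem, ".tsv"),
    sep = "\t", row.names = FALSE, col.names = rec$labels, quote = FALSE
  )
  jsonlite::write_json(
    list(rate = rec$rate, labels = rec$labels, events = rec$events),
    paste0(stem, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(stem)
}

#' @rdname write_recording
#' @param montage Optional `"mst_montage"`; when given, channels are
#'   reordered to montage order and missing channels raise an error naming
#'   them.
#' @export
read_recording <- function(stem, montage = NULL) {
  hdr <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  dat <- utils::read.table(paste0(stem, ".tsv"), header = TRUE, sep = "\t",
                           check.names = FALSE)
  mat <- t(as.matrix(dat))
  events <- as.data.frame(hdr$events)
  if (!nrow(events)) {
    events <- data.frame(sample = integer(0), condition = character(0))
  }
  rec <- recording(mat, hdr$rate, rownames(mat), events)
  if (!is.null(montage)) {
    missing <- setdiff(montage$labels, rec$labels)
    if (length(missing)) {
      stop("recording is missing montage channels: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    rec$data <- rec$data[montage$labels, , drop = FALSE]
    rec$labels <- montage$labels
  }
  rec
}
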