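#' Continuous multichannel EEG record
#'
#' Lightweight container for a continuous recording: a channels x samples
#' matrix plus sampling rate and an event table. Events carry the sample
#' index of each stimulus onset (0-based, following the package-wide
#' convention) and arbitrary further columns (AM rate, cue, condition, ...).
#'
#' @param data Numeric matrix, channels x samples (microvolts).
#' @param fs_hz Sampling rate in Hz.
#' @param channel_names Character vector, one name per row of `data`.
#' @param events Data frame with at least an `onset_sample` column (0-based
#'   sample indices), or `NULL`.
#' @return An object of class `eeg_continuous`.
#' @export
eeg_continuous <- function(data, fs_hz, channel_names, events = NULL) {
  stopifnot(is.matrix(data), is.numeric(data))
  if (nrow(data) != length(channel_names)) {
    stop("channel_names length (", length(channel_names),
         ") does not match data rows (", nrow(data), ")")
  }
  if (!is.null(events)) {
    stopifnot(is.data.frame(events))
    if (!"onset_sample" %in% names(events)) {
      stop("events must contain an 'onset_sample' column")
    }
  }
  rownames(data) <- channel_names
  structure(
    list(data = data, fs_hz = fs_hz, channel_names = channel_names,
         events = events),
    class = "eeg_continuous"
  )
}

#' @export
print.eeg_continuous <- function(x, ...) {
  cat(sprintf("<eeg_continuous> %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
              nrow(x$data), ncol(x$data), x$fs_hz, ncol(x$data) / x$fs_hz,
              if (is.null(x$events)) 0L else nrow(x$events)))
  invisible(x)
}

#' Epoched multichannel EEG
#'
#' Container for epoched data: a trials x channels x samples array with a
#' per-trial condition label and a bad-trial mask. The time axis is implied
#' by `t0_s` (epoch start relative to the event, seconds) and `fs_hz`;
#' windows throughout the package are half-open `[start, end)` in
#' event-relative seconds.
#'
#' @param data Numeric array, trials x channels x samples.
#' @param fs_hz Sampling rate, Hz.
#' @param t0_s Epoch start relative to the event, seconds (e.g. -0.5).
#' @param labels Character or factor vector of per-trial condition labels.
#' @param channel_names Channel names, one per array column.
#' @param bad_mask Logical per-trial mask; `TRUE` marks a rejected trial.
#' @param event_table Optional data frame with one row of event metadata per
#'   trial.
#' @return An object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, fs_hz, t0_s, labels, channel_names,
                       bad_mask = rep(FALSE, dim(data)[1]),
                       event_table = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  n <- dim(data)[1]
  if (length(labels) != n) stop("labels length must equal trial count")
  if (length(bad_mask) != n) stop("bad_mask length must equal trial count")
  if (dim(data)[2] != length(channel_names)) {
    stop("channel_names length must equal channel dimension")
  }
  good <- which(!bad_mask)
  if (length(good) > 0 && anyNA(data[good, , , drop = FALSE])) {
    stop("retained trials contain NA values")
  }
  structure(
    list(data = data, fs_hz = fs_hz, t0_s = t0_s,
         labels = as.character(labels), channel_names = channel_names,
         bad_mask = bad_mask, event_table = event_table),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_epochs> %d trials (%d good) x %d channels x %d samples @ %g Hz, t0 = %g s\n",
              d[1], sum(!x$bad_mask), d[2], d[3], x$fs_hz, x$t0_s))
  tab <- table(x$labels[!x$bad_mask])
  cat("  conditions:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Time axis of an epochs object
#'
#' @param e An `eeg_epochs` object.
#' @return Numeric vector of sample times in seconds relative to the event.
#' @export
epoch_times <- function(e) {
  e$t0_s + (seq_len(dim(e$data)[3]) - 1) / e$fs_hz
}

#' Indices of retained (non-rejected) trials
#'
#' @param e An `eeg_epochs` object.
#' @param condition Optional condition label to filter on.
#' @return Integer vector of trial indices.
#' @export
good_trials <- function(e, condition = NULL) {
  keep <- !e$bad_mask
  if (!is.null(condition)) keep <- keep & e$labels %in% condition
  which(keep)
}

# Sample index range (1-based, inclusive) of a half-open time window
# [w1, w2) expressed relative to the event.
window_samples <- function(e, window_s) {
  t <- epoch_times(e)
  idx <- which(t >= window_s[1] - 1e-9 & t < window_s[2] - 1e-9)
  if (length(idx) == 0) {
    stop("window [", window_s[1], ", ", window_s[2], ") lies outside the epoch")
  }
  idx
}
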