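#' Zero-phase band-pass filter a continuous record
#'
#' Applies a zero-phase (forward-backward) Butterworth band-pass, implemented
#' as a cascade of a 2nd-order high-pass and a 4th-order low-pass, each run
#' through [signal::filtfilt()]. The cascade keeps the high-pass numerically
#' stable at the very low cutoffs used for evoked analyses (0.1 Hz at a
#' 1000 Hz rate). Setting `hp_hz = 0` skips the high-pass stage.
#'
#' @param x An `eeg_continuous`.
#' @param hp_hz High-pass cutoff, Hz (0 = none).
#' @param lp_hz Low-pass cutoff, Hz; must satisfy `hp_hz < lp_hz < fs/2`.
#' @param hp_order,lp_order Butterworth orders of the two stages.
#' @return Filtered `eeg_continuous`.
#' @export
bandpass_filter <- function(x, hp_hz, lp_hz, hp_order = 2, lp_order = 4) {
  stopifnot(inherits(x, "eeg_continuous"))
  fs <- x$fs_hz
  if (!(hp_hz >= 0 && hp_hz < lp_hz && lp_hz < fs / 2)) {
    stop("invalid band: need 0 <= hp < lp < fs/2 (got ", hp_hz, ", ", lp_hz,
         " at fs ", fs, ")")
  }
  lp <- signal::butter(lp_order, lp_hz / (fs / 2), type = "low")
  hp <- if (hp_hz > 0) signal::butter(hp_order, hp_hz / (fs / 2), type = "high")
  out <- x$data
  for (ch in seq_len(nrow(out))) {
    y <- signal::filtfilt(lp, out[ch, ])
    if (!is.null(hp)) y <- signal::filtfilt(hp, y)
    out[ch, ] <- y
  }
  x$data <- out
  x
}

#' Cut a continuous record into event-locked epochs
#'
#' Extracts one epoch per event over the half-open window
#' `[window_s[1], window_s[2])` relative to each event's `onset_sample`.
#' Events whose window falls outside the record are kept (so trial indexing
#' matches the event table) but flagged in the bad-trial mask with a warning.
#'
#' @param x An `eeg_continuous` with an event table.
#' @param window_s Epoch window, seconds relative to the event, e.g.
#'   `c(-0.5, 2.5)`.
#' @param label_col Event-table column used as the per-trial condition label
#'   (default `"am_rate"` falling back to `"condition"` then to `"event"`).
#' @return An [eeg_epochs()] object; trials are ordered as the events.
#' @export
epoch_data <- function(x, window_s, label_col = NULL) {
  stopifnot(inherits(x, "eeg_continuous"))
  if (is.null(x$events) || nrow(x$events) == 0) {
    stop("record has no events to epoch around")
  }
  fs <- x$fs_hz
  if (is.null(label_col)) {
    label_col <- intersect(c("am_rate", "condition"), names(x$events))[1]
  }
  labels <- if (!is.na(label_col) && label_col %in% names(x$events)) {
    as.character(x$events[[label_col]])
  } else rep("event", nrow(x$events))

  n_smp <- round((window_s[2] - window_s[1]) * fs)
  off0 <- round(window_s[1] * fs)
  n_ev <- nrow(x$events)
  n_ch <- nrow(x$data)
  out <- array(0, c(n_ev, n_ch, n_smp))
  bad <- rep(FALSE, n_ev)
  for (i in seq_len(n_ev)) {
    start <- x$events$onset_sample[i] + off0 + 1L   # 1-based
    stop_ <- start + n_smp - 1L
    if (start < 1 || stop_ > ncol(x$data)) {
      bad[i] <- TRUE
      next
    }
    out[i, , ] <- x$data[, start:stop_]
  }
  if (any(bad)) {
    warning(sum(bad), " event(s) fell outside the record and were flagged bad")
  }
  eeg_epochs(out, fs, window_s[1], labels, x$channel_names, bad_mask = bad,
             event_table = x$events)
}

# Per-trial maximum (over channels) peak-to-peak range within a window.
trial_ranges <- function(e, window_s) {
  idx <- window_samples(e, window_s)
  n_ch <- dim(e$data)[2]
  vapply(seq_len(dim(e$data)[1]), function(i) {
    seg <- matrix(e$data[i, , idx], n_ch, length(idx))
    max(apply(seg, 1, function(v) diff(range(v))))
  }, numeric(1))
}

#' Reject trials exceeding an absolute peak-to-peak range
#'
#' Masks every trial for which any channel's peak-to-peak amplitude range
#' within `window_s` exceeds `range_limit`. The default limit of 300 uV over
#' 0-2 s is the screening rule applied before component decomposition.
#'
#' @param e An `eeg_epochs`.
#' @param range_limit Range limit, uV (default 300).
#' @param window_s Window checked, seconds relative to the event
#'   (default `c(0, 2)`).
#' @return `eeg_epochs` with updated `bad_mask`; trial order is preserved and
#'   already-bad trials stay bad.
#' @export
reject_absolute <- function(e, range_limit = 300, window_s = c(0, 2)) {
  stopifnot(inherits(e, "eeg_epochs"))
  r <- trial_ranges(e, window_s)
  e$bad_mask <- e$bad_mask | (r > range_limit)
  e
}

#' Reject the fraction of trials with the largest ranges
#'
#' Among currently retained trials, masks the `ceiling(fraction * n_good)`
#' trials with the largest maximum-channel peak-to-peak range in `window_s`.
#' Ties are broken deterministically in favor of keeping the earlier trial.
#'
#' @param e An `eeg_epochs`.
#' @param fraction Fraction to reject in `[0, 1)` (default 0.10).
#' @param window_s Window checked (default `c(0, 2)`).
#' @return `eeg_epochs` with updated `bad_mask`.
#' @export
reject_percentile <- function(e, fraction = 0.10, window_s = c(0, 2)) {
  stopifnot(inherits(e, "eeg_epochs"), fraction >= 0, fraction < 1)
  if (fraction == 0) return(e)
  good <- which(!e$bad_mask)
  n_rm <- ceiling(fraction * length(good))
  if (n_rm == 0) return(e)
  r <- trial_ranges(e, window_s)[good]
  # order by descending range; among equal ranges the later trial goes first
  ord <- order(-r, -good)
  e$bad_mask[good[ord[seq_len(n_rm)]]] <- TRUE
  e
}

#' Re-reference epochs to the common average
#'
#' Subtracts the instantaneous mean over all channels from every channel, so
#' the per-sample channel mean is zero afterwards. Idempotent.
#'
#' @param e An `eeg_epochs`.
#' @return Average-referenced `eeg_epochs`.
#' @export
rereference_average <- function(e) {
  stopifnot(inherits(e, "eeg_epochs"))
  d <- e$data
  for (i in seq_len(dim(d)[1])) {
    seg <- matrix(d[i, , ], dim(d)[2], dim(d)[3])
    d[i, , ] <- sweep(seg, 2, colMeans(seg))
  }
  e$data <- d
  e
}
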