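#' Event-related potential of one condition
#'
#' Arithmetic mean over the retained trials of a condition, in the time
#' domain.
#'
#' @param e An `eeg_epochs`.
#' @param condition Condition label (e.g. an AM rate); `NULL` averages all
#'   retained trials.
#' @return Object of class `erp_result`: list with `data` (channels x
#'   samples), `fs_hz`, `t0_s`, `condition`, `n_trials`, `channel_names`.
#' @export
compute_erp <- function(e, condition = NULL) {
  stopifnot(inherits(e, "eeg_epochs"))
  idx <- good_trials(e, condition)
  if (length(idx) == 0) {
    stop("no retained trials", if (!is.null(condition))
      paste0(" in condition '", condition, "'"))
  }
  avg <- matrix(0, dim(e$data)[2], dim(e$data)[3])
  for (i in idx) avg <- avg + e$data[i, , , drop = TRUE]
  structure(list(data = avg / length(idx), fs_hz = e$fs_hz, t0_s = e$t0_s,
                 condition = if (is.null(condition)) "all" else
                   as.character(condition),
                 n_trials = length(idx), channel_names = e$channel_names),
            class = "erp_result")
}

#' Global field power of an ERP
#'
#' The per-sample standard deviation of voltage across electrodes
#' (population convention, n denominator), averaged over the window that
#' spans the obligatory onset components P1, N1 and P2 (0-230 ms by
#' default). A reference-free scalar measure of onset-response strength.
#'
#' @param erp An `erp_result`.
#' @param window_s Averaging window, seconds (default `c(0, 0.230)`,
#'   half-open).
#' @return GFP in uV.
#' @export
global_field_power <- function(erp, window_s = c(0, 0.230)) {
  stopifnot(inherits(erp, "erp_result"))
  t <- erp$t0_s + (seq_len(ncol(erp$data)) - 1) / erp$fs_hz
  sel <- t >= window_s[1] - 1e-9 & t < window_s[2] - 1e-9
  if (!any(sel)) stop("GFP window lies outside the epoch")
  seg <- erp$data[, sel, drop = FALSE]
  n_ch <- nrow(seg)
  sd_pop <- sqrt(colMeans(seg^2) - colMeans(seg)^2)
  mean(sd_pop)
}

#' Evoked (ERP) spectrum of the steady-state window
#'
#' Cuts the ERP to the steady-state window (0.5-2 s by default, skipping the
#' onset response), applies a rectangular window, and estimates power on a
#' 1-Hz grid with boxcar spectral smoothing: the segment is zero-padded to a
#' fine grid and squared-amplitude power is averaged over +/- half the
#' smoothing bandwidth around each output frequency.
#'
#' @param erp An `erp_result`.
#' @param window_s Analysis window, seconds (default `c(0.5, 2)`).
#' @param freqs Output frequency grid, Hz (default `1:60`).
#' @param smoothing_hz Smoothing bandwidth (default 2, i.e. +/- 1 Hz).
#' @return A [spectral_estimate()] (power in uV^2 per smoothed bin).
#' @export
evoked_spectrum <- function(erp, window_s = c(0.5, 2), freqs = 1:60,
                            smoothing_hz = 2) {
  stopifnot(inherits(erp, "erp_result"))
  fs <- erp$fs_hz
  t <- erp$t0_s + (seq_len(ncol(erp$data)) - 1) / fs
  sel <- t >= window_s[1] - 1e-9 & t < window_s[2] - 1e-9
  if (!any(sel)) stop("spectral window lies outside the epoch")
  if (diff(window_s) < 2 / smoothing_hz) {
    stop("window too short for the requested spectral smoothing")
  }
  if (max(freqs) >= fs / 2) stop("requested frequencies exceed Nyquist")
  pw <- fft_power_grid(erp$data[, sel, drop = FALSE], fs, freqs, smoothing_hz)
  spectral_estimate(freqs, pw, erp$channel_names, smoothing_hz, window_s,
                    "rectangular", erp$n_trials)
}

#' Intertrial phase coherence
#'
#' ITPC(f, channel) is the modulus of the across-trial mean of unit phase
#' vectors, where phases come from the windowed Fourier transform of each
#' trial over `window_s`. 1 indicates perfect phase locking, 0 random
#' phases; by construction the measure ignores per-trial amplitude.
#'
#' @param e An `eeg_epochs` with at least two retained trials.
#' @param freqs Frequencies, Hz (default `1:60`).
#' @param window_s Analysis window (default `c(0.5, 2)`).
#' @param condition Optional condition filter.
#' @return Object of class `itpc_estimate`: list with `freqs_hz`, `itpc`
#'   (channels x freqs, in `[0, 1]`), `n_trials`, `channel_names`.
#' @export
itpc <- function(e, freqs = 1:60, window_s = c(0.5, 2), condition = NULL) {
  stopifnot(inherits(e, "eeg_epochs"))
  idx <- good_trials(e, condition)
  if (length(idx) < 2) stop("ITPC needs at least 2 retained trials")
  sel <- window_samples(e, window_s)
  acc <- matrix(0 + 0i, dim(e$data)[2], length(freqs))
  for (i in idx) {
    seg <- matrix(e$data[i, , sel], dim(e$data)[2], length(sel))
    X <- dtft(seg, e$fs_hz, freqs)
    mod <- Mod(X)
    mod[mod == 0] <- 1
    acc <- acc + X / mod
  }
  structure(list(freqs_hz = freqs, itpc = Mod(acc) / length(idx),
                 n_trials = length(idx), channel_names = e$channel_names),
            class = "itpc_estimate")
}

#' Steady-state power summary at the AM rates
#'
#' Reduces per-condition evoked spectra to a tidy table of fronto-central
#' power at the stimulation rates, the unit of analysis for the
#' session-by-rate inference.
#'
#' @param spectra Named list: condition label -> `spectral_estimate` on a
#'   common frequency grid.
#' @param montage The montage.
#' @param set Electrode set to average over (default `"frontocentral_9"`).
#' @param rates AM rates to extract, Hz (default `c(4, 20, 40)`); each must
#'   lie on the frequency grid.
#' @param session Optional session identifier copied into the table.
#' @return Data frame with columns `session`, `condition`, `am_rate`,
#'   `power`.
#' @export
assr_summary <- function(spectra, montage, set = "frontocentral_9",
                         rates = c(4, 20, 40), session = NA) {
  stopifnot(is.list(spectra), length(spectra) >= 1)
  if (is.null(names(spectra)) || any(names(spectra) == "")) {
    stop("spectra must be a named list keyed by condition")
  }
  rows <- lapply(names(spectra), function(cond) {
    sp <- spectra[[cond]]
    stopifnot(inherits(sp, "spectral_estimate"))
    bins <- match(rates, sp$freqs_hz)
    if (anyNA(bins)) {
      stop("AM rate(s) ", paste(rates[is.na(bins)], collapse = ", "),
           " not on the frequency grid of condition '", cond, "'")
    }
    avg <- spectrum_set_average(sp, montage, set)
    data.frame(session = session, condition = cond, am_rate = rates,
               power = avg[bins], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
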