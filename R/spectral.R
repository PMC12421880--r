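# Spectral primitives: DPSS tapers, windowed FFT power on a 1-Hz grid,
# boxcar spectral smoothing.

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers of length `n` for a half-bandwidth of
#' `half_bw_hz` at sampling rate `fs`, via the eigenvectors of the standard
#' symmetric tridiagonal Slepian matrix. Tapers are unit-energy; the number
#' of tapers defaults to `2*n*W - 1` rounded down (the usual multitaper
#' choice).
#'
#' @param n Taper length, samples.
#' @param half_bw_hz Spectral half-bandwidth, Hz.
#' @param fs Sampling rate, Hz.
#' @param k Number of tapers; default `floor(2 * n * half_bw_hz / fs - 1)`,
#'   at least 1.
#' @return Matrix n x k, columns are tapers.
#' @export
dpss_tapers <- function(n, half_bw_hz, fs, k = NULL) {
  W <- half_bw_hz / fs
  if (W <= 0 || W >= 0.5) stop("half bandwidth must lie in (0, fs/2)")
  if (is.null(k)) k <- max(1L, floor(2 * n * W - 1))
  t_ <- seq_len(n) - 1
  diag_main <- ((n - 1 - 2 * t_) / 2)^2 * cos(2 * pi * W)
  diag_off <- t_[-1] * (n - t_[-1]) / 2
  M <- diag(diag_main)
  M[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- diag_off
  M[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- diag_off
  eg <- eigen(M, symmetric = TRUE)
  v <- eg$vectors[, seq_len(k), drop = FALSE]
  # sign convention: positive mean (even tapers) / positive initial slope
  for (j in seq_len(k)) {
    s <- sum(v[, j])
    if (abs(s) > 1e-8 && s < 0) v[, j] <- -v[, j]
    if (abs(s) <= 1e-8 && v[2, j] - v[1, j] < 0) v[, j] <- -v[, j]
  }
  v
}

#' Frequency-resolved power container
#'
#' @param freqs_hz Strictly increasing frequency grid, Hz.
#' @param power Channels x frequencies matrix of nonnegative power.
#' @param channel_names Channel names.
#' @param smoothing_hz Spectral smoothing bandwidth, Hz.
#' @param window_s Analysis window, seconds relative to the event.
#' @param taper `"rectangular"` or `"dpss"`.
#' @param n_trials Number of trials entering the estimate.
#' @return Object of class `spectral_estimate`.
#' @export
spectral_estimate <- function(freqs_hz, power, channel_names, smoothing_hz,
                              window_s, taper, n_trials = NA_integer_) {
  stopifnot(all(diff(freqs_hz) > 0), all(power >= -1e-12))
  structure(list(freqs_hz = freqs_hz, power = power,
                 channel_names = channel_names, smoothing_hz = smoothing_hz,
                 window_s = window_s, taper = taper, n_trials = n_trials),
            class = "spectral_estimate")
}

#' @export
print.spectral_estimate <- function(x, ...) {
  cat(sprintf("<spectral_estimate> %d channels x %d freqs (%g-%g Hz), %s taper\n",
              nrow(x$power), length(x$freqs_hz), min(x$freqs_hz),
              max(x$freqs_hz), x$taper))
  invisible(x)
}

#' Average spectral power over an electrode set
#'
#' @param spec A `spectral_estimate`.
#' @param montage The montage.
#' @param set Electrode-set name (see [montage_set()]).
#' @return Numeric vector of power over the frequency grid.
#' @export
spectrum_set_average <- function(spec, montage, set) {
  chans <- montage_set(montage, set)
  idx <- match(chans, spec$channel_names)
  if (anyNA(idx)) {
    warning("electrode set '", set, "' not fully present; using intersection")
    idx <- idx[!is.na(idx)]
  }
  colMeans(spec$power[idx, , drop = FALSE])
}

# Rectangular-window power of a channels x samples segment on a 1-Hz-style
# grid: zero-pad to pad_s seconds, take squared amplitude spectrum, smooth
# with a +/- smoothing/2 boxcar, sample at the requested frequencies.
fft_power_grid <- function(seg, fs, freqs, smoothing_hz, pad_s = 4,
                           taper = NULL) {
  n <- ncol(seg)
  n_pad <- max(round(pad_s * fs), n)
  if (!is.null(taper)) seg <- seg * matrix(taper, nrow(seg), n, byrow = TRUE)
  padded <- cbind(seg, matrix(0, nrow(seg), n_pad - n))
  X <- stats::mvfft(t(padded))                 # n_pad x channels
  fbin <- (seq_len(n_pad) - 1) * fs / n_pad
  half <- floor(n_pad / 2) + 1
  p <- (2 * Mod(X[seq_len(half), , drop = FALSE]) / n)^2
  fbin <- fbin[seq_len(half)]
  hw <- smoothing_hz / 2
  out <- matrix(0, nrow(seg), length(freqs))
  for (i in seq_along(freqs)) {
    sel <- which(fbin >= freqs[i] - hw - 1e-9 & fbin <= freqs[i] + hw + 1e-9)
    out[, i] <- colMeans(p[sel, , drop = FALSE])
  }
  out
}

# DTFT of a channels x samples segment at arbitrary frequencies.
dtft <- function(seg, fs, freqs) {
  n <- ncol(seg)
  t_ <- (seq_len(n) - 1) / fs
  E <- exp(-2i * pi * outer(t_, freqs))        # n x F
  seg %*% E                                    # channels x F
}
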