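#' Parameters of the neural/artifact signal model
#'
#' Collects the amplitudes and rates of every signal class the synthesizer
#' injects into a session: the auditory steady-state oscillation per AM rate,
#' the tri-phasic P1-N1-P2 onset response, the sharp low-latency CI artifact
#' with a lateralized temporal topography, anticipation-period alpha with a
#' cue-driven hemispheric modulation, 1/f background noise and blink-like
#' transients. Units are microvolts at the topography center unless noted.
#'
#' The alpha model is multiplicative: each hemisphere carries a band-limited
#' (7-13 Hz) noise source of variance `alpha_base_power`; during the
#' anticipation period its power is scaled by `1 + d` when the cued side is
#' ipsilateral to that hemisphere and `1 - d` when contralateral, where
#' `d = alpha_lateralization` for the hemisphere opposite the implant and
#' `d = alpha_lateralization * alpha_asymmetry` for the hemisphere on the
#' implant side. `alpha_asymmetry > 1` therefore plants a stronger attention
#' effect over the implanted side. On front-cue trials the same modulation
#' is applied with opposite sign keyed to the to-be-ignored lateral speaker,
#' planting a distractor-driven reversal in the suppression index.
#'
#' @param assr_amp_per_rate Named numeric: steady-state amplitude (uV) per AM
#'   rate, names are rates in Hz.
#' @param onset_amp P1-N1-P2 peak scale, uV.
#' @param ci_artifact_amp CI artifact peak amplitude, uV.
#' @param ci_topo_width Spatial Gaussian width (unit-sphere chord) of the
#'   artifact topography around the implant-side temporal channels.
#' @param alpha_base_power Variance (uV^2) of each hemispheric alpha source.
#' @param alpha_lateralization Signed cue-modulation depth `d` of alpha power
#'   (|d * alpha_asymmetry| must stay below 1).
#' @param alpha_asymmetry Ratio of modulation depth on the implant-side
#'   versus opposite hemisphere.
#' @param noise_1f_amp RMS (uV) of each spatially smooth 1/f background
#'   source; 0 disables background noise.
#' @param blink_rate_hz Mean rate of blink transients (Poisson), Hz.
#' @param fs_hz Sampling rate (default 1000 Hz, the recording rate).
#' @param phase_jitter_sd SD (radians) of trial-to-trial ASSR phase jitter;
#'   0 (default) makes the steady-state response perfectly phase-locked.
#' @param seed Integer seed for all synthesis randomness.
#' @return Object of class `neural_sim_params`.
#' @export
neural_sim_params <- function(assr_amp_per_rate = c(`4` = 1.5, `20` = 0.8,
                                                    `40` = 1.0),
                              onset_amp = 15, ci_artifact_amp = 150,
                              ci_topo_width = 0.4, alpha_base_power = 10,
                              alpha_lateralization = 0.2,
                              alpha_asymmetry = 1.5, noise_1f_amp = 5,
                              blink_rate_hz = 0.1, fs_hz = 1000,
                              phase_jitter_sd = 0, seed = 1) {
  stopifnot(all(assr_amp_per_rate >= 0), onset_amp >= 0,
            ci_artifact_amp >= 0, ci_topo_width > 0,
            alpha_base_power >= 0, is.finite(alpha_lateralization),
            is.finite(alpha_asymmetry), noise_1f_amp >= 0,
            blink_rate_hz >= 0, fs_hz > 0, phase_jitter_sd >= 0)
  dmax <- abs(alpha_lateralization) * max(1, abs(alpha_asymmetry))
  if (dmax >= 1) {
    stop("alpha modulation depth |lateralization x asymmetry| must be < 1")
  }
  structure(list(assr_amp_per_rate = assr_amp_per_rate,
                 onset_amp = onset_amp, ci_artifact_amp = ci_artifact_amp,
                 ci_topo_width = ci_topo_width,
                 alpha_base_power = alpha_base_power,
                 alpha_lateralization = alpha_lateralization,
                 alpha_asymmetry = alpha_asymmetry,
                 noise_1f_amp = noise_1f_amp, blink_rate_hz = blink_rate_hz,
                 fs_hz = fs_hz, phase_jitter_sd = phase_jitter_sd,
                 seed = seed),
            class = "neural_sim_params")
}

# Tri-phasic onset-response template: positive-negative-positive bumps at
# roughly 50/100/180 ms, zero before stimulus onset.
onset_response_template <- function(t, amp) {
  g <- function(mu, sd) exp(-(t - mu)^2 / (2 * sd^2))
  w <- amp * (0.5 * g(0.050, 0.012) - g(0.100, 0.018) + 0.7 * g(0.180, 0.030))
  w[t < 0] <- 0
  w
}

# Sharp low-latency biphasic CI-artifact transient (~8-15 ms).
ci_artifact_template <- function(t, amp) {
  g <- function(mu, sd) exp(-(t - mu)^2 / (2 * sd^2))
  w <- amp * (g(0.008, 0.0025) - 0.6 * g(0.015, 0.0035))
  w[t < 0] <- 0
  w
}

#' Deterministic source waveform of one passive-listening tone
#'
#' The auditory source injected for a tone of a given AM rate: the onset
#' template plus the steady-state sinusoid at the AM rate over the tone
#' duration. With all noise amplitudes zero, the trial-averaged ERP at any
#' channel equals this waveform scaled by that channel's topography weight.
#'
#' @param params `neural_sim_params`.
#' @param am_rate AM rate, Hz.
#' @param t Time relative to tone onset, seconds.
#' @param tone_dur_s Tone duration, seconds.
#' @param phase ASSR phase offset, radians (default 0).
#' @return Numeric waveform, uV.
#' @export
passive_source_waveform <- function(params, am_rate, t, tone_dur_s = 2,
                                    phase = 0) {
  amp <- params$assr_amp_per_rate[[as.character(am_rate)]]
  if (is.null(amp)) stop("no ASSR amplitude configured for rate ", am_rate)
  w <- onset_response_template(t, params$onset_amp)
  on <- t >= 0 & t < tone_dur_s
  w[on] <- w[on] + amp * sin(2 * pi * am_rate * t[on] + phase)
  w
}

# 1/f-shaped noise sources: rows are sources, unit RMS each, scaled by amp.
oneoverf_noise <- function(n_src, n_samp, fs, rng, amp) {
  if (amp <= 0 || n_src == 0) return(matrix(0, n_src, n_samp))
  out <- matrix(0, n_src, n_samp)
  f <- c(0, seq_len(n_samp - 1)) * fs / n_samp
  f <- pmin(f, fs - f)                      # two-sided frequency axis
  shape <- 1 / sqrt(pmax(f, 1))             # power ~ 1/f above 1 Hz
  shape[1] <- 0                             # no DC
  for (s in seq_len(n_src)) {
    x <- rng$norm(n_samp)
    y <- Re(stats::fft(stats::fft(x) * shape, inverse = TRUE)) / n_samp
    out[s, ] <- amp * y / stats::sd(y)
  }
  out
}

# Band-limited Gaussian noise, unit variance, via FFT brick-wall filtering.
bandlimited_noise <- function(n_samp, fs, band, rng) {
  x <- rng$norm(n_samp)
  f <- c(0, seq_len(n_samp - 1)) * fs / n_samp
  f <- pmin(f, fs - f)
  keep <- f >= band[1] & f <= band[2]
  y <- Re(stats::fft(stats::fft(x) * keep, inverse = TRUE)) / n_samp
  y / stats::sd(y)
}

# Smooth random background topographies plus blink machinery shared by both
# session generators.
background_activity <- function(params, montage, n_samp, rng,
                                n_noise_src = 30) {
  fs <- params$fs_hz
  data <- matrix(0, nrow(montage), n_samp)
  if (params$noise_1f_amp > 0) {
    centers <- montage$name[rng$int(n_noise_src, nrow(montage))]
    topo <- vapply(centers, function(ch) topography_gaussian(montage, ch, 0.35),
                   numeric(nrow(montage)))
    src <- oneoverf_noise(n_noise_src, n_samp, fs, rng, params$noise_1f_amp)
    data <- data + topo %*% src
    # small spatially white sensor noise keeps the covariance full rank
    data <- data + 0.1 * params$noise_1f_amp *
      matrix(rng$norm(nrow(montage) * n_samp), nrow(montage))
  }
  if (params$blink_rate_hz > 0) {
    n_blink <- rng$pois(1, params$blink_rate_hz * n_samp / fs)
    if (n_blink > 0) {
      topo_blink <- (topography_gaussian(montage, "Fp1", 0.4) +
                       topography_gaussian(montage, "Fp2", 0.4)) / 2
      tmpl <- 100 * sin(pi * seq(0, 1, length.out = round(0.3 * fs)))
      onsets <- sort(rng$int(n_blink, max(1, n_samp - length(tmpl))))
      s <- numeric(n_samp)
      for (o in onsets) {
        idx <- o:(o + length(tmpl) - 1)
        s[idx] <- s[idx] + tmpl
      }
      data <- data + topo_blink %o% s
    }
  }
  data
}

ci_topo_center <- function(ci_side) if (ci_side == "left") "T7" else "T8"

#' Generate a synthetic passive-listening EEG session
#'
#' Synthesizes a continuous 64-channel record of the passive AM-tone
#' experiment: for each tone, a P1-N1-P2 onset response plus an AM-rate-locked
#' steady-state oscillation are mixed through a fronto-central topography, a
#' sharp low-latency CI artifact (plus a weak rate-locked artifact pedestal)
#' through a temporal topography on the implant side, on top of spatially
#' smooth 1/f background noise and blink transients.
#'
#' @param design A [passive_design()].
#' @param params A [neural_sim_params()].
#' @param montage An [montage_64()] montage.
#' @param ci_side Implant side, `"left"` or `"right"`.
#' @return An [eeg_continuous()] whose `events` table has columns
#'   `onset_sample` (0-based) and `am_rate`.
#' @export
generate_passive_session <- function(design, params, montage,
                                     ci_side = c("right", "left")) {
  stopifnot(inherits(design, "passive_design"),
            inherits(params, "neural_sim_params"),
            inherits(montage, "eeg_montage"))
  ci_side <- match.arg(ci_side)
  fs <- params$fs_hz
  if (fs <= 2 * max(design$am_rates_hz)) {
    stop("sampling rate must exceed twice the highest AM rate")
  }
  rng <- local_rng(params$seed)
  trials <- design$trials
  n_tr <- nrow(trials)
  pad <- 1.0
  onset_s <- pad +
    cumsum(c(0, utils::head(design$tone_dur_s + trials$isi_s, -1)))
  onset_smp <- round(onset_s * fs)            # 0-based
  n_samp <- max(onset_smp) + round((design$tone_dur_s + pad) * fs)

  phases <- if (params$phase_jitter_sd > 0) {
    params$phase_jitter_sd * rng$norm(n_tr)
  } else rep(0, n_tr)

  tone_n <- round((design$tone_dur_s + 0.5) * fs)   # template span per tone
  tau <- (seq_len(tone_n) - 1) / fs
  # the auditory source carries ongoing 1/f activity in addition to its
  # evoked response, as a cortical source does; without it the source would
  # hold negligible variance and never survive the PCA variance cut
  s_aud <- if (params$noise_1f_amp > 0) {
    as.numeric(oneoverf_noise(1, n_samp, fs, rng, 0.6 * params$noise_1f_amp))
  } else numeric(n_samp)
  s_ci <- numeric(n_samp)
  for (i in seq_len(n_tr)) {
    idx <- onset_smp[i] + seq_len(tone_n)           # 1-based into record
    w <- passive_source_waveform(params, trials$am_rate[i], tau,
                                 design$tone_dur_s, phases[i])
    s_aud[idx] <- s_aud[idx] + w
    if (params$ci_artifact_amp > 0) {
      on <- tau < design$tone_dur_s
      a <- ci_artifact_template(tau, params$ci_artifact_amp)
      a[on] <- a[on] + 0.05 * params$ci_artifact_amp *
        sin(2 * pi * trials$am_rate[i] * tau[on])
      s_ci[idx] <- s_ci[idx] + a
    }
  }
  topo_aud <- topography_gaussian(montage, "FCz", 0.5)
  topo_ci <- topography_gaussian(montage, ci_topo_center(ci_side),
                                 params$ci_topo_width)
  data <- topo_aud %o% s_aud
  if (params$ci_artifact_amp > 0) data <- data + topo_ci %o% s_ci
  data <- data + background_activity(params, montage, n_samp, rng)

  eeg_continuous(data, fs, montage$name,
                 events = data.frame(onset_sample = onset_smp,
                                     am_rate = trials$am_rate))
}

#' Generate a synthetic spatial-attention EEG session
#'
#' Synthesizes the cue-target spatial listening task: each trial presents a
#' visual cue (front or side), an anticipation period during which the two
#' hemispheric occipito-parietal alpha sources are power-modulated by the
#' cued side (see [neural_sim_params()] for the modulation model), then the
#' competing spoken numbers, which evoke an onset response and a CI artifact.
#' Background 1/f noise and blinks are added throughout.
#'
#' @param design An [attention_design()].
#' @param params A [neural_sim_params()].
#' @param montage An [montage_64()] montage.
#' @return An [eeg_continuous()] whose `events` table is the design trial
#'   table plus `onset_sample` (0-based, the *cue* onset) and
#'   `sound_sample`.
#' @export
generate_attention_session <- function(design, params, montage) {
  stopifnot(inherits(design, "attention_design"),
            inherits(params, "neural_sim_params"),
            inherits(montage, "eeg_montage"))
  fs <- params$fs_hz
  rng <- local_rng(params$seed)
  trials <- design$trials
  n_tr <- nrow(trials)
  spacing_s <- 4.5                      # cue-to-cue interval; epochs are -1..4 s
  pad <- 1.5
  cue_s <- pad + (seq_len(n_tr) - 1) * spacing_s
  cue_smp <- round(cue_s * fs)          # 0-based
  n_samp <- max(cue_smp) + round((spacing_s + pad) * fs)

  ci_side <- design$ci_side
  d_side <- c(left = params$alpha_lateralization *
                if (ci_side == "left") params$alpha_asymmetry else 1,
              right = params$alpha_lateralization *
                if (ci_side == "right") params$alpha_asymmetry else 1)

  data <- matrix(0, nrow(montage), n_samp)
  hemi_center <- c(left = "PO7", right = "PO8")
  for (h in c("left", "right")) {
    src <- bandlimited_noise(n_samp, fs, c(7, 13), rng) *
      sqrt(params$alpha_base_power)
    gain <- rep(1, n_samp)
    for (i in seq_len(n_tr)) {
      # side cue: alpha power rises ipsilateral to the attended side and
      # falls contralateral; front cue: the reversed pattern keyed to the
      # to-be-ignored lateral speaker (distractor-driven suppression)
      sgn <- if (trials$cue[i] == "side") {
        if (trials$side_speaker[i] == h) 1 else -1
      } else {
        if (trials$side_speaker[i] == h) -1 else 1
      }
      a0 <- cue_smp[i] + round(design$cue_dur_s * fs) + 1
      a1 <- cue_smp[i] + round((design$cue_dur_s + trials$anticipation_s[i]) * fs)
      gain[a0:a1] <- sqrt(1 + sgn * d_side[[h]])
    }
    topo <- topography_gaussian(montage, hemi_center[[h]], 0.5)
    topo[montage$hemisphere != h] <- 0
    data <- data + topo %o% (src * gain)
  }

  # sound-evoked activity at number onset
  sound_smp <- cue_smp +
    round((design$cue_dur_s + trials$anticipation_s) * fs)
  tmpl_n <- round(0.6 * fs)
  tau <- (seq_len(tmpl_n) - 1) / fs
  s_aud <- numeric(n_samp)
  s_ci <- numeric(n_samp)
  for (i in seq_len(n_tr)) {
    idx <- sound_smp[i] + seq_len(tmpl_n)
    s_aud[idx] <- s_aud[idx] + onset_response_template(tau, 0.5 * params$onset_amp)
    if (params$ci_artifact_amp > 0) {
      s_ci[idx] <- s_ci[idx] + ci_artifact_template(tau, params$ci_artifact_amp)
    }
  }
  data <- data + topography_gaussian(montage, "FCz", 0.5) %o% s_aud
  if (params$ci_artifact_amp > 0) {
    data <- data + topography_gaussian(montage, ci_topo_center(ci_side),
                                       params$ci_topo_width) %o% s_ci
  }
  data <- data + background_activity(params, montage, n_samp, rng)

  ev <- cbind(trials, onset_sample = cue_smp, sound_sample = sound_smp)
  cnt <- table(ev$condition)
  if (any(cnt == 0)) stop("design error: empty condition")
  eeg_continuous(data, fs, montage$name, events = ev)
}

#' Write the condition table of an attention session as TSV
#'
#' @param x An `eeg_continuous` from [generate_attention_session()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_condition_table <- function(x, path) {
  stopifnot(inherits(x, "eeg_continuous"), !is.null(x$events))
  cols <- intersect(c("trial", "block", "cue", "target_side",
                      "distractor_side", "condition", "onset_sample"),
                    names(x$events))
  utils::write.table(x$events[, cols], path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
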