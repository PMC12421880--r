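#' Multitaper spectrum of the anticipation period
#'
#' Estimates oscillatory power in the cue-target anticipation window
#' (0.75-1.5 s after cue onset by default, i.e. after cue offset and before
#' the earliest possible sound), per condition: single-trial power from DPSS
#' multitapering with the given spectral half-bandwidth is averaged over the
#' retained trials of each condition. Power is returned as spectral density
#' (uV^2/Hz) on a 1-Hz grid, so band power is the sum over the band's bins.
#'
#' @param e Cue-locked `eeg_epochs`.
#' @param window_s Analysis window, seconds after cue onset
#'   (default `c(0.75, 1.5)`).
#' @param freqs Frequency grid, Hz (default `1:30`).
#' @param smoothing_hz Multitaper spectral half-bandwidth, Hz (default 2;
#'   with the default 0.75-s window this yields 2 tapers).
#' @param conditions Conditions to estimate; default all labels present.
#' @return Named list of [spectral_estimate()] objects, one per condition.
#' @export
anticipation_spectrum <- function(e, window_s = c(0.75, 1.5), freqs = 1:30,
                                  smoothing_hz = 2, conditions = NULL) {
  stopifnot(inherits(e, "eeg_epochs"))
  sel <- window_samples(e, window_s)
  n <- length(sel)
  fs <- e$fs_hz
  if (max(freqs) >= fs / 2) stop("requested frequencies exceed Nyquist")
  tapers <- dpss_tapers(n, smoothing_hz, fs)
  if (is.null(conditions)) conditions <- unique(e$labels[!e$bad_mask])
  n_pad <- max(2^ceiling(log2(4 * fs)), n)     # fine grid for 1-Hz sampling
  fbin <- (seq_len(n_pad) - 1) * fs / n_pad
  half <- floor(n_pad / 2) + 1
  fbin <- fbin[seq_len(half)]
  bins <- vapply(freqs, function(f) which.min(abs(fbin - f)), integer(1))

  out <- list()
  for (cond in conditions) {
    idx <- good_trials(e, cond)
    if (length(idx) == 0) stop("no retained trials in condition '", cond, "'")
    acc <- matrix(0, dim(e$data)[2], length(freqs))
    for (i in idx) {
      seg <- matrix(e$data[i, , sel], dim(e$data)[2], n)
      ptr <- matrix(0, dim(e$data)[2], length(freqs))
      for (k in seq_len(ncol(tapers))) {
        tap <- seg * matrix(tapers[, k], nrow(seg), n, byrow = TRUE)
        X <- stats::mvfft(t(cbind(tap, matrix(0, nrow(seg), n_pad - n))))
        p <- 2 * Mod(X[seq_len(half), , drop = FALSE])^2 / fs
        ptr <- ptr + t(p[bins, , drop = FALSE])
      }
      acc <- acc + ptr / ncol(tapers)
    }
    out[[as.character(cond)]] <- spectral_estimate(
      freqs, acc / length(idx), e$channel_names, smoothing_hz, window_s,
      "dpss", length(idx))
  }
  out
}

#' Normalized lateralization index
#'
#' The contrast `(a - b) / (a + b)` used by every attention index in the
#' package; bounded in `[-1, 1]` for nonnegative power and antisymmetric in
#' its arguments.
#'
#' @param pow_a,pow_b Nonnegative power values (vectors allowed).
#' @return `(pow_a - pow_b) / (pow_a + pow_b)`; `NA` with a warning where
#'   both inputs are zero.
#' @export
lateralization_index <- function(pow_a, pow_b) {
  if (any(pow_a < 0 | pow_b < 0)) stop("power must be nonnegative")
  s <- pow_a + pow_b
  out <- ifelse(s == 0, NA_real_, (pow_a - pow_b) / s)
  if (anyNA(out)) warning("zero total power: lateralization index undefined")
  out
}

# Shared engine: per-electrode LI between two condition spectra, averaged
# over the band, then over each occipito-parietal set.
li_result <- function(kind, spec_a, spec_b, montage, band,
                      sets = c(left = "op_left_12", right = "op_right_12")) {
  stopifnot(inherits(spec_a, "spectral_estimate"),
            inherits(spec_b, "spectral_estimate"),
            identical(spec_a$freqs_hz, spec_b$freqs_hz))
  fsel <- spec_a$freqs_hz >= band[1] & spec_a$freqs_hz <= band[2]
  li_fe <- lateralization_index(spec_a$power[, fsel, drop = FALSE],
                                spec_b$power[, fsel, drop = FALSE])
  per_electrode <- rowMeans(li_fe)
  names(per_electrode) <- spec_a$channel_names
  set_avg <- vapply(sets, function(s) {
    chans <- intersect(montage_set(montage, s), spec_a$channel_names)
    if (length(chans) < length(montage_set(montage, s))) {
      warning("set '", s, "' incomplete; averaging over the intersection")
    }
    mean(per_electrode[chans])
  }, numeric(1))
  structure(list(index_kind = kind, band_hz = band,
                 per_electrode = per_electrode, set_avg = set_avg,
                 sets = sets),
            class = "lateralization_result")
}

#' @export
print.lateralization_result <- function(x, ...) {
  cat(sprintf("<lateralization_result> %s, band %g-%g Hz\n", x$index_kind,
              x$band_hz[1], x$band_hz[2]))
  print(round(x$set_avg, 4))
  invisible(x)
}

#' Attentional modulation index (AMI)
#'
#' Per-electrode alpha-band lateralization of power between the select-left
#' and select-right conditions:
#' `(P_select-left - P_select-right) / (P_select-left + P_select-right)`,
#' computed per frequency on condition-average power, averaged over the band
#' and over each occipito-parietal electrode set. Under the canonical
#' ipsilateral alpha increase, left-hemisphere electrodes give positive AMI
#' and right-hemisphere electrodes negative AMI.
#'
#' @param spec_select_left,spec_select_right `spectral_estimate`s of the two
#'   lateral-target conditions.
#' @param montage The montage.
#' @param band Frequency band, Hz (default `c(7, 13)`, alpha).
#' @return A `lateralization_result` with per-electrode values and
#'   `set_avg["left"]` / `set_avg["right"]`.
#' @export
ami <- function(spec_select_left, spec_select_right, montage,
                band = c(7, 13)) {
  li_result("AMI", spec_select_left, spec_select_right, montage, band)
}

#' Suppression lateralization index
#'
#' As [ami()], but contrasting the two distractor-lateral (front-cue)
#' conditions: `(P_suppress-left - P_suppress-right) /
#' (P_suppress-left + P_suppress-right)`.
#'
#' @param spec_suppress_left,spec_suppress_right Spectra of trials with the
#'   to-be-ignored lateral speaker on the left / right.
#' @inheritParams ami
#' @return A `lateralization_result`.
#' @export
li_suppression <- function(spec_suppress_left, spec_suppress_right, montage,
                           band = c(7, 13)) {
  li_result("LI_suppression", spec_suppress_left, spec_suppress_right,
            montage, band)
}

#' Hemisphere-specific alpha lateralization indices (ALI)
#'
#' For each hemisphere's occipito-parietal set, contrasts alpha power when
#' the lateral target is ipsilateral versus contralateral to that set:
#' `ALI_H = LI(P_H | target ipsi, P_H | target contra)`, band-averaged.
#' Positive values indicate the canonical ipsilateral alpha increase. The
#' two outputs are keyed by implant side so that `ali_ci_side` always refers
#' to the hemisphere over the implant.
#'
#' @param spec_target_left,spec_target_right Spectra of the two
#'   lateral-target (side-cue) conditions.
#' @param montage The montage.
#' @param ci_side Implant side, `"left"` or `"right"`.
#' @param band Frequency band (default `c(7, 13)`).
#' @return Named numeric vector `c(ali_ci_side =, ali_non_ci_side =)` with
#'   the per-hemisphere values attached as attribute `"by_hemisphere"`.
#' @export
ali_by_ci_side <- function(spec_target_left, spec_target_right, montage,
                           ci_side = c("right", "left"), band = c(7, 13)) {
  ci_side <- match.arg(ci_side)
  li_for_set <- function(set, ipsi_spec, contra_spec) {
    r <- li_result("ALI", ipsi_spec, contra_spec, montage, band,
                   sets = c(h = set))
    r$set_avg[["h"]]
  }
  ali_left <- li_for_set("op_left_12", spec_target_left, spec_target_right)
  ali_right <- li_for_set("op_right_12", spec_target_right, spec_target_left)
  by_h <- c(left = ali_left, right = ali_right)
  out <- c(ali_ci_side = by_h[[ci_side]],
           ali_non_ci_side = by_h[[setdiff(c("left", "right"), ci_side)]])
  attr(out, "by_hemisphere") <- by_h
  out
}

#' Tidy table of lateralization indices
#'
#' Flattens `lateralization_result`s into the long format consumed by the
#' repeated-measures machinery.
#'
#' @param results Named list of `lateralization_result` objects (names are
#'   free-form identifiers).
#' @param participant,session,ci_status Identifiers copied into the table.
#' @return Data frame with columns `participant`, `session`, `ci_status`,
#'   `index_kind`, `hemisphere_set`, `band_lo`, `band_hi`, `value`.
#' @export
lateralization_table <- function(results, participant = NA, session = NA,
                                 ci_status = NA) {
  rows <- lapply(results, function(r) {
    stopifnot(inherits(r, "lateralization_result"))
    data.frame(participant = participant, session = session,
               ci_status = ci_status, index_kind = r$index_kind,
               hemisphere_set = names(r$set_avg),
               band_lo = r$band_hz[1], band_hi = r$band_hz[2],
               value = unname(r$set_avg), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
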