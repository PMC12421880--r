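#' Decompose epochs into independent components
#'
#' Concatenates the retained trials, reduces dimensionality by PCA to the
#' smallest rank whose cumulative explained variance reaches `var_target`
#' (the 90\%-variance rule), and runs FastICA on the retained subspace.
#' Projecting the data through all components reproduces the PCA-retained
#' part of the data exactly.
#'
#' @param e An `eeg_epochs` with at least two retained trials.
#' @param var_target Cumulative PCA variance to retain, in (0, 1]
#'   (default 0.90).
#' @param method ICA contrast: `"logcosh"` (default) or `"kurtosis"`,
#'   passed to [ica::icafast()].
#' @param seed Integer seed for the ICA initialization; the PCA stage is
#'   deterministic.
#' @param maxit Maximum FastICA iterations.
#' @return An object of class `component_model`: list with `mixing`
#'   (channels x k), `unmixing` (k x channels), `center` (channel means),
#'   `var_explained` (per component, fraction of total variance), `k`,
#'   `pca_var_retained`, and `labels` (initialized to `NA`, see
#'   [classify_components()]).
#' @export
fit_components <- function(e, var_target = 0.90, method = c("logcosh",
                                                            "kurtosis"),
                           seed = 1, maxit = 200) {
  stopifnot(inherits(e, "eeg_epochs"), var_target > 0, var_target <= 1)
  method <- match.arg(method)
  good <- good_trials(e)
  if (length(good) < 2) stop("need at least 2 retained trials for ICA")
  n_ch <- dim(e$data)[2]
  n_smp <- dim(e$data)[3]
  X <- matrix(0, n_ch, length(good) * n_smp)
  for (j in seq_along(good)) {
    X[, (j - 1) * n_smp + seq_len(n_smp)] <- e$data[good[j], , , drop = TRUE]
  }
  center <- rowMeans(X)
  Xc <- X - center
  sv <- svd(Xc, nu = n_ch, nv = 0)
  ev <- sv$d^2
  tol <- max(ev) * 1e-10
  rank <- sum(ev > tol)
  cumvar <- cumsum(ev) / sum(ev)
  k <- which(cumvar >= var_target - 1e-12)[1]
  if (k > rank) {
    warning("rank-deficient data: reducing components from ", k, " to ", rank)
    k <- rank
  }
  U <- sv$u[, seq_len(k), drop = FALSE]
  Z <- t(U) %*% Xc                      # k x T scores
  if (k == 1) {
    mixing <- U
    unmixing <- t(U)
  } else {
    set.seed(seed)
    fit <- ica::icafast(t(Z), nc = k, center = TRUE, maxit = maxit,
                        fun = method)
    # icafast: scale(t(Z)) = S %*% t(M); map mixing back to channel space
    M <- fit$M                          # k x k, score-space mixing
    mixing <- U %*% M
    unmixing <- solve(M) %*% t(U)
  }
  src_var <- vapply(seq_len(k), function(j) {
    sum(mixing[, j]^2) * stats::var(as.numeric(unmixing[j, , drop = FALSE] %*% Xc))
  }, numeric(1))
  m <- list(mixing = mixing, unmixing = unmixing, center = center,
            var_explained = src_var / sum(ev / (ncol(Xc) - 1)),
            k = k, pca_var_retained = cumvar[k],
            labels = rep(NA_character_, k))
  class(m) <- "component_model"
  m
}

#' @export
print.component_model <- function(x, ...) {
  cat(sprintf("<component_model> %d components, %.1f%% variance retained\n",
              x$k, 100 * x$pca_var_retained))
  if (!all(is.na(x$labels))) print(table(x$labels, useNA = "ifany"))
  invisible(x)
}

# Per-component evoked diagnostics used by the classifier.
component_scores <- function(m, e, montage, ci_side) {
  good <- good_trials(e)
  n_smp <- dim(e$data)[3]
  t <- epoch_times(e)
  k <- m$k
  tc_evoked <- matrix(0, k, n_smp)
  trial_var <- matrix(0, length(good), k)
  spec_acc <- NULL
  for (j in seq_along(good)) {
    tc <- m$unmixing %*% e$data[good[j], , , drop = TRUE]   # k x samples
    tc_evoked <- tc_evoked + tc
    trial_var[j, ] <- apply(tc, 1, stats::var)
    p <- Mod(stats::mvfft(t(tc)))^2
    spec_acc <- if (is.null(spec_acc)) p else spec_acc + p
  }
  tc_evoked <- tc_evoked / length(good)
  fs <- e$fs_hz
  freqs <- (seq_len(n_smp) - 1) * fs / n_smp
  fsel <- freqs >= 2 & freqs <= 40
  slope <- vapply(seq_len(k), function(j) {
    lf <- log(freqs[fsel])
    lp <- log(spec_acc[fsel, j] + 1e-12)
    stats::coef(stats::lm(lp ~ lf))[2]
  }, numeric(1))

  post <- t >= 0 & t < 0.25
  latency <- vapply(seq_len(k), function(j) {
    seg <- abs(tc_evoked[j, post])
    t[post][which.max(seg)]
  }, numeric(1))
  evoked_ratio <- vapply(seq_len(k), function(j) {
    stats::var(tc_evoked[j, ]) / mean(trial_var[, j])
  }, numeric(1))
  # sound-evokedness: RMS of the averaged time course after onset relative
  # to the pre-stimulus baseline; ~1 for non-evoked components regardless of
  # trial count, large for onset-locked components
  base <- t < 0
  evk <- t >= 0 & t < 0.35
  onset_ratio <- vapply(seq_len(k), function(j) {
    sqrt(mean(tc_evoked[j, evk]^2) / (mean(tc_evoked[j, base]^2) + 1e-300))
  }, numeric(1))

  w <- abs(m$mixing)
  w <- sweep(w, 2, colSums(w), "/")
  set_frac <- function(set) {
    idx <- match(montage_set(montage, set), e$channel_names)
    colSums(w[idx, , drop = FALSE])
  }
  ci_set <- if (ci_side == "left") "temporal_left" else "temporal_right"
  data.frame(
    component = seq_len(k),
    latency_s = latency,
    evoked_ratio = evoked_ratio,
    onset_ratio = onset_ratio,
    ci_concentration = set_frac(ci_set),
    fc_concentration = set_frac("frontocentral_9"),
    frontal_concentration = {
      idx <- match(c("Fp1", "Fp2", "AF7", "AF3", "AF4", "AF8"),
                   e$channel_names)
      colSums(w[idx, , drop = FALSE])
    },
    spectral_slope = slope
  )
}

#' Default classifier thresholds
#'
#' Documented score thresholds for [classify_components()]. A component is
#' sound-evoked when the post-onset RMS of its trial-averaged time course
#' exceeds `onset_ratio` times the pre-stimulus baseline RMS; sound-evoked
#' components are split into CI artifact versus auditory by peak latency
#' (`ci_latency_s`) and by topographic weight concentration over the
#' implant-side temporal set versus the fronto-central set (fractions of
#' total absolute weight; the uniform baseline is set size / 64).
#' Non-evoked components with a steep negative log-log spectral slope are
#' brain activity; frontally concentrated components and everything else
#' are other artifacts. The thresholds were calibrated on synthetic
#' sessions and are exposed through the run configuration.
#'
#' @return Named list of thresholds.
#' @export
classifier_thresholds <- function() {
  list(onset_ratio = 3, ci_latency_s = 0.035, ci_concentration = 0.20,
       fc_concentration = 0.22, frontal_concentration = 0.45,
       brain_slope = -0.5)
}

#' Label independent components
#'
#' Scores every component on evoked peak latency, topographic concentration
#' and spectral shape (see [classifier_thresholds()]) and assigns one of the
#' labels `ci_artifact`, `auditory`, `brain_other`, `artifact_other`. The
#' visual-inspection step of a human analyst is replaced by these documented
#' score rules.
#'
#' @param m A `component_model` from [fit_components()].
#' @param e The `eeg_epochs` the model was fitted on (stimulus-locked, so
#'   evoked time courses are meaningful).
#' @param montage The montage.
#' @param ci_side Implant side, `"left"` or `"right"`.
#' @param thresholds Score thresholds, see [classifier_thresholds()].
#' @param require_auditory Error when no component qualifies as auditory
#'   (default `TRUE`; the pipeline cannot proceed without one).
#' @return The model with `labels` filled in and the score table attached as
#'   attribute `"scores"`.
#' @export
classify_components <- function(m, e, montage, ci_side = c("right", "left"),
                                thresholds = classifier_thresholds(),
                                require_auditory = TRUE) {
  ci_side <- match.arg(ci_side)
  sc <- component_scores(m, e, montage, ci_side)
  th <- thresholds
  labels <- rep("artifact_other", m$k)
  evoked <- sc$onset_ratio >= th$onset_ratio
  is_ci <- evoked & sc$latency_s <= th$ci_latency_s &
    sc$ci_concentration >= th$ci_concentration
  is_aud <- evoked & !is_ci & sc$latency_s > th$ci_latency_s &
    sc$fc_concentration >= th$fc_concentration
  labels[is_ci] <- "ci_artifact"
  labels[is_aud] <- "auditory"
  rest <- !is_ci & !is_aud
  is_blink <- rest & sc$frontal_concentration >= th$frontal_concentration
  is_brain <- rest & !is_blink & sc$spectral_slope <= th$brain_slope
  labels[is_brain] <- "brain_other"
  if (require_auditory && !any(labels == "auditory")) {
    stop("no auditory component found; cannot continue the evoked pipeline")
  }
  m$labels <- labels
  attr(m, "scores") <- cbind(sc, label = labels)
  m
}

#' Reconstruct epochs from a subset of components
#'
#' Projects the channel data onto the component subspace and reconstructs it
#' from the kept components only. `keep`/`reject` may be component indices
#' or label names. Keeping all components reproduces the PCA-retained data.
#'
#' @param e An `eeg_epochs`.
#' @param m A (classified) `component_model`.
#' @param keep Components to keep (indices or labels). Mutually exclusive
#'   with `reject`.
#' @param reject Components to remove (indices or labels).
#' @return Reconstructed `eeg_epochs`.
#' @export
project_components <- function(e, m, keep = NULL, reject = NULL) {
  stopifnot(inherits(e, "eeg_epochs"), inherits(m, "component_model"))
  if (is.null(keep) == is.null(reject)) {
    stop("specify exactly one of keep or reject")
  }
  as_idx <- function(x) {
    if (is.character(x)) which(m$labels %in% x) else as.integer(x)
  }
  idx <- if (!is.null(keep)) as_idx(keep) else {
    setdiff(seq_len(m$k), as_idx(reject))
  }
  if (length(idx) == 0) stop("empty component keep set")
  P <- m$mixing[, idx, drop = FALSE] %*% m$unmixing[idx, , drop = FALSE]
  d <- e$data
  for (i in seq_len(dim(d)[1])) {
    seg <- matrix(d[i, , ], dim(d)[2], dim(d)[3]) - m$center
    d[i, , ] <- P %*% seg + m$center
  }
  e$data <- d
  e
}
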