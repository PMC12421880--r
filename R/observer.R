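#' Simulated psychometric observer
#'
#' An observer stands in for the human listener when exercising the adaptive
#' procedures. Its probability of a correct response at stimulus level `x` is
#'
#' \deqn{p(x) = \gamma + (1 - \gamma - \lambda)\,
#'   \frac{1}{1 + e^{-\beta (x - \theta)}}}
#'
#' with guess rate \eqn{\gamma}, lapse rate \eqn{\lambda}, threshold
#' \eqn{\theta} (in task-level units) and slope \eqn{\beta} (1/level-unit).
#' The logistic link makes `p` monotone nondecreasing in `x - threshold`.
#'
#' @param kind Task type: `"threeAFC_amrd"` (modulation-rate discrimination,
#'   level = deviant-minus-standard AM-rate difference in Hz, guess 1/3),
#'   `"speech_srt"` (two-talker number report, level = SNR in dB, guess 1/9
#'   for the nine-alternative set), or `"detection"` (level = dB SPL,
#'   guess 0).
#' @param threshold Psychometric midpoint \eqn{\theta}, level units.
#' @param slope Logistic slope \eqn{\beta}, 1/level-units (> 0).
#' @param guess Lower asymptote \eqn{\gamma}; defaults per `kind`.
#' @param lapse Upper-asymptote deficit \eqn{\lambda} (default 0).
#' @return Object of class `observer_model`.
#' @examples
#' obs <- observer("threeAFC_amrd", threshold = 1, slope = 8)
#' psychometric_p(obs, c(0.5, 1, 2))
#' @export
observer <- function(kind = c("threeAFC_amrd", "speech_srt", "detection"),
                     threshold, slope, guess = NULL, lapse = 0) {
  kind <- match.arg(kind)
  if (is.null(guess)) {
    guess <- switch(kind, threeAFC_amrd = 1 / 3, speech_srt = 1 / 9,
                    detection = 0)
  }
  stopifnot(is.finite(threshold), slope > 0, lapse >= 0)
  if (!(guess >= 0 && guess < 1 - lapse && 1 - lapse <= 1)) {
    stop("observer requires 0 <= guess < 1 - lapse <= 1")
  }
  structure(list(kind = kind, threshold = threshold, slope = slope,
                 guess = guess, lapse = lapse),
            class = "observer_model")
}

#' Probability correct of an observer at a stimulus level
#'
#' @param obs An `observer_model`.
#' @param level Stimulus level(s), task units.
#' @return Probability correct, same length as `level`.
#' @export
psychometric_p <- function(obs, level) {
  stopifnot(inherits(obs, "observer_model"), all(is.finite(level)))
  obs$guess + (1 - obs$guess - obs$lapse) /
    (1 + exp(-obs$slope * (level - obs$threshold)))
}

#' Level at which an observer reaches a given probability correct
#'
#' Inverse of [psychometric_p()]; the independent reference for staircase
#' convergence points (e.g. the 70.7\% level of a 2-down-1-up track).
#'
#' @param obs An `observer_model`.
#' @param p Target probability correct, must lie strictly between `guess`
#'   and `1 - lapse`.
#' @return Stimulus level, task units.
#' @export
psychometric_q <- function(obs, p) {
  stopifnot(p > obs$guess, p < 1 - obs$lapse)
  f <- (p - obs$guess) / (1 - obs$guess - obs$lapse)
  obs$threshold + log(f / (1 - f)) / obs$slope
}

#' Draw one Bernoulli response from an observer
#'
#' Uses the current R random stream; seed with [set.seed()] (or let the
#' calling procedure manage seeding) for reproducible response streams.
#'
#' @param obs An `observer_model`.
#' @param level Stimulus level, task units (finite).
#' @return Logical: `TRUE` = correct.
#' @export
observer_respond <- function(obs, level) {
  stopifnot(is.finite(level))
  stats::runif(1) < psychometric_p(obs, level)
}
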