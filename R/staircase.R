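# Adaptive psychophysical procedures: the 2-down-1-up AM-rate discrimination
# staircase, the interleaved blockwise 1-down-1-up speech SNR tracking, and
# the method-of-limits detection threshold.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  expr
}

#' Configuration of the AM-rate discrimination staircase
#'
#' Defaults implement the modulation-rate difference task: the deviant starts
#' at a 2-Hz difference from the 4-Hz standard (i.e. 6 Hz), moves in 0.5-Hz
#' steps until the fourth reversal and 0.25-Hz steps after, terminates at the
#' tenth reversal, and the threshold is the mean difference over the last six
#' reversals. The deviant cannot reach the standard: the difference is
#' clamped to `[0.25, 2]` Hz.
#'
#' @param start_level Starting deviant-minus-standard difference, Hz.
#' @param step_initial,step_final Step sizes, Hz.
#' @param reversals_step_change Reversal count after which the step shrinks.
#' @param reversals_stop Total reversals at termination.
#' @param threshold_reversals Number of final reversals averaged into the
#'   threshold (inclusive of the terminating reversal).
#' @param level_bounds Allowed difference range, Hz.
#' @param max_trials Trial cap guarding against non-termination.
#' @return Named list of class `staircase_config`.
#' @export
amrd_config <- function(start_level = 2.0, step_initial = 0.5,
                        step_final = 0.25, reversals_step_change = 4,
                        reversals_stop = 10, threshold_reversals = 6,
                        level_bounds = c(0.25, 2.0), max_trials = 400) {
  stopifnot(start_level > 0, start_level <= level_bounds[2],
            threshold_reversals <= reversals_stop)
  structure(as.list(environment()), class = "staircase_config")
}

#' Run one 2-down-1-up AM-rate discrimination staircase
#'
#' Transformed up-down rule converging on the 70.7\% point of the
#' psychometric function: the level decreases only after two consecutive
#' correct responses (the correct counter resets after every level change)
#' and increases after each incorrect response. A reversal is a trial at
#' which the prescribed step direction changes relative to the previous
#' prescribed direction; the threshold is the mean level over the last
#' `threshold_reversals` reversal levels.
#'
#' @param obs An [observer()] whose level unit is the deviant-minus-standard
#'   AM-rate difference in Hz (3-AFC, guess 1/3).
#' @param config An [amrd_config()].
#' @param seed Integer seed; the trace replays deterministically from
#'   `(config, seed)`.
#' @return Object of class `staircase_trace`: list with `trials` (data frame
#'   `trial`, `level`, `correct`, `is_reversal`, `step_size`),
#'   `reversal_levels`, `threshold`, and the `config` echo.
#' @export
amrd_run <- function(obs, config = amrd_config(), seed = 1) {
  stopifnot(inherits(obs, "observer_model"),
            inherits(config, "staircase_config"))
  with_seed(seed, {
    level <- config$start_level
    step <- config$step_initial
    streak <- 0L
    last_dir <- 0L
    rev_levels <- numeric(0)
    rows <- vector("list", config$max_trials)
    for (tr in seq_len(config$max_trials)) {
      correct <- observer_respond(obs, level)
      dir <- 0L
      if (correct) {
        streak <- streak + 1L
        if (streak == 2L) { dir <- -1L; streak <- 0L }
      } else {
        dir <- +1L
        streak <- 0L
      }
      is_rev <- dir != 0L && last_dir != 0L && dir != last_dir
      rows[[tr]] <- data.frame(trial = tr, level = level, correct = correct,
                               is_reversal = is_rev, step_size = step)
      if (is_rev) {
        rev_levels <- c(rev_levels, level)
        if (length(rev_levels) == config$reversals_step_change) {
          step <- config$step_final
        }
        if (length(rev_levels) >= config$reversals_stop) break
      }
      if (dir != 0L) {
        last_dir <- dir
        level <- min(max(level + dir * step, config$level_bounds[1]),
                     config$level_bounds[2])
      }
    }
    if (length(rev_levels) < config$reversals_stop) {
      stop("staircase did not terminate within ", config$max_trials,
           " trials (", length(rev_levels), " reversals); partial trace: ",
           nrow(do.call(rbind, rows[!vapply(rows, is.null, logical(1))])),
           " trials")
    }
    k <- config$threshold_reversals
    thr <- mean(utils::tail(rev_levels, k))
    structure(list(trials = do.call(rbind, rows[seq_len(tr)]),
                   reversal_levels = rev_levels, threshold = thr,
                   config = config, seed = seed),
              class = "staircase_trace")
  })
}

#' @export
print.staircase_trace <- function(x, ...) {
  cat(sprintf("<staircase_trace> %d trials, %d reversals, threshold = %.3f\n",
              nrow(x$trials), length(x$reversal_levels), x$threshold))
  invisible(x)
}

#' Combine the two AM-rate discrimination runs
#'
#' The task is administered twice; the minimum of the two thresholds is the
#' participant's value.
#'
#' @param t1,t2 Thresholds (Hz) of the two runs.
#' @return `min(t1, t2)`.
#' @export
amrd_threshold_from_runs <- function(t1, t2) {
  stopifnot(is.finite(t1), is.finite(t2))
  min(t1, t2)
}

#' Batch of AM-rate discrimination staircases
#'
#' @param obs An [observer()].
#' @param n_runs Number of independent runs.
#' @param config An [amrd_config()].
#' @param seed Base seed; run `i` uses `seed + i`.
#' @return Data frame with columns `run`, `threshold`, `n_trials`.
#' @export
amrd_batch <- function(obs, n_runs, config = amrd_config(), seed = 1) {
  rows <- lapply(seq_len(n_runs), function(i) {
    tr <- amrd_run(obs, config, seed = seed + i)
    data.frame(run = i, threshold = tr$threshold, n_trials = nrow(tr$trials))
  })
  do.call(rbind, rows)
}

#' Simulate one interleaved 1-down-1-up speech-in-noise session
#'
#' Runs the blockwise spatial listening session against simulated observers:
#' each of the four conditions keeps its own SNR track starting at
#' `start_snr_db`, lowered by `step_db` after a correct response and raised
#' by `step_db` after an incorrect one; only the two conditions of the
#' block's speaker setup are titrated within a block. The speech reception
#' threshold (SRT) of a condition is the mean SNR over all its trials except
#' those of the first block in which the condition occurred, and is flagged
#' invalid above `invalid_above_db`.
#'
#' @param observers A single [observer()] (level = SNR in dB) used for all
#'   conditions, or a named list with one observer per condition label.
#' @param design An [attention_design()].
#' @param seed Integer seed.
#' @param start_snr_db Starting SNR (default +10 dB).
#' @param step_db Step size (default 2 dB).
#' @param snr_bounds Track clamp (default `c(-40, 40)` dB).
#' @param invalid_above_db SRT validity limit (default +40 dB).
#' @return Object of class `srt_result`: list with `srt` (data frame
#'   `condition`, `srt_db`, `n_included`, `first_block`, `valid`) and
#'   `trace` (per-trial data frame `trial`, `block`, `condition`, `snr_db`,
#'   `correct`).
#' @export
srt_session <- function(observers, design, seed = 1, start_snr_db = 10,
                        step_db = 2, snr_bounds = c(-40, 40),
                        invalid_above_db = 40) {
  stopifnot(inherits(design, "attention_design"))
  trials <- design$trials
  conds <- sort(unique(trials$condition))
  if (inherits(observers, "observer_model")) {
    observers <- stats::setNames(rep(list(observers), length(conds)), conds)
  }
  if (!all(conds %in% names(observers))) {
    stop("missing observer for condition(s): ",
         paste(setdiff(conds, names(observers)), collapse = ", "))
  }
  with_seed(seed, {
    snr <- stats::setNames(rep(start_snr_db, length(conds)), conds)
    n <- nrow(trials)
    level <- numeric(n)
    correct <- logical(n)
    for (i in seq_len(n)) {
      cond <- trials$condition[i]
      level[i] <- snr[[cond]]
      correct[i] <- observer_respond(observers[[cond]], level[i])
      delta <- if (correct[i]) -step_db else step_db
      snr[[cond]] <- min(max(snr[[cond]] + delta, snr_bounds[1]),
                         snr_bounds[2])
    }
    trace <- data.frame(trial = trials$trial, block = trials$block,
                        condition = trials$condition, snr_db = level,
                        correct = correct)
    srt <- do.call(rbind, lapply(conds, function(cond) {
      rows <- trace[trace$condition == cond, ]
      if (nrow(rows) == 0) stop("condition never run: ", cond)
      fb <- min(rows$block)
      inc <- rows[rows$block > fb, ]
      if (nrow(inc) == 0) stop("condition '", cond,
                               "' occurs only in its first block")
      s <- mean(inc$snr_db)
      data.frame(condition = cond, srt_db = s, n_included = nrow(inc),
                 first_block = fb, valid = s <= invalid_above_db)
    }))
    structure(list(srt = srt, trace = trace, seed = seed), class = "srt_result")
  })
}

#' @export
print.srt_result <- function(x, ...) {
  cat("<srt_result>\n")
  print(x$srt, row.names = FALSE)
  invisible(x)
}

#' Cochlear-implant benefit from paired sessions
#'
#' `benefit = SRT(CI on) - SRT(CI off)` per condition; negative values mean
#' better (lower) thresholds with the implant active. The participant is
#' flagged for exclusion when any condition's SRT exceeds +40 dB in either
#' recording.
#'
#' @param srt_on,srt_off `srt_result`s of the CI-on and CI-off runs.
#' @return Data frame `condition`, `srt_on`, `srt_off`, `benefit_db`, with
#'   attribute `"excluded"` (logical).
#' @export
ci_benefit <- function(srt_on, srt_off) {
  stopifnot(inherits(srt_on, "srt_result"), inherits(srt_off, "srt_result"))
  a <- srt_on$srt
  b <- srt_off$srt
  if (!setequal(a$condition, b$condition)) {
    stop("condition sets of the two recordings differ")
  }
  b <- b[match(a$condition, b$condition), ]
  out <- data.frame(condition = a$condition, srt_on = a$srt_db,
                    srt_off = b$srt_db, benefit_db = a$srt_db - b$srt_db)
  attr(out, "excluded") <- any(!a$valid) || any(!b$valid)
  out
}

#' Detection threshold by the method of limits
#'
#' Simulates ascending runs (level raised in `step_db` steps from well below
#' the observer's detection point until a detection response) and descending
#' runs (lowered from well above until detection is lost). The ascending
#' score is the first detected level; the descending score is the lowest
#' level still detected (one step above the first miss), so a noiseless
#' observer yields identical scores in both directions. The threshold is the
#' mean over the last two ascending and last two descending run scores.
#'
#' @param obs A `"detection"` [observer()]; level unit dB.
#' @param n_ascending,n_descending Number of runs per direction (default 3).
#' @param step_db Step size, dB (default 1).
#' @param start_offset_db Starting distance from the observer threshold, dB
#'   (default 15).
#' @param seed Integer seed.
#' @param max_steps Step cap per run; a run that never elicits a response
#'   event within the cap is an error.
#' @return List of class `mol_result`: `threshold`, `ascending_scores`,
#'   `descending_scores`.
#' @export
method_of_limits <- function(obs, n_ascending = 3, n_descending = 3,
                             step_db = 1, start_offset_db = 15, seed = 1,
                             max_steps = 200) {
  stopifnot(inherits(obs, "observer_model"))
  with_seed(seed, {
    run <- function(direction) {
      level <- obs$threshold - direction * start_offset_db
      for (s in seq_len(max_steps)) {
        heard <- observer_respond(obs, level)
        if (direction > 0 && heard) return(level)
        if (direction < 0 && !heard) return(level + step_db)
        level <- level + direction * step_db
      }
      stop("method-of-limits run produced no response event within ",
           max_steps, " steps")
    }
    asc <- vapply(seq_len(n_ascending), function(i) run(+1), numeric(1))
    desc <- vapply(seq_len(n_descending), function(i) run(-1), numeric(1))
    structure(list(threshold = mol_threshold_from_scores(asc, desc),
                   ascending_scores = asc, descending_scores = desc),
              class = "mol_result")
  })
}

#' Method-of-limits threshold estimator
#'
#' The mean over the last two ascending and the last two descending run
#' scores (four values).
#'
#' @param ascending_scores,descending_scores Run scores, dB, in run order;
#'   at least two per direction.
#' @return Threshold, dB.
#' @export
mol_threshold_from_scores <- function(ascending_scores, descending_scores) {
  stopifnot(length(ascending_scores) >= 2, length(descending_scores) >= 2)
  mean(c(utils::tail(ascending_scores, 2), utils::tail(descending_scores, 2)))
}
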