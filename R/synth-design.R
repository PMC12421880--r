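#' Design of a passive amplitude-modulated tone session
#'
#' Builds the trial list of the passive listening experiment: `n_per_rate`
#' tones per amplitude-modulation (AM) rate in pseudo-random order with no
#' more than `max_run` consecutive tones of the same rate, and inter-stimulus
#' intervals jittered on a 0.1-s grid. The defaults reproduce the study
#' conditions: 60 tones per rate at 4, 20 and 40 Hz (180 tones total), 2-s
#' tones, ISI 0.5-1.5 s.
#'
#' @param n_per_rate Trials per AM rate (default 60).
#' @param am_rates_hz AM rates in Hz (default `c(4, 20, 40)`).
#' @param tone_dur_s Tone duration, seconds (default 2).
#' @param isi_range_s Inter-stimulus interval range, seconds (default
#'   `c(0.5, 1.5)`); ISIs are drawn uniformly from the 0.1-s grid spanning
#'   this range.
#' @param max_run Maximum run of identical consecutive AM rates (default 3).
#' @param seed Integer seed; the trial order and ISIs are deterministic
#'   given the seed.
#' @return An object of class `passive_design`: a list with a `trials` data
#'   frame (`trial`, `am_rate`, `isi_s`) and the design parameters.
#' @export
passive_design <- function(n_per_rate = 60, am_rates_hz = c(4, 20, 40),
                           tone_dur_s = 2, isi_range_s = c(0.5, 1.5),
                           max_run = 3, seed = 1) {
  stopifnot(n_per_rate >= 1, length(am_rates_hz) >= 1, max_run >= 1)
  k <- length(am_rates_hz)
  n_total <- n_per_rate * k
  # feasibility: the most frequent rate must be interleavable
  if (k > 1 && n_per_rate > (n_total - n_per_rate + 1) * max_run) {
    stop("design infeasible: n_per_rate = ", n_per_rate,
         " cannot be sequenced with max_run = ", max_run)
  }
  if (k == 1 && n_per_rate > max_run) {
    stop("design infeasible: a single AM rate cannot satisfy max_run = ",
         max_run)
  }
  rng <- local_rng(seed)
  seq_rates <- constrained_sequence(rep(n_per_rate, k), max_run, rng)
  isi_grid <- seq(isi_range_s[1], isi_range_s[2], by = 0.1)
  isi <- isi_grid[rng$int(n_total, length(isi_grid))]
  structure(
    list(trials = data.frame(trial = seq_len(n_total),
                             am_rate = am_rates_hz[seq_rates],
                             isi_s = isi),
         n_per_rate = n_per_rate, am_rates_hz = am_rates_hz,
         tone_dur_s = tone_dur_s, isi_range_s = isi_range_s,
         max_run = max_run, seed = seed),
    class = "passive_design"
  )
}

# Draw a sequence with given per-symbol counts and maximum run length.
# Sequential sampling proportional to remaining counts among symbols that do
# not extend a maximal run; restarts on a dead end (rare), capped.
constrained_sequence <- function(counts, max_run, rng) {
  k <- length(counts)
  for (attempt in 1:1000) {
    rem <- counts
    out <- integer(sum(counts))
    run_sym <- 0L; run_len <- 0L
    ok <- TRUE
    for (i in seq_along(out)) {
      allowed <- which(rem > 0)
      if (run_len >= max_run) allowed <- setdiff(allowed, run_sym)
      if (length(allowed) == 0) { ok <- FALSE; break }
      p <- rem[allowed] / sum(rem[allowed])
      sym <- if (length(allowed) == 1) allowed else {
        allowed[findInterval(rng$unif(1), cumsum(p)) + 1L]
      }
      out[i] <- sym
      rem[sym] <- rem[sym] - 1L
      if (sym == run_sym) run_len <- run_len + 1L else {
        run_sym <- sym; run_len <- 1L
      }
    }
    if (ok) return(out)
  }
  stop("could not sequence the design within the restart cap")
}

#' Design of the auditory spatial attention session
#'
#' Builds the blocked trial table of the spatial listening task. One
#' loudspeaker is always frontal; the lateral loudspeaker alternates between
#' left and right block-wise, starting on the left for listeners with a
#' right-ear CI and vice versa. Each block mixes side-cue trials (attend the
#' lateral speaker, i.e. *select* it) and front-cue trials (attend the front
#' speaker, i.e. *suppress* the lateral one) in random order. The defaults
#' give the study session: 6 blocks of 50 trials (25 front cues + 25 side
#' cues), 300 trials, 75 per condition.
#'
#' Condition labels are relative to the implanted ear:
#' `select_ci`, `suppress_ci`, `select_nonci`, `suppress_nonci`.
#'
#' @param n_blocks Number of blocks (default 6).
#' @param trials_per_block Trials per block (default 50).
#' @param cue_front_per_block,cue_side_per_block Front-cue and side-cue
#'   trials per block (defaults 25 each).
#' @param ci_side Side of the cochlear implant, `"left"` or `"right"`.
#' @param cue_dur_s Visual cue duration, seconds (default 0.5).
#' @param anticipation_range_s Cue-to-sound anticipation period range,
#'   seconds, jittered on a 0.1-s grid (default `c(1.0, 1.8)`).
#' @param number_dur_s Spoken-number duration, seconds (default 0.5).
#' @param seed Integer seed.
#' @return An object of class `attention_design`: list with a `trials` data
#'   frame (`trial`, `block`, `cue`, `side_speaker`, `target_side`,
#'   `distractor_side`, `condition`, `anticipation_s`) and parameters.
#' @export
attention_design <- function(n_blocks = 6, trials_per_block = 50,
                             cue_front_per_block = 25,
                             cue_side_per_block = 25,
                             ci_side = c("left", "right"),
                             cue_dur_s = 0.5,
                             anticipation_range_s = c(1.0, 1.8),
                             number_dur_s = 0.5, seed = 1) {
  ci_side <- match.arg(ci_side)
  if (cue_front_per_block + cue_side_per_block != trials_per_block) {
    stop("cue_front_per_block + cue_side_per_block must equal trials_per_block")
  }
  if (cue_front_per_block < 1 || cue_side_per_block < 1 || n_blocks < 2) {
    stop("design error: every condition needs at least one trial")
  }
  if (n_blocks %% 2 != 0) {
    stop("design error: n_blocks must be even so both lateral setups occur equally often")
  }
  rng <- local_rng(seed)
  # lateral speaker alternates; first block lateral speaker is opposite the CI
  first_side <- if (ci_side == "right") "left" else "right"
  other_side <- setdiff(c("left", "right"), first_side)
  block_side <- rep(c(first_side, other_side), length.out = n_blocks)

  ant_grid <- seq(anticipation_range_s[1], anticipation_range_s[2], by = 0.1)
  rows <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    cue <- c(rep("side", cue_side_per_block), rep("front", cue_front_per_block))
    cue <- cue[rng$perm(length(cue))]
    side <- block_side[b]
    target <- ifelse(cue == "side", side, "front")
    distract <- ifelse(cue == "side", "front", side)
    role <- ifelse(cue == "side", "select", "suppress")
    ear <- ifelse(side == ci_side, "ci", "nonci")
    rows[[b]] <- data.frame(
      block = b, cue = cue, side_speaker = side,
      target_side = target, distractor_side = distract,
      condition = paste(role, ear, sep = "_"),
      anticipation_s = ant_grid[rng$int(trials_per_block, length(ant_grid))],
      stringsAsFactors = FALSE
    )
  }
  trials <- do.call(rbind, rows)
  trials <- cbind(trial = seq_len(nrow(trials)), trials)
  structure(
    list(trials = trials, n_blocks = n_blocks,
         trials_per_block = trials_per_block,
         cue_front_per_block = cue_front_per_block,
         cue_side_per_block = cue_side_per_block,
         ci_side = ci_side, cue_dur_s = cue_dur_s,
         anticipation_range_s = anticipation_range_s,
         number_dur_s = number_dur_s, seed = seed),
    class = "attention_design"
  )
}

#' Longest run of identical values
#'
#' Utility used to verify sequencing constraints.
#' @param x Atomic vector.
#' @return Length of the longest run.
#' @export
longest_run <- function(x) {
  if (length(x) == 0) return(0L)
  max(rle(as.character(x))$lengths)
}

# Small deterministic RNG scope: draws come from R's RNG seeded locally
# without disturbing the caller's RNG state.
local_rng <- function(seed) {
  env <- new.env()
  env$state <- {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    s
  }
  with_state <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    })
    f()
  }
  list(
    unif = function(n) with_state(function() runif(n)),
    norm = function(n) with_state(function() rnorm(n)),
    int = function(n, k) with_state(function() sample.int(k, n, replace = TRUE)),
    perm = function(n) with_state(function() sample.int(n)),
    pois = function(n, lambda) with_state(function() rpois(n, lambda))
  )
}
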