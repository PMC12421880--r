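test_that("the 2-down-1-up staircase follows its stop rule and replays deterministically", {
  obs <- observer("threeAFC_amrd", threshold = 1, slope = 8)
  for (seed in 1:10) {
    tr <- amrd_run(obs, seed = seed)
    expect_equal(length(tr$reversal_levels), 10)
    expect_equal(sum(tr$trials$is_reversal), 10)
    expect_true(all(tr$trials$level >= 0.25 & tr$trials$level <= 2))
    # step schedule: 0.5 until the 4th reversal, then 0.25
    expect_true(all(tr$trials$step_size %in% c(0.5, 0.25)))
  }
  # deterministic replay from (config, seed)
  expect_identical(amrd_run(obs, seed = 3)$trials, amrd_run(obs, seed = 3)$trials)
  # threshold is the mean of the last six reversal levels
  tr <- amrd_run(obs, seed = 5)
  expect_equal(tr$threshold, mean(utils::tail(tr$reversal_levels, 6)))
})

test_that("a near-perfect observer drives the track to the lower bound", {
  obs <- observer("threeAFC_amrd", threshold = -10, slope = 2, lapse = 0.03)
  tr <- amrd_run(obs, seed = 2)
  # monotone nonincreasing until the first incorrect response
  first_bad <- which(!tr$trials$correct)[1]
  expect_true(all(diff(tr$trials$level[seq_len(first_bad)]) <= 0))
  expect_equal(min(tr$trials$level), 0.25)
  expect_lte(tr$threshold, 0.25 + 2 * 0.5)
  # an observer that is always correct never reverses: capped with an error
  perfect <- observer("threeAFC_amrd", threshold = -100, slope = 5)
  expect_error(amrd_run(perfect, seed = 1), "did not terminate")
})

test_that("staircase thresholds sit at the 70.7% point for a steep observer", {
  obs <- observer("threeAFC_amrd", threshold = 1, slope = 8)
  b <- amrd_batch(obs, 300, seed = 40)
  p_at_mean <- psychometric_p(obs, mean(b$threshold))
  expect_lt(abs(p_at_mean - 0.707), 0.03)
})

test_that("the participant threshold is the minimum of two runs", {
  expect_equal(amrd_threshold_from_runs(0.5, 0.75), 0.5)
  expect_equal(amrd_threshold_from_runs(0.3, 0.3), 0.3)
  # min of two runs is stochastically no larger than a single run
  obs <- observer("threeAFC_amrd", threshold = 1, slope = 8)
  b <- amrd_batch(obs, 200, seed = 60)
  pairs <- matrix(b$threshold, ncol = 2)
  expect_lte(mean(pmin(pairs[, 1], pairs[, 2])), mean(pairs[, 1]))
})

test_that("interleaved SRT tracking oscillates around a deterministic threshold", {
  des <- attention_design(ci_side = "right", seed = 1)
  # deterministic observer: correct iff SNR >= -3 (steep logistic)
  obs <- observer("speech_srt", threshold = -3, slope = 1000, guess = 0)
  s <- srt_session(obs, des, seed = 1)
  expect_equal(nrow(s$trace), 300)
  expect_equal(as.vector(table(s$trace$condition)), rep(75L, 4))
  late <- s$trace[s$trace$block > 2, ]
  expect_true(all(abs(late$snr_db - (-3)) <= 3))
  expect_true(all(abs(s$srt$srt_db - (-3)) <= 2))
  # SRT excludes the first block of each condition
  for (cond in s$srt$condition) {
    rows <- s$trace[s$trace$condition == cond, ]
    fb <- min(rows$block)
    expect_equal(s$srt$srt_db[s$srt$condition == cond],
                 mean(rows$snr_db[rows$block > fb]))
    expect_equal(s$srt$n_included[s$srt$condition == cond], 50)
  }
})

test_that("SRT estimates target the 50% point of a probabilistic observer", {
  des <- attention_design(ci_side = "right", seed = 1)
  obs <- observer("speech_srt", threshold = -2, slope = 0.5)
  srts <- vapply(1:200, function(i) {
    mean(srt_session(obs, des, seed = 500 + i)$srt$srt_db)
  }, numeric(1))
  expect_lt(abs(psychometric_p(obs, mean(srts)) - 0.50), 0.03)
})

test_that("CI benefit subtracts on-minus-off and applies the validity rule", {
  des <- attention_design(ci_side = "right", seed = 1)
  obs_good <- observer("speech_srt", threshold = -5, slope = 1000, guess = 0)
  on <- srt_session(obs_good, des, seed = 2)
  off <- srt_session(obs_good, des, seed = 3)
  # identical observers: benefit near zero everywhere
  ben <- ci_benefit(on, off)
  expect_true(all(abs(ben$benefit_db) < 1))
  expect_false(attr(ben, "excluded"))
  # hand case via doctored results
  on2 <- on; off2 <- off
  on2$srt$srt_db[] <- -5
  off2$srt$srt_db[] <- 3
  expect_equal(unique(ci_benefit(on2, off2)$benefit_db), -8)
  # any SRT above +40 dB flags the participant
  off3 <- off
  off3$srt$srt_db[1] <- 41
  off3$srt$valid[1] <- FALSE
  expect_true(attr(ci_benefit(on, off3), "excluded"))
})

test_that("method of limits averages the last two runs per direction", {
  expect_equal(mol_threshold_from_scores(c(10, 11, 12), c(8, 9, 10)), 10.5)
  # steep observer: threshold recovered to within one step
  obs <- observer("detection", threshold = 23.3, slope = 1000)
  r <- method_of_limits(obs, seed = 1)
  expect_lte(abs(r$threshold - 23.3), 1)
  # translation equivariance
  obs2 <- observer("detection", threshold = 23.3 + 6, slope = 1000)
  r2 <- method_of_limits(obs2, seed = 1)
  expect_equal(r2$threshold - r$threshold, 6, tolerance = 1e-9)
})

test_that("up-down rules converge on their nominal percent-correct points", {
  # 2-down-1-up: empirical p(correct) at visited levels late in the track
  obs <- observer("threeAFC_amrd", threshold = 1, slope = 8)
  lv <- unlist(lapply(1:150, function(i) {
    tr <- amrd_run(obs, seed = 900 + i)$trials
    utils::tail(tr$level, 15)
  }))
  expect_lt(abs(mean(psychometric_p(obs, lv)) - 0.707), 0.03)
  # 1-down-1-up
  des <- attention_design(ci_side = "right", seed = 1)
  obs2 <- observer("speech_srt", threshold = -2, slope = 0.5)
  lv2 <- unlist(lapply(1:30, function(i) {
    tr <- srt_session(obs2, des, seed = 700 + i)$trace
    tr$snr_db[tr$block > 2]
  }))
  expect_lt(abs(mean(psychometric_p(obs2, lv2)) - 0.50), 0.03)
})
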