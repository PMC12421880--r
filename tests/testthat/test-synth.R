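test_that("passive design obeys counts, run-length and ISI grid constraints", {
  des <- passive_design(seed = 4)                 # full study defaults
  expect_equal(nrow(des$trials), 180)
  expect_equal(as.vector(table(des$trials$am_rate)), rep(60L, 3))
  expect_lte(longest_run(des$trials$am_rate), 3)
  expect_true(all(des$trials$isi_s >= 0.5 & des$trials$isi_s <= 1.5))
  # ISIs on the 0.1 s grid
  expect_equal(des$trials$isi_s, round(des$trials$isi_s, 1))
  # run-length property over many seeds
  for (s in 1:20) {
    d <- passive_design(n_per_rate = 15, max_run = 3, seed = s)
    expect_lte(longest_run(d$trials$am_rate), 3)
    expect_equal(as.vector(table(d$trials$am_rate)), rep(15L, 3))
  }
  expect_error(passive_design(n_per_rate = 10, am_rates_hz = 4, max_run = 3),
               "infeasible")
})

test_that("attention design balances conditions and alternates the setup", {
  des <- attention_design(ci_side = "right", seed = 2)  # study defaults
  tr <- des$trials
  expect_equal(nrow(tr), 300)
  expect_equal(as.vector(table(tr$condition)), rep(75L, 4))
  # lateral speaker alternates block-wise, starting opposite the implant
  side_by_block <- tapply(tr$side_speaker, tr$block, unique)
  expect_equal(as.character(unlist(side_by_block)),
               rep(c("left", "right"), 3))
  des_l <- attention_design(ci_side = "left", seed = 2)
  expect_equal(unique(des_l$trials$side_speaker[des_l$trials$block == 1]),
               "right")
  # anticipation jitter on the 0.1 s grid within range
  expect_true(all(tr$anticipation_s >= 1.0 & tr$anticipation_s <= 1.8))
  expect_equal(tr$anticipation_s, round(tr$anticipation_s, 1))
  expect_error(attention_design(trials_per_block = 50,
                                cue_front_per_block = 50,
                                cue_side_per_block = 0),
               "at least one trial")
})

test_that("sessions are bit-identical under identical seeds", {
  a <- small_passive(seed = 9, n_per_rate = 3)
  b <- small_passive(seed = 9, n_per_rate = 3)
  expect_identical(a$data, b$data)
  expect_identical(a$events, b$events)
  s1 <- small_attention(seed = 5, trials_per_block = 4)$session
  s2 <- small_attention(seed = 5, trials_per_block = 4)$session
  expect_identical(s1$data, s2$data)
})

test_that("noise-free synthesis injects the exact deterministic waveform", {
  cp <- clean_passive(ci_artifact_amp = 0)
  e <- epoch_data(cp$session, c(-0.5, 2.5))
  expect_equal(length(good_trials(e)), nrow(cp$design$trials))
  erp <- compute_erp(e, "40")
  w <- passive_source_waveform(cp$params, 40, epoch_times(e))
  # ERP at every channel equals the source scaled by its topography weight
  fcz <- match("FCz", test_montage$name)
  ratio <- erp$data[fcz, which.max(abs(w))] / max(abs(w)) * sign(w[which.max(abs(w))])
  expect_equal(erp$data[fcz, ], ratio * w, tolerance = 1e-9)
})

test_that("evoked spectrum of noise-free sessions peaks exactly at the AM rate and scales as amplitude squared", {
  cp <- clean_passive(ci_artifact_amp = 0)
  e <- epoch_data(cp$session, c(-0.5, 2.5))
  for (rate in c(4, 20, 40)) {
    sp <- evoked_spectrum(compute_erp(e, as.character(rate)))
    fc <- spectrum_set_average(sp, test_montage, "frontocentral_9")
    expect_equal(sp$freqs_hz[which.max(fc)], rate)
  }
  # amplitude doubling quadruples peak power
  des <- cp$design
  p2 <- neural_sim_params(fs_hz = 250, noise_1f_amp = 0, blink_rate_hz = 0,
                          ci_artifact_amp = 0,
                          assr_amp_per_rate = c(`4` = 1.5, `20` = 0.8,
                                                `40` = 2.0),
                          seed = 101)
  x2 <- generate_passive_session(des, p2, test_montage, ci_side = "right")
  sp1 <- evoked_spectrum(compute_erp(epoch_data(cp$session, c(-0.5, 2.5)),
                                     "40"))
  sp2 <- evoked_spectrum(compute_erp(epoch_data(x2, c(-0.5, 2.5)), "40"))
  a1 <- spectrum_set_average(sp1, test_montage, "frontocentral_9")[40]
  a2 <- spectrum_set_average(sp2, test_montage, "frontocentral_9")[40]
  expect_equal(a2 / a1, 4, tolerance = 0.01)
})

test_that("CI artifact topography centers on the configured implant side", {
  for (side in c("left", "right")) {
    des <- passive_design(n_per_rate = 2, seed = 1)
    pars <- neural_sim_params(fs_hz = 250, noise_1f_amp = 0,
                              blink_rate_hz = 0, seed = 1)
    x <- generate_passive_session(des, pars, test_montage, ci_side = side)
    # center of mass of RMS amplitude in the first 30 ms after onset
    on <- x$events$onset_sample[1] + seq_len(round(0.03 * 250))
    rms <- sqrt(rowMeans(x$data[, on]^2))
    com_x <- sum(rms * test_montage$x) / sum(rms)
    if (side == "left") expect_lt(com_x, 0) else expect_gt(com_x, 0)
  }
})

test_that("simulated observers follow their psychometric function", {
  obs <- observer("threeAFC_amrd", threshold = 1, slope = 8)
  # chance floor and asymptote
  expect_equal(psychometric_p(obs, -20), 1 / 3, tolerance = 1e-6)
  expect_equal(psychometric_p(obs, 20), 1, tolerance = 1e-6)
  # closed-form midpoint: p(threshold) = guess + (1 - guess)/2 = 2/3
  expect_equal(psychometric_p(obs, 1), 2 / 3)
  set.seed(42)
  emp <- mean(replicate(1e5, observer_respond(obs, 1)))
  expect_equal(emp, 2 / 3, tolerance = 0.01)
  # inverse
  expect_equal(psychometric_p(obs, psychometric_q(obs, 0.707)), 0.707)
  expect_error(observer("detection", threshold = 0, slope = 1, guess = 0.5,
                        lapse = 0.6), "guess")
})

test_that("zero alpha lateralization leaves hemispheric power symmetric on average", {
  att <- small_attention(seed = 3, trials_per_block = 20,
                         alpha_lateralization = 0)
  e <- epoch_data(att$session, c(-1, 4))
  spec <- anticipation_spectrum(e)
  a <- ami(spec[["select_nonci"]], spec[["select_ci"]], test_montage)
  # Monte-Carlo fluctuation of the set-average AMI at these trial counts
  expect_lt(max(abs(a$set_avg)), 0.15)
})
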