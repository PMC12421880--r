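test_that("dpss tapers are orthonormal and match the requested bandwidth", {
  v <- dpss_tapers(188, 2, 250)
  expect_equal(ncol(v), 2)                       # 2*0.752*2 - 1 tapers
  expect_equal(crossprod(v), diag(2), tolerance = 1e-8)
})

test_that("multitaper anticipation spectrum partitions variance correctly", {
  fs <- 250
  n <- round(2.5 * fs)
  # narrow-band 10 Hz process of known variance; spillover from the 2 Hz
  # half-bandwidth stays inside the 7-13 Hz summation band
  set.seed(21)
  n_tr <- 60
  sigma2 <- 4
  arr <- array(0, c(n_tr, 2, n))
  for (i in seq_len(n_tr)) {
    x <- rnorm(n)
    f <- c(0, seq_len(n - 1)) * fs / n
    f <- pmin(f, fs - f)
    y <- Re(stats::fft(stats::fft(x) * (f >= 9.5 & f <= 10.5),
                       inverse = TRUE)) / n
    arr[i, 1, ] <- sqrt(sigma2) * y / sd(y)
    arr[i, 2, ] <- sqrt(sigma2) * y / sd(y)
  }
  e <- epochs_from_array(arr, fs = fs, t0 = 0)
  spec <- anticipation_spectrum(e, window_s = c(0.75, 1.5))[["a"]]
  band_power <- sum(spec$power[1, spec$freqs_hz >= 7 & spec$freqs_hz <= 13])
  expect_equal(band_power, sigma2, tolerance = 0.1 * sigma2)
  # white noise: flat between 5 and 25 Hz
  set.seed(22)
  arr2 <- array(rnorm(200 * 1 * n), c(200, 1, n))
  sp2 <- anticipation_spectrum(epochs_from_array(arr2, fs = fs, t0 = 0),
                               window_s = c(0.75, 1.5))[["a"]]
  mid <- sp2$power[1, sp2$freqs_hz >= 5 & sp2$freqs_hz <= 25]
  expect_lte(max(mid) / min(mid), 1.5)
  # zero data, zero power
  sp0 <- anticipation_spectrum(epochs_from_array(array(0, c(2, 1, n)),
                                                 fs = fs, t0 = 0),
                               window_s = c(0.75, 1.5))[["a"]]
  expect_equal(max(sp0$power), 0)
})

test_that("the lateralization index is the bounded normalized contrast", {
  expect_equal(lateralization_index(5, 5), 0)
  expect_equal(lateralization_index(2, 1), 1 / 3)
  expect_equal(lateralization_index(0, 5), -1)
  expect_warning(out <- lateralization_index(0, 0), "undefined")
  expect_true(is.na(out))
  expect_error(lateralization_index(-1, 2), "nonnegative")
})

test_that("AMI recovers the planted lateralization pattern and is antisymmetric", {
  att <- small_attention(seed = 6)
  e <- epoch_data(att$session, c(-1, 4))
  spec <- anticipation_spectrum(e)
  # ci_side = right: lateral speaker left => select_nonci, right => select_ci
  a <- ami(spec[["select_nonci"]], spec[["select_ci"]], test_montage)
  expect_gt(a$set_avg[["left"]], 0)
  expect_lt(a$set_avg[["right"]], 0)
  expect_true(all(abs(a$per_electrode) <= 1))
  # swapping conditions flips every value exactly
  b <- ami(spec[["select_ci"]], spec[["select_nonci"]], test_montage)
  expect_equal(b$per_electrode, -a$per_electrode)
  # identical inputs give exactly zero
  z <- ami(spec[["select_ci"]], spec[["select_ci"]], test_montage)
  expect_equal(unname(z$set_avg), c(0, 0))
})

test_that("suppression index shows the planted distractor-driven reversal", {
  att <- small_attention(seed = 8)
  e <- epoch_data(att$session, c(-1, 4))
  spec <- anticipation_spectrum(e)
  a <- ami(spec[["select_nonci"]], spec[["select_ci"]], test_montage)
  s <- li_suppression(spec[["suppress_nonci"]], spec[["suppress_ci"]],
                      test_montage)
  # reversed sign relative to the target-driven effect, on both sets
  expect_lt(sign(s$set_avg[["left"]]) * sign(a$set_avg[["left"]]), 0)
  expect_lt(sign(s$set_avg[["right"]]) * sign(a$set_avg[["right"]]), 0)
  expect_true(all(abs(s$per_electrode) <= 1))
})

test_that("hemisphere-specific ALI reflects the planted asymmetry and relabeling", {
  att <- small_attention(seed = 10, alpha_asymmetry = 2)
  e <- epoch_data(att$session, c(-1, 4))
  spec <- anticipation_spectrum(e)
  alis <- ali_by_ci_side(spec[["select_nonci"]], spec[["select_ci"]],
                         test_montage, ci_side = "right")
  # stronger modulation over the implant-side hemisphere
  expect_gt(alis[["ali_ci_side"]], alis[["ali_non_ci_side"]])
  expect_gt(alis[["ali_ci_side"]], 0)
  # relabeling the implant side swaps the outputs exactly
  alis2 <- ali_by_ci_side(spec[["select_nonci"]], spec[["select_ci"]],
                          test_montage, ci_side = "left")
  expect_equal(alis[["ali_ci_side"]], alis2[["ali_non_ci_side"]])
  expect_equal(alis[["ali_non_ci_side"]], alis2[["ali_ci_side"]])
  # symmetric modulation: hemispheres agree within Monte-Carlo fluctuation
  att_sym <- small_attention(seed = 14, alpha_asymmetry = 1,
                             trials_per_block = 30)
  spec_sym <- anticipation_spectrum(epoch_data(att_sym$session, c(-1, 4)))
  alis_sym <- ali_by_ci_side(spec_sym[["select_nonci"]],
                             spec_sym[["select_ci"]],
                             test_montage, ci_side = "right")
  expect_lt(abs(alis_sym[["ali_ci_side"]] - alis_sym[["ali_non_ci_side"]]),
            0.12)
})

test_that("indices are invariant to global power rescaling", {
  att <- small_attention(seed = 6)
  e <- epoch_data(att$session, c(-1, 4))
  spec <- anticipation_spectrum(e)
  scale_spec <- function(sp, c) { sp$power <- sp$power * c; sp }
  a1 <- ami(spec[["select_nonci"]], spec[["select_ci"]], test_montage)
  a2 <- ami(scale_spec(spec[["select_nonci"]], 7),
            scale_spec(spec[["select_ci"]], 7), test_montage)
  expect_equal(a1$per_electrode, a2$per_electrode, tolerance = 1e-12)
})

test_that("recovered AMI magnitude grows with the planted modulation depth", {
  depths <- c(0.1, 0.3, 0.5)
  rec <- vapply(seq_along(depths), function(i) {
    att <- small_attention(seed = 30 + i, alpha_lateralization = depths[i])
    spec <- anticipation_spectrum(epoch_data(att$session, c(-1, 4)))
    a <- ami(spec[["select_nonci"]], spec[["select_ci"]], test_montage)
    mean(abs(a$set_avg))
  }, numeric(1))
  expect_true(all(diff(rec) > 0))
})

test_that("lateralization tables flatten results in the long stats format", {
  att <- small_attention(seed = 6)
  spec <- anticipation_spectrum(epoch_data(att$session, c(-1, 4)))
  a <- ami(spec[["select_nonci"]], spec[["select_ci"]], test_montage)
  tab <- lateralization_table(list(a), participant = 3, session = 1,
                              ci_status = "on")
  expect_equal(nrow(tab), 2)
  expect_setequal(tab$hemisphere_set, c("left", "right"))
  expect_equal(tab$value, unname(a$set_avg))
})
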