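test_that("the ERP is the arithmetic mean over retained trials only", {
  arr <- array(0, c(3, 2, 10))
  arr[1, , ] <- 1
  arr[2, , ] <- -1
  arr[3, , ] <- 100
  e <- epochs_from_array(arr, labels = c("a", "a", "a"))
  # identical trials reproduce themselves; opposite trials cancel
  expect_equal(unique(as.numeric(compute_erp(
    epochs_from_array(array(2, c(4, 2, 10))))$data)), 2)
  e$bad_mask[3] <- TRUE
  expect_equal(as.numeric(compute_erp(e, "a")$data), rep(0, 20))
  expect_error(compute_erp(e, "missing"), "no retained trials")
})

test_that("global field power follows the population-SD convention", {
  # two channels at +1/-1: population SD = 1 at every sample
  arr <- array(0, c(1, 2, 100))
  arr[1, 1, ] <- 1
  arr[1, 2, ] <- -1
  e <- epochs_from_array(arr)
  expect_equal(global_field_power(compute_erp(e), c(0, 1)), 1)
  # spatially constant field: zero dispersion
  expect_equal(global_field_power(compute_erp(
    epochs_from_array(array(3, c(1, 4, 100)))), c(0, 1)), 0)
  # homogeneity: scaling data by c scales GFP by |c|
  set.seed(2)
  arr2 <- array(rnorm(1 * 6 * 100), c(1, 6, 100))
  g1 <- global_field_power(compute_erp(epochs_from_array(arr2)), c(0, 1))
  g2 <- global_field_power(compute_erp(epochs_from_array(-2.5 * arr2)),
                           c(0, 1))
  expect_equal(g2, 2.5 * g1)
})

test_that("evoked spectrum localizes pure tones and vanishes for zero input", {
  fs <- 250
  t <- seq(0, 3 - 1 / fs, 1 / fs)
  arr <- array(0, c(1, 2, length(t)))
  arr[1, 1, ] <- 3 * sin(2 * pi * 40 * t)
  arr[1, 2, ] <- 3 * sin(2 * pi * 40 * t)
  e <- epochs_from_array(arr, fs = fs, t0 = -0.5)
  sp <- evoked_spectrum(compute_erp(e))
  expect_equal(sp$freqs_hz[which.max(sp$power[1, ])], 40)
  expect_true(all(sp$power >= 0))
  # zero signal: all power zero
  sp0 <- evoked_spectrum(compute_erp(
    epochs_from_array(array(0, c(1, 2, length(t))), fs = fs, t0 = -0.5)))
  expect_equal(max(sp0$power), 0)
  # too-short window for the requested smoothing
  e2 <- epochs_from_array(array(0, c(1, 2, 200)), fs = fs, t0 = 0)
  expect_error(evoked_spectrum(compute_erp(e2), window_s = c(0, 0.5),
                               smoothing_hz = 2), "too short")
})

test_that("ITPC is 1 for common phase, bounded, and amplitude-invariant", {
  fs <- 250
  t <- seq(0, 1.5 - 1 / fs, 1 / fs)
  base <- sin(2 * pi * 5 * t) + 0.5 * cos(2 * pi * 11 * t)
  arr <- array(0, c(10, 1, length(t)))
  set.seed(4)
  scales <- runif(10, 0.2, 3)
  for (i in 1:10) arr[i, 1, ] <- scales[i] * base
  e <- epochs_from_array(arr, fs = fs, t0 = 0)
  it <- itpc(e, freqs = c(5, 11), window_s = c(0, 1.5))
  expect_equal(as.numeric(it$itpc), c(1, 1), tolerance = 1e-9)
  # amplitude invariance: different positive scalings, same ITPC
  arr2 <- arr
  for (i in 1:10) arr2[i, 1, ] <- 10 * scales[11 - i] * base
  it2 <- itpc(epochs_from_array(arr2, fs = fs, t0 = 0), freqs = c(5, 11),
              window_s = c(0, 1.5))
  expect_equal(it2$itpc, it$itpc, tolerance = 1e-9)
  expect_error(itpc(epochs_from_array(array(0, c(1, 1, 10)))), "at least 2")
})

test_that("ITPC of random phases matches the Rayleigh small-sample limit", {
  # E[ITPC] ~ sqrt(pi)/2 / sqrt(n) for uniformly random phases
  fs <- 250
  n_tr <- 64
  n_ch <- 24
  t <- seq(0, 1.5 - 1 / fs, 1 / fs)
  set.seed(9)
  arr <- array(0, c(n_tr, n_ch, length(t)))
  for (i in seq_len(n_tr)) for (j in seq_len(n_ch)) {
    arr[i, j, ] <- sin(2 * pi * 10 * t + runif(1, 0, 2 * pi))
  }
  e <- epochs_from_array(arr, fs = fs, t0 = 0)
  it <- itpc(e, freqs = 10, window_s = c(0, 1.5))
  expect_lt(abs(mean(it$itpc) - sqrt(pi) / 2 / sqrt(n_tr)), 0.03)
  expect_true(all(it$itpc >= 0 & it$itpc <= 1))
})

test_that("the steady-state summary projects set-average power at the AM rates", {
  cp <- clean_passive(ci_artifact_amp = 0)
  e <- epoch_data(cp$session, c(-0.5, 2.5))
  spectra <- lapply(c(`4` = "4", `20` = "20", `40` = "40"), function(cond) {
    evoked_spectrum(compute_erp(e, cond))
  })
  tab <- assr_summary(spectra, test_montage, session = 1)
  expect_equal(nrow(tab), 9)
  expect_setequal(unique(tab$am_rate), c(4, 20, 40))
  # table values equal the spectrum read at the matching bin
  row <- tab[tab$condition == "40" & tab$am_rate == 40, ]
  fc <- spectrum_set_average(spectra[["40"]], test_montage,
                             "frontocentral_9")
  expect_equal(row$power, fc[40])
  # single condition in, rows only for it
  tab1 <- assr_summary(spectra["4"], test_montage)
  expect_equal(unique(tab1$condition), "4")
  expect_error(assr_summary(unname(spectra), test_montage), "named")
})

test_that("the AM-rate bin is the spectral argmax in >= 95/100 noisy runs at unit SNR", {
  # injected steady-state amplitude equals the white-noise SD
  fs <- 250
  t <- seq(-0.5, 2.5 - 1 / fs, 1 / fs)
  on <- t >= 0 & t < 2
  hits <- 0
  set.seed(12)
  for (run in 1:100) {
    arr <- array(rnorm(10 * 3 * length(t)), c(10, 3, length(t)))
    for (i in 1:10) for (j in 1:3) {
      arr[i, j, on] <- arr[i, j, on] + sin(2 * pi * 40 * t[on])
    }
    sp <- evoked_spectrum(compute_erp(epochs_from_array(arr, fs = fs,
                                                        t0 = -0.5)))
    if (sp$freqs_hz[which.max(colMeans(sp$power))] == 40) hits <- hits + 1
  }
  expect_gte(hits, 95)
})
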