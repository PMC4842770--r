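test_that("zero-phase band-pass preserves passband amplitude and phase", {
  fs <- 2500
  t <- (0:24999) / fs
  x <- sin(2 * pi * 10 * t)
  rec <- recording(rbind(x), fs)
  y <- bandpass_zero_phase(rec, 0.5, 250)$data[1, ]
  k <- 5000:20000  # steady-state portion
  amp <- sd(y[k]) / sd(x[k])
  expect_gt(amp, 0.99)
  expect_lt(amp, 1.01)
  # zero phase shift at 10 Hz: cross-correlation peaks at lag 0
  cc <- ccf(y[k], x[k], lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  # DC is attenuated below 1%
  dc <- bandpass_zero_phase(recording(rbind(rep(1, 25000)), fs),
                            0.5, 250)$data[1, ]
  expect_lt(max(abs(dc[k])), 0.01)

  # impulse response is symmetric about its extremum
  imp <- rep(0, 20001); imp[10001] <- 1
  h <- bandpass_zero_phase(recording(rbind(imp), fs), 0.5, 250)$data[1, ]
  expect_equal(which.max(abs(h)), 10001L)
  expect_lt(max(abs(h - rev(h))), 1e-6)

  expect_error(bandpass_zero_phase(rec, 0.5, 1300), "Nyquist")
})

test_that("epoching yields the exact window duration and sample count", {
  fs <- 1000
  n <- 60000
  ev <- c(5000, 15000, 25000, 40000)
  rec <- recording(matrix(rnorm(2 * n), 2), fs, events = ev)
  ep <- segment_epochs(rec, -800, 3500)
  expect_equal(dim(ep$data), c(4L, 2L, 4300L))
  expect_equal(dim(ep$data)[3] / ep$fs * 1000, 4300)  # 4300 ms
  expect_equal(ep$window, c(-800, 3500))
  # first epoch sample is exactly onset - 800 ms
  expect_equal(ep$data[1, 1, 1], rec$data[1, 5000 - 800])
  # half-open window: last sample is onset + 3500 ms - 1 sample
  expect_equal(ep$data[1, 1, 4300], rec$data[1, 5000 + 3500 - 1])

  # events with no room are skipped with a warning
  rec2 <- recording(matrix(rnorm(2 * 5000), 2), fs, events = c(500, 3000))
  expect_warning(ep2 <- segment_epochs(rec2, -800, 3500), "skipped")
  expect_equal(dim(ep2$data)[1], 0L)

  # no events -> zero trials
  ep0 <- segment_epochs(recording(matrix(rnorm(1000), 1), fs), -100, 100)
  expect_equal(dim(ep0$data)[1], 0L)
  expect_error(average_erp(ep0), "empty error")
})

test_that("amplitude rejection drops exactly the artifact epoch", {
  fs <- 200
  tpl <- sin(2 * pi * 4 * (0:199) / fs)
  # 12 identical smooth epochs, one with a 100x amplitude artifact
  n_ep <- 12
  data <- matrix(rep(tpl, n_ep), 1)
  ev <- seq(1, by = 200, length.out = n_ep)
  art <- 7
  idx <- (art - 1) * 200 + 50:60
  data[1, idx] <- data[1, idx] + 100
  rec <- recording(data, fs, events = ev)
  ep <- segment_epochs(rec, 0, 1000)
  rj <- reject_epochs(ep, 6)
  expect_equal(attr(rj, "dropped"), art)
  expect_equal(dim(rj$data)[1], n_ep - 1L)

  # identical clean epochs: none dropped
  clean <- segment_epochs(recording(matrix(rep(tpl, n_ep), 1), fs,
                                    events = ev), 0, 1000)
  rj2 <- reject_epochs(clean, 6)
  expect_equal(length(attr(rj2, "dropped")), 0L)

  # infinite threshold keeps everything
  expect_equal(dim(reject_epochs(ep, Inf)$data)[1], n_ep)
  expect_error(reject_epochs(ep, 0), "amp_thresh_sd")
})

test_that("ERP averaging obeys the 1/sqrt(n) law", {
  set.seed(12)
  fs <- 250
  tpl <- exp(-(0:499) / 100) * sin(2 * pi * 8 * (0:499) / fs)
  n_tr <- 100
  noise_sd <- 1
  arr <- array(NA_real_, c(n_tr, 1, 500))
  for (i in 1:n_tr) arr[i, 1, ] <- tpl + rnorm(500, sd = noise_sd)
  ep <- structure(list(data = arr, fs = fs, window = c(0, 2000),
                       channel_names = "ch1"), class = "epoch_set")
  erp <- average_erp(ep)
  resid_sd <- sd(erp[1, ] - tpl)
  expect_lt(abs(resid_sd - noise_sd / 10), 0.3 * noise_sd / 10)

  # identical epochs: the mean is the epoch
  arr2 <- array(rep(tpl, each = 5), c(5, 1, 500))
  ep2 <- ep; ep2$data <- arr2
  expect_equal(average_erp(ep2)[1, ], tpl)
})

test_that("PLV is 1 for copies and constant lags, ~0 for independent noise", {
  fs <- 250
  t <- (0:9999) / fs
  x <- sin(2 * pi * 6 * t)
  # exact copy
  M <- plv_matrix(rbind(x, x), fs = fs)
  expect_equal(M[1, 2], 1, tolerance = 1e-9)
  expect_equal(diag(M), c(1, 1))

  # constant phase lag at the same frequency
  y <- sin(2 * pi * 6 * t + 1.1)
  M2 <- plv_matrix(rbind(x, y), band = c(4, 8), fs = fs)
  expect_equal(M2[1, 2], 1, tolerance = 1e-3)

  # amplitude scaling and common phase offsets do not change PLV
  M3 <- plv_matrix(rbind(5 * x, 0.1 * y), band = c(4, 8), fs = fs)
  expect_equal(M3[1, 2], M2[1, 2], tolerance = 1e-6)
  x2 <- sin(2 * pi * 6 * t + 0.7); y2 <- sin(2 * pi * 6 * t + 1.8)
  M4 <- plv_matrix(rbind(x2, y2), band = c(4, 8), fs = fs)
  expect_equal(M4[1, 2], M2[1, 2], tolerance = 1e-3)

  # independent noise: PLV near the Rayleigh floor, ~sqrt(pi / (4 n)).
  # Unfiltered phases are used so successive phase samples stay close to
  # independent; a narrow band-pass would shrink the effective sample count.
  set.seed(77)
  nz <- matrix(rnorm(2 * 12500), 2)
  M5 <- plv_matrix(nz, fs = fs)
  expect_lt(M5[1, 2], 0.05)

  expect_error(plv_matrix(rbind(x, y), band = c(4, 200), fs = fs),
               "Nyquist")
  expect_error(plv_matrix(rbind(x), fs = fs), "2 channels")
})

test_that("PLV matrices are symmetric, bounded and band-aware", {
  set.seed(13)
  rec <- make_erp_dataset(n_trials = 4, n_channels = 6, fs = 500,
                          snr = 2, seed = 13,
                          coupled_groups = list(1:3),
                          coupling_bands = list(c(4, 8)))
  ep <- segment_epochs(rec, -800, 3500)
  M <- plv_matrix(ep, band = "theta")
  expect_equal(M, t(M))
  expect_true(all(M >= 0 & M <= 1))
  expect_equal(diag(M), rep(1, 6))
  # coupled trio should out-synchronize independent channels in-band
  expect_gt(mean(M[1:3, 1:3][upper.tri(M[1:3, 1:3])]),
            mean(M[4:6, 4:6][upper.tri(M[4:6, 4:6])]))
  # per-trial averaging agrees with concatenation to first order
  Mt <- plv_matrix(ep, band = "theta", per_trial = TRUE)
  expect_equal(dim(Mt), c(6L, 6L))
  expect_true(all(Mt >= 0 & Mt <= 1))
})

test_that("the six canonical bands are ordered and Nyquist-safe at 600 Hz", {
  b <- ieeg_bands()
  expect_equal(names(b), c("delta", "theta", "alpha", "beta", "low_gamma",
                           "high_gamma"))
  edges <- unlist(b)
  expect_true(all(diff(unlist(lapply(b, `[`, 1))) > 0))
  for (nm in names(b)) expect_lt(b[[nm]][2], 300)
})
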