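test_that("bandpass passes mid-band tones at unit gain and kills DC", {
  fs <- 250
  t <- (0:(20 * fs - 1)) / fs
  tone <- recording(matrix(sin(2 * pi * 10 * t), 1), fs, modality = "EEG")
  spec <- filter_spec("bandpass", 1, 50, order = 4, zero_phase = TRUE)
  out <- butterworth_filter(tone, spec)
  # steady-state amplitude (discard edges)
  mid <- out$data[1, (5 * fs):(15 * fs)]
  expect_equal(max(abs(mid)), 1, tolerance = 0.01)

  dc <- recording(matrix(rep(1, 20 * fs), 1), fs, modality = "EEG")
  out_dc <- butterworth_filter(dc, spec)
  expect_lt(max(abs(out_dc$data[1, (5 * fs):(15 * fs)])), 1e-3)
})

test_that("zero-phase filtering introduces no lag", {
  fs <- 100
  n <- 1000
  pulse <- exp(-((1:n) - 500)^2 / (2 * 30^2))  # symmetric Gaussian pulse
  rec <- recording(matrix(pulse, 1), fs, modality = "EEG")
  out <- butterworth_filter(rec, filter_spec("lowpass", high_hz = 10,
                                             order = 4, zero_phase = TRUE))
  y <- out$data[1, ]
  # peak cross-correlation at lag 0
  cc <- stats::ccf(pulse, y, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  # output symmetric about the same center
  expect_equal(which.max(y), 500, tolerance = 1)

  # causal filtering of the same pulse does lag
  outc <- butterworth_filter(rec, filter_spec("lowpass", high_hz = 10,
                                              order = 4, zero_phase = FALSE))
  expect_gt(which.max(outc$data[1, ]), 500)
})

test_that("filter parameter and length errors are raised", {
  rec <- make_recording(1, 50, fs = 100)
  expect_error(butterworth_filter(rec, filter_spec("lowpass", high_hz = 60,
                                                   order = 4)), "Nyquist")
  short <- make_recording(1, 10, fs = 100)
  expect_error(
    butterworth_filter(short, filter_spec("lowpass", high_hz = 10, order = 4,
                                          zero_phase = TRUE)),
    "too short")
})

test_that("mbll inverts a forward-simulated optical-density model", {
  params <- mbll_params()
  fs <- 10; n <- 200
  set.seed(9)
  d_hbo <- cumsum(rnorm(n, sd = 0.01))
  d_hbr <- cumsum(rnorm(n, sd = 0.005))
  M <- params$extinction * (params$distance_cm * params$dpf)
  dod <- M %*% rbind(d_hbo, d_hbr)
  base <- c(1.3, 0.9)                     # baseline intensities per wavelength
  I <- base * 10^(-dod)                   # forward Beer-Lambert
  # prepend a flat baseline so the baseline window recovers `base`
  I_full <- cbind(matrix(base, 2, 50), I)
  rec <- recording(I_full, fs, modality = "NIRS_INTENSITY")
  res <- mbll(rec, params, baseline_window = 1:50)
  expect_equal(res$hbo$data[1, 51:(n + 50)], d_hbo, tolerance = 1e-10)
  expect_equal(res$hbr$data[1, 51:(n + 50)], d_hbr, tolerance = 1e-10)
})

test_that("mbll identity system returns optical densities unchanged", {
  params <- mbll_params(extinction = diag(2), dpf = c(1, 1), distance_cm = 1)
  I <- matrix(c(rep(1, 10), 10^-c(0.1, 0.2), rep(1, 10), 10^-c(0.3, 0.4)),
              2, 12, byrow = TRUE)
  rec <- recording(I, 10, modality = "NIRS_INTENSITY")
  res <- mbll(rec, params, baseline_window = 1:10)
  expect_equal(res$hbo$data[1, 11:12], c(0.1, 0.2), tolerance = 1e-12)
  expect_equal(res$hbr$data[1, 11:12], c(0.3, 0.4), tolerance = 1e-12)
  # intensity equal to baseline -> zero concentration change
  expect_equal(res$hbo$data[1, 1:10], rep(0, 10))
})

test_that("mbll guards modality, parity and positivity", {
  rec <- make_recording(2, 20, fs = 10, modality = "EEG")
  expect_error(mbll(rec), "NIRS_INTENSITY")
  odd <- recording(matrix(abs(rnorm(30)) + 1, 3, 10), 10,
                   modality = "NIRS_INTENSITY")
  expect_error(mbll(odd), "even")
  neg <- recording(matrix(c(rep(1, 19), -1), 2, 10), 10,
                   modality = "NIRS_INTENSITY")
  expect_error(mbll(neg), "positive")
  expect_error(mbll_params(extinction = matrix(1, 2, 2)), "singular")
})

test_that("mbll is linear in the optical-density stage", {
  params <- mbll_params()
  M <- params$extinction * (params$distance_cm * params$dpf)
  conc <- function(dod) solve(M, dod)
  set.seed(2)
  d1 <- matrix(rnorm(10), 2); d2 <- matrix(rnorm(10), 2)
  expect_equal(conc(2 * d1 + 3 * d2), 2 * conc(d1) + 3 * conc(d2),
               tolerance = 1e-12)
})

test_that("baseline_standardize yields population z-scores and is idempotent", {
  rec <- recording(matrix(c(1, 3), 1), fs = 1, modality = "EEG")
  out <- baseline_standardize(rec)
  expect_equal(out$data[1, ], c(-1, 1))
  rec2 <- make_recording(2, 100, seed = 3)
  once <- baseline_standardize(rec2)
  twice <- baseline_standardize(once)
  expect_equal(twice$data, once$data, tolerance = 1e-12)
  const <- recording(matrix(c(rnorm(10), rep(2, 10)), 2, 10, byrow = TRUE),
                     1, modality = "EEG")
  expect_error(baseline_standardize(const), "ch02")
})

test_that("downsample preserves low-frequency amplitude, length and DC", {
  fs <- 1000
  t <- (0:(10 * fs - 1)) / fs
  tone <- recording(matrix(sin(2 * pi * 1 * t), 1), fs, modality = "EEG")
  out <- downsample(tone, 200)
  expect_equal(out$fs, 200)
  expect_equal(n_samples(out), round(10 * fs * 200 / 1000))
  mid <- out$data[1, 500:1500]
  expect_equal(max(abs(mid)), 1, tolerance = 0.01)

  const <- recording(matrix(rep(2.5, 1000), 1), fs = 100, modality = "EEG")
  cd <- downsample(const, 20)
  expect_equal(max(abs(cd$data - 2.5)), 0, tolerance = 1e-6)
  expect_error(downsample(const, 100), "below the source rate")
})

test_that("moving_average_downsize matches hand-computed windows", {
  rec <- recording(matrix(c(1, 2, 3, 4), 1), fs = 4, modality = "EEG")
  out <- moving_average_downsize(rec, window_s = 1, target_fs = 1)
  expect_equal(as.numeric(out$data), 2.5)

  const <- recording(matrix(rep(7, 40), 2, 20), fs = 10, modality = "EEG")
  expect_equal(unique(as.numeric(
    moving_average_downsize(const, 0.5, 5)$data)), 7)

  rec2 <- make_recording(2, 50, fs = 10, seed = 8)
  ident <- moving_average_downsize(rec2, window_s = 0.1, target_fs = 10)
  expect_equal(ident$data, rec2$data, tolerance = 1e-12)

  expect_error(moving_average_downsize(make_recording(1, 5, fs = 1), 10, 1),
               "exceeds")
})

test_that("preprocessing preserves channel count and names", {
  rec <- make_recording(3, 500, fs = 100, seed = 4)
  ops <- list(
    butterworth_filter(rec, filter_spec("bandpass", 1, 40, 4)),
    baseline_standardize(rec),
    downsample(rec, 20),
    moving_average_downsize(rec, 0.5, 20)
  )
  for (out in ops) {
    expect_equal(n_channels(out), 3)
    expect_identical(out$channel_names, rec$channel_names)
  }
})

test_that("presets encode the two dataset protocols", {
  b <- preprocess_preset("buccino")
  expect_equal(c(b$eeg$low_hz, b$eeg$high_hz, b$eeg$order), c(1, 50, 4))
  expect_false(b$eeg$zero_phase)
  expect_equal(c(b$nirs$low_hz, b$nirs$high_hz), c(0.01, 0.2))
  tb <- preprocess_preset("tuberlin")
  expect_equal(tb$eeg_downsample_hz, 200)
  expect_equal(tb$nirs_downsample_hz, 10)
  expect_true(tb$eeg$zero_phase)
  expect_equal(c(tb$eeg$low_hz, tb$eeg$high_hz, tb$eeg$order), c(1, 40, 6))
  expect_equal(tb$nirs$kind, "lowpass")
  expect_equal(tb$nirs$high_hz, 0.2)
})
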