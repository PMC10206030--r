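test_that("pad_missing applies the preceding-mean rule", {
  expect_equal(pad_missing(c(1, 2, 3, 4, NA)), c(1, 2, 3, 4, 2.5))
  x <- rnorm(20)
  expect_identical(pad_missing(x), x)

  # runs are filled left to right, padded values counting as available
  expect_equal(pad_missing(c(1, 1, 1, 1, NA, NA)), rep(1, 6))
  got <- pad_missing(c(1, 2, 3, 4, NA, NA))
  v5 <- mean(c(1, 2, 3, 4))
  v6 <- mean(c(2, 3, 4, v5))
  expect_equal(got, c(1, 2, 3, 4, v5, v6))

  expect_error(pad_missing(c(1, NA, 3, 4, 5)), "first 4 positions")
})

test_that("pad_missing is idempotent on its own output", {
  set.seed(501)
  for (rep in 1:10) {
    x <- rnorm(200)
    x[sample(5:200, 30)] <- NA
    once <- pad_missing(x)
    expect_false(anyNA(once))
    expect_identical(pad_missing(once), once)
  }
})

test_that("low-pass filter meets its frequency-response contract", {
  fs <- 16
  t <- (0:800) / fs  # 50 s, whole cycles for the test tones

  # DC gain is 1
  expect_equal(lowpass(rep(3.7, 801), fs), rep(3.7, 801), tolerance = 1e-9)

  # 2 Hz (stop band, 4x cutoff): RMS attenuated below 1%
  x2 <- sin(2 * pi * 2 * t)
  expect_lt(rms(lowpass(x2, fs)) / rms(x2), 0.01)

  # 0.05 Hz (pass band): RMS preserved within 5%
  x005 <- sin(2 * pi * 0.05 * t)
  expect_lt(abs(rms(lowpass(x005, fs)) / rms(x005) - 1), 0.05)

  expect_error(lowpass(rnorm(10), fs), "too short")
  expect_error(lowpass(rnorm(100), fs, cutoff = 9), "Nyquist")
})

test_that("low-pass filter is linear", {
  set.seed(502)
  x <- rnorm(300); y <- rnorm(300)
  a <- 2.5; b <- -1.3
  lhs <- lowpass(a * x + b * y, 16)
  rhs <- a * lowpass(x, 16) + b * lowpass(y, 16)
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("baseline removal strips trends while keeping the activation shape", {
  fs <- 16
  n <- 320
  tt <- (0:(n - 1)) / fs

  # pure linear ramp: detrended output has negligible residual slope
  a <- 0.8
  out <- suppressWarnings(remove_baseline(a * tt, fs))
  slope_left <- abs(lfs(out, tt))
  expect_lt(slope_left, 0.01 * a)

  expect_equal(suppressWarnings(remove_baseline(rep(0, 100), fs)), rep(0, 100))

  # plateau activation plus slow sinusoidal drift: the detrended series stays
  # close to the drift-free reference
  cfg <- sim_config(cardiac_amplitude = 0, noise_sd = 0, missing_rate = 0,
                    subject_jitter_sd = 0)
  ref_cfg <- clean_config()
  for (seed in c(601, 602, 603)) {
    tr <- generate_trial(cfg, "LF", seed = seed)
    ref <- generate_trial(ref_cfg, "LF", seed = seed)
    x <- suppressWarnings(remove_baseline(tr$recording$series$ROEA$HbO2, fs))
    expect_gte(cor(x, ref$recording$series$ROEA$HbO2), 0.9)
  }

  expect_error(remove_baseline(rnorm(32), fs), "at least 64")
})

test_that("preprocessing a recording preserves shape and removes artifacts", {
  fs <- 16
  # artifact-free input: output differs from the clean input only by its own
  # linear trend (preprocessing is trend free by construction) and edge effects
  tr <- tiny_trial("SE", seed = 604)
  pre <- preprocess_recording(tr$recording)
  mid <- 17:144
  lin_detrend <- function(x) unname(lm.fit(cbind(1, seq_along(x)), x)$residuals)
  for (ch in c("RDT", "RES")) {
    got <- lin_detrend(pre$series[[ch]]$HbO2[mid])
    ref <- lin_detrend(tr$recording$series[[ch]]$HbO2[mid])
    expect_lt(rms(got - ref), 0.1 * rms(ref))
    expect_gt(cor(got, ref), 0.99)
  }

  # cardiac interference at 1.2 Hz: band power reduced by >= 99%
  cfg <- sim_config(drift_amplitude = 0, noise_sd = 0, missing_rate = 0,
                    subject_jitter_sd = 0, cardiac_amplitude = 0.5)
  trc <- generate_trial(cfg, "NC", seed = 605)
  prec <- preprocess_recording(trc$recording)
  band_power <- function(x) {
    tt <- (seq_along(x) - 1) / fs
    # projection onto the quadrature pair at the cardiac frequency
    (mean(x * sin(2 * pi * 1.2 * tt))^2 + mean(x * cos(2 * pi * 1.2 * tt))^2)
  }
  raw_p <- band_power(trc$recording$series$LES$Hb)
  filt_p <- band_power(prec$series$LES$Hb)
  expect_lt(filt_p / raw_p, 0.01)

  # missing samples: none remain after preprocessing
  cfgm <- sim_config(missing_rate = 0.05)
  trm <- generate_trial(cfgm, "TR", seed = 606)
  expect_true(any(unlist(trm$recording$missing_mask)))
  prem <- preprocess_recording(trm$recording)
  expect_false(anyNA(unlist(lapply(prem$series, unlist))))

  # length and channel count are never changed
  expect_identical(names(prem$series), trm$recording$channels)
  expect_identical(lengths(lapply(prem$series, function(s) s$Hb)),
                   lengths(lapply(trm$recording$series, function(s) s$Hb)))
})

test_that("emd separates an oscillation from a trend", {
  t <- (0:639) / 16
  x <- sin(2 * pi * 1.5 * t) + 0.2 * t
  dec <- emd(x)
  expect_gte(length(dec$imfs), 1)
  # residual carries the trend: highly correlated with t, little oscillation
  expect_gt(cor(dec$residual, t), 0.99)
  recon <- Reduce(`+`, dec$imfs) + dec$residual
  expect_equal(recon, x, tolerance = 1e-10)
  # IMF1 recovers most of the oscillation
  expect_gt(cor(dec$imfs[[1]], sin(2 * pi * 1.5 * t)), 0.95)
})
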