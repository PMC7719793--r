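make_tone <- function(freq, sfreq = 250, window = c(0.5, 3), trials = 2,
                      channels = 2) {
  ns <- round((window[2] - window[1]) * sfreq)
  t <- (seq_len(ns) - 1) / sfreq
  dat <- array(0, dim = c(trials, channels, ns))
  for (i in seq_len(trials)) for (j in seq_len(channels))
    dat[i, j, ] <- sin(2 * pi * freq * t + 0.3 * i + 0.7 * j)
  epoch_array(dat, sfreq, window)
}

test_that("band-pass gains match the analytic filter response", {
  rms <- function(x) sqrt(mean(x^2))
  # reference: squared magnitude response of the same design (two passes),
  # from the transfer-function polynomials at the tone frequency
  gain2 <- function(freq, sfreq = 250) {
    bf <- signal::butter(5, c(8, 30) / (sfreq / 2), type = "pass")
    z <- exp(-1i * 2 * pi * freq / sfreq * (seq_along(bf$b) - 1))
    za <- exp(-1i * 2 * pi * freq / sfreq * (seq_along(bf$a) - 1))
    Mod(sum(bf$b * z) / sum(bf$a * za))^2
  }
  ep15 <- make_tone(15)
  out15 <- bandpass_epochs(ep15)
  ratio15 <- rms(out15$data[1, 1, ]) / rms(ep15$data[1, 1, ])
  expect_lt(abs(ratio15 - gain2(15)), 0.05)
  expect_gt(ratio15, 0.95)

  ep2 <- make_tone(2)
  out2 <- bandpass_epochs(ep2)
  ratio2 <- rms(out2$data[1, 1, ]) / rms(ep2$data[1, 1, ])
  expect_lt(ratio2, 0.05)
  expect_lt(abs(ratio2 - gain2(2)), 0.05)

  # zero in, zero out; invalid band rejected
  zero <- epoch_array(array(0, dim = c(1, 2, 625)), 250)
  expect_equal(bandpass_epochs(zero)$data, zero$data)
  expect_error(bandpass_epochs(ep15, band = c(8, 200)), "sfreq/2")
})

test_that("CSP concentrates on the discriminative channel in a 2-channel toy", {
  set.seed(31)
  ns <- 625; trials <- 40
  dat <- array(rnorm(trials * 2 * ns), dim = c(trials, 2, ns))
  y <- rep(c(1, -1), each = trials / 2)
  dat[y == 1, 1, ] <- dat[y == 1, 1, ] * 3   # class +1 has high var on ch 1
  ep <- epoch_array(dat, 250)
  filt <- fit_spatial_filters(ep, y, n_filters = 2)
  w1 <- filt[, 1]
  expect_gt(w1[1]^2 / sum(w1^2), 0.9)

  # consistent channel permutation permutes the filters (up to sign)
  perm <- c(2, 1)
  ep_p <- epoch_array(dat[, perm, ], 250)
  filt_p <- fit_spatial_filters(ep_p, y, n_filters = 2)
  for (k in 1:2) {
    agree <- min(sum(abs(filt_p[perm, k] - filt[, k])),
                 sum(abs(filt_p[perm, k] + filt[, k])))
    expect_lt(agree, 1e-6 * sum(abs(filt[, k])) + 1e-8)
  }
})

test_that("identical class covariances give uninformative filters", {
  set.seed(37)
  dat <- array(rnorm(60 * 3 * 625), dim = c(60, 3, 625))
  y <- rep(c(1, -1), 30)
  ep <- epoch_array(dat, 250)
  filt <- fit_spatial_filters(ep, y, n_filters = 2)
  expect_equal(attr(filt, "eigenvalues"), c(0.5, 0.5), tolerance = 0.05)
})

test_that("band-power matrices carry the planted variance contrast", {
  set.seed(41)
  ns <- 625; trials <- 100
  dat <- array(rnorm(trials * 2 * ns), dim = c(trials, 2, ns))
  y <- rep(c(1, -1), each = trials / 2)
  dat[y == 1, 1, ] <- dat[y == 1, 1, ] * 2   # variance x4 on channel 1
  ep <- epoch_array(dat, 250)
  filt <- diag(2)                             # identity spatial filters
  ds <- band_power_matrix(ep, filt, n_windows = 5, y = y)
  expect_equal(ds$p, 2L); expect_equal(ds$q, 5L)
  arr <- simplify2array(ds$trials)
  row1_diff <- mean(arr[1, , y == 1]) - mean(arr[1, , y == -1])
  row2_diff <- mean(arr[2, , y == 1]) - mean(arr[2, , y == -1])
  expect_lt(abs(row1_diff - log(4)), 0.15)
  expect_lt(abs(row2_diff), 0.1)

  # single window gives column vectors
  ds1 <- band_power_matrix(ep, filt, n_windows = 1)
  expect_equal(ds1$q, 1L)
  # constant signal hits the variance floor
  con <- epoch_array(array(1, dim = c(1, 2, 625)), 250)
  dsc <- band_power_matrix(con, filt, n_windows = 5)
  expect_equal(unique(as.numeric(dsc$trials[[1]])), log(1e-12))
  expect_error(band_power_matrix(ep, filt, n_windows = 100), "10 samples")
})

test_that("feature scaling standardizes entries using training statistics", {
  ds <- toy_dataset(n = 25, seed = 51)
  sc <- fit_feature_scaler(ds)
  z <- apply_feature_scaler(ds, sc)
  arr <- simplify2array(z$trials)
  expect_lt(max(abs(apply(arr, c(1, 2), mean))), 1e-12)
  expect_lt(max(abs(apply(arr, c(1, 2), sd) - 1)), 1e-12)
})

test_that("planted ERD is decodable through the full feature pipeline", {
  ee <- synth_eeg(n_trials = 80, channels = 3, effect_size = 0.3, seed = 1)
  tr <- 1:40; te <- 41:80
  ep_tr <- epoch_array(ee$epochs$data[tr, , ], 250)
  ep_te <- epoch_array(ee$epochs$data[te, , ], 250)
  bp_tr <- bandpass_epochs(ep_tr); bp_te <- bandpass_epochs(ep_te)
  filt <- fit_spatial_filters(bp_tr, ee$y[tr], n_filters = 2)
  ds_tr <- band_power_matrix(bp_tr, filt, n_windows = 5, y = ee$y[tr])
  ds_te <- band_power_matrix(bp_te, filt, n_windows = 5)
  sc <- fit_feature_scaler(ds_tr)
  fit <- smm(apply_feature_scaler(ds_tr, sc), C = 1, tau = 0.1)
  pred <- ifelse(predict(fit, apply_feature_scaler(ds_te, sc),
                         type = "decision") >= 0, 1, -1)
  expect_gt(mean(pred == ee$y[te]), 0.8)
})

test_that("feature operations are deterministic", {
  ee <- synth_eeg(n_trials = 10, channels = 3, seed = 5)
  b1 <- bandpass_epochs(ee$epochs); b2 <- bandpass_epochs(ee$epochs)
  expect_identical(b1$data, b2$data)
  f1 <- fit_spatial_filters(b1, ee$y, 2)
  f2 <- fit_spatial_filters(b2, ee$y, 2)
  expect_identical(unclass(f1), unclass(f2))
})
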