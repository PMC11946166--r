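make_intensity_recording <- function(I, fs = 75) {
  nirs_recording(test_montage(), fs, I, empty_events())
}

test_that("delta-OD of a constant channel is zero and scale-invariant", {
  n <- 1000
  set.seed(1)
  I <- matrix(exp(rnorm(n * 36, log(1e6), 0.01)), n, 36)
  I[, 1] <- 5e5                       # constant channel
  r <- make_intensity_recording(I)
  od <- intensity_to_od(r)
  expect_equal(od$data[, 1], rep(0, n))
  r10 <- make_intensity_recording(10 * I)
  expect_equal(intensity_to_od(r10)$data, od$data, tolerance = 1e-12)
})

test_that("delta-OD recovers a zero-mean log-attenuation exactly", {
  n <- 2000; fs <- 75
  t <- (seq_len(n) - 1) / fs
  a <- 0.01 * sin(2 * pi * 0.2 * t)          # zero-mean attenuation
  I <- matrix(rep(2e6 * exp(-a), 36), n, 36)
  od <- intensity_to_od(make_intensity_recording(I))
  ## reference is mean(I), not exp(mean(log I)); correct for the
  ## (constant, second-order) Jensen offset before comparing
  resid <- od$data[, 5] - a
  expect_lt(diff(range(resid)), 1e-9)
})

test_that("bad-channel screen flags flat and dropout channels, not clean ones", {
  n <- 75 * 20
  set.seed(2)
  I <- matrix(exp(rnorm(n * 36, log(1e6), 0.005)), n, 36)
  I[, 3] <- 1e6                                  # dead flat
  drop <- rep(c(1, 0.5), each = 75)              # 50% square-wave dropouts
  I[, 8] <- 1e6 * rep_len(drop, n)
  r <- make_intensity_recording(I)
  mask <- detect_bad_channels(r)
  expect_true(mask$flagged[3])
  expect_true(mask$flagged[8])
  expect_gt(mask$cv[8], 0.15)
  expect_false(any(mask$flagged[-c(3, 8)]))
  expect_error(detect_bad_channels(make_intensity_recording(I[1:100, ])),
               "10 s")
})

test_that("clean generator output at nominal noise passes the screen", {
  sess <- short_session(seed = 11)
  mask <- detect_bad_channels(sess$recordings$second)
  expect_false(any(mask$flagged))
})

test_that("bandpass keeps 0.1 Hz, rejects 1.2 Hz, is zero-phase and linear", {
  fs <- 75; n <- fs * 120
  t <- (seq_len(n) - 1) / fs
  x01 <- sin(2 * pi * 0.1 * t)
  x12 <- sin(2 * pi * 1.2 * t)
  mid <- (fs * 30):(fs * 90)
  y01 <- bandpass(cbind(x01), fs = fs)[, 1]
  y12 <- bandpass(cbind(x12), fs = fs)[, 1]
  expect_equal(max(abs(y01[mid])), 1, tolerance = 0.05)
  expect_lt(max(abs(y12[mid])), max(abs(x12)) / 10)
  ## zero signal maps to zero
  expect_equal(bandpass(cbind(rep(0, n)), fs = fs)[, 1], rep(0, n))
  ## zero phase: cross-correlation with the input peaks at zero lag
  lags <- -5:5
  cc <- vapply(lags, function(l)
    sum(x01[mid] * y01[mid + l]), 0)
  expect_lte(abs(lags[which.max(cc)]), 1)
  expect_error(bandpass(cbind(x01), 0.5, 0.1, fs = fs), "invalid band")
})

test_that("MBLL inversion is exact on forward-generated optical density", {
  m <- test_montage()
  p <- mbll_params(m)
  wl <- montage_wavelengths(m)
  E <- extinction_at(wl)
  hbo_true <- 1e-6; hbr_true <- -0.5e-6        # Molar mm
  n <- 50
  odm <- matrix(0, n, 36)
  for (i in seq_len(36)) {
    w <- as.character(m$channels$wavelength[i])
    odm[, i] <- E[w, "hbo"] * hbo_true + E[w, "hbr"] * hbr_true
  }
  od <- od_from_matrix(odm)
  conc <- od_to_conc(od, p)
  expect_equal(max(abs(conc$hbo - hbo_true)), 0, tolerance = 1e-9)
  expect_equal(max(abs(conc$hbr - hbr_true)), 0, tolerance = 1e-9)
  ## zero in, zero out
  conc0 <- od_to_conc(od_from_matrix(matrix(0, n, 36)), p)
  expect_equal(max(abs(conc0$hbt)), 0)
  ## linearity: doubling OD doubles all concentrations
  conc2 <- od_to_conc(od_from_matrix(2 * odm), p)
  expect_equal(conc2$hbo, 2 * conc$hbo, tolerance = 1e-12)
  ## conservation
  expect_equal(conc$hbt, conc$hbo + conc$hbr, tolerance = 1e-12)
})

test_that("an isolated 762 nm OD increase moves HbR more than HbO", {
  m <- test_montage()
  odm <- matrix(0, 10, 36)
  odm[, m$channels$wavelength == 762] <- 1e-3
  conc <- od_to_conc(od_from_matrix(odm), mbll_params(m))
  expect_gt(abs(conc$hbr[1, 1]), abs(conc$hbo[1, 1]))
})

test_that("a singular extinction table is rejected", {
  tab <- data.frame(wavelength_nm = c(700, 900),
                    eps_hbo = c(1, 1), eps_hbr = c(2, 2))
  expect_error(mbll_params(test_montage(), extinction = tab), "singular")
})

test_that("block averaging reproduces single and repeated epochs", {
  m <- test_montage()
  n <- 75 * 60
  set.seed(4)
  odm <- matrix(rnorm(n * 36, sd = 1e-4), n, 36)
  conc <- od_to_conc(od_from_matrix(odm), mbll_params(m))
  one <- block_average(conc, list(c(10, 20)))
  idx <- sample_window(10, 20, 75)
  expect_equal(one$hbt$mean, conc$hbt[idx, ], tolerance = 1e-12)
  ## identical epochs: the average equals any single epoch
  conc$hbt[sample_window(30, 40, 75), ] <- conc$hbt[idx, ]
  conc$hbo[sample_window(30, 40, 75), ] <- conc$hbo[idx, ]
  conc$hbr[sample_window(30, 40, 75), ] <- conc$hbr[idx, ]
  two <- block_average(conc, list(c(10, 20), c(30, 40)))
  expect_equal(two$hbt$mean, conc$hbt[idx, ], tolerance = 1e-12)
  expect_error(block_average(conc, list(c(55, 65))), "outside")
  expect_error(block_average(conc, list(c(10, 20), c(30, 41))), "length")
})

test_that("block-average error scales as sigma over sqrt(n)", {
  ## constructed epochs: fixed response + iid noise, Monte-Carlo over seeds
  fs <- 25; len <- fs * 10
  hrf <- canonical_hrf(seq(0, 10, length.out = len))
  sigma <- 0.5
  rms_for <- function(n_ep, seed) {
    set.seed(seed)
    est <- rowMeans(matrix(hrf, len, n_ep) +
                    matrix(rnorm(len * n_ep, sd = sigma), len, n_ep))
    sqrt(mean((est - hrf)^2))
  }
  rms10 <- mean(vapply(1:50, function(s) rms_for(10, s), 0))
  rms40 <- mean(vapply(1:50, function(s) rms_for(40, 100 + s), 0))
  expect_equal(rms10, sigma / sqrt(10), tolerance = 0.3)
  expect_equal(rms40, sigma / sqrt(40), tolerance = 0.3)
  expect_equal(rms10 / rms40, 2, tolerance = 0.3)
})
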