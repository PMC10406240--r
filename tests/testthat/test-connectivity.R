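test_that("cross-spectra are Hermitian with real autospectra on the requested grid", {
  set.seed(1)
  ep <- eeg_epochs(array(rnorm(5 * 3 * 256), c(5, 3, 256)), fs = 128)
  cs <- estimate_cross_spectra(ep, resolution_hz = 0.5)
  expect_equal(diff(cs$freqs)[1], 0.5)
  herm_err <- vapply(seq_along(cs$freqs), function(b) {
    max(Mod(cs$S[, , b] - Conj(t(cs$S[, , b]))))
  }, numeric(1))
  expect_lt(max(herm_err), 1e-12)
  expect_lt(max(abs(Im(apply(cs$S, 3, diag)))), 1e-12)
  expect_true(all(Re(apply(cs$S, 3, diag)) >= 0))

  # pure sinusoid: autospectrum peaks at its own grid bin
  tt <- (0:255) / 128
  dat2 <- array(rnorm(3 * 2 * 256, sd = 1e-3), c(3, 2, 256))
  for (t in 1:3) dat2[t, 1, ] <- sin(2 * pi * 10 * tt + t)
  cs2 <- estimate_cross_spectra(eeg_epochs(dat2, fs = 128))
  auto <- Re(cs2$S[1, 1, ])
  expect_equal(cs2$freqs[which.max(auto)], 10)

  # a single trial cannot give a meaningful coherency
  ep1 <- eeg_epochs(array(rnorm(1 * 2 * 64), c(1, 2, 64)), fs = 64)
  expect_error(estimate_cross_spectra(ep1), ">= 2 trials")
})

test_that("coherency is normalized and recovers the closed-form phase of a delayed pair", {
  ep <- delayed_pair_epochs(freq = 10, lag_s = 0.025, n_trials = 50, seed = 2)
  cs <- estimate_cross_spectra(ep)
  coh <- coherency(cs)
  i10 <- which(coh$freqs == 10)
  # quarter-cycle delay: phase pi/2 at 10 Hz, both in S and in COH
  expect_equal(Arg(cs$S[1, 2, i10]), pi / 2, tolerance = 0.02)
  expect_equal(coh$C[1, 2, i10], exp(1i * pi / 2), tolerance = 0.02)
  expect_equal(Re(coh$C[1, 1, i10]), 1, tolerance = 1e-9)
  expect_lt(max(Mod(coh$C), na.rm = TRUE), 1 + 1e-9)

  # independent white noise: |COH| shrinks toward the 1/sqrt(n) bias floor
  set.seed(3)
  epn <- eeg_epochs(array(rnorm(100 * 2 * 128), c(100, 2, 128)), fs = 64)
  cohn <- coherency(estimate_cross_spectra(epn))
  expect_lt(mean(Mod(cohn$C[1, 2, ])), 2 / sqrt(100))
})

test_that("band-averaged iCOH matches closed forms and band bookkeeping", {
  # zero-lag identical signals carry no imaginary coherency
  lay <- synthetic_layout(2)
  sm <- source_model(10, noise_sd = 0.01)
  mm <- mixing_model(lay, weights = matrix(c(1, 1), ncol = 1))
  ep0 <- simulate_epochs(sm, mm, 40, 2, 128, seed = 4)
  ic0 <- icoh_band(coherency(estimate_cross_spectra(ep0)), eeg_bands()$alpha)
  expect_lt(ic0$W[1, 2], 0.05)

  # delayed sinusoid: band iCOH = |sin(2 pi f lag)| within 0.05
  for (lag in c(0.025, 0.0125)) {
    ep <- delayed_pair_epochs(freq = 10, lag_s = lag, n_trials = 100, seed = 6)
    ic <- icoh_band(coherency(estimate_cross_spectra(ep)),
                    band_spec("alpha_peak", 9.5, 10.5))
    expect_equal(ic$W[1, 2], abs(sin(2 * pi * 10 * lag)), tolerance = 0.05)
  }

  # delta on a 0.5 Hz grid spans the 8 bins 0.5 ... 4.0
  set.seed(5)
  ep <- eeg_epochs(array(rnorm(3 * 2 * 256), c(3, 2, 256)), fs = 128)
  cs <- estimate_cross_spectra(ep, resolution_hz = 0.5)
  d <- eeg_bands()$delta
  expect_equal(sum(cs$freqs >= d$f_lo & cs$freqs <= d$f_hi), 8)

  coh <- coherency(cs)
  expect_error(icoh_band(coh, band_spec("supra", 200, 300)), "supra")

  # connectivity matrix contract: symmetric, zero diagonal, [0, 1]
  ic <- icoh_band(coh, eeg_bands()$theta)
  expect_identical(ic$W, t(ic$W))
  expect_identical(unname(diag(ic$W)), rep(0, 2))
  expect_true(all(ic$W >= 0 & ic$W <= 1))
})

test_that("band-limited correlation uses absolute trial-averaged Pearson coefficients", {
  # y = -x gives |r| = 1
  set.seed(7)
  dat <- array(NA_real_, c(2, 2, 256))
  for (t in 1:2) {
    base <- rnorm(256)
    dat[t, 1, ] <- base
    dat[t, 2, ] <- -base
  }
  r <- correlation_matrix(eeg_epochs(dat, fs = 128), band_spec("wide", 1, 30))
  expect_equal(r$W[1, 2], 1, tolerance = 1e-6)

  # independent channels: near-zero average correlation
  epn <- eeg_epochs(array(rnorm(50 * 2 * 256), c(50, 2, 256)), fs = 128)
  rn <- correlation_matrix(epn, band_spec("alpha", 7, 13))
  expect_lt(rn$W[1, 2], 0.1)

  # constant channel: undefined correlations become 0 with a warning
  datc <- array(rnorm(2 * 2 * 64), c(2, 2, 64))
  datc[, 2, ] <- 5
  expect_warning(rc <- correlation_matrix(eeg_epochs(datc, fs = 64),
                                          band_spec("th", 4, 7)),
                 "constant")
  expect_equal(rc$W[1, 2], 0)

  expect_error(correlation_matrix(epn, band_spec("hi", 10, 100)), "Nyquist")
})
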