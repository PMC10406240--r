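test_that("simulation is deterministic in the seed and cohort seeds derive from the spec", {
  lay <- synthetic_layout(6)
  sm <- source_model(c(8, 12),
                     coupling = data.frame(from = 1, to = 2, lag_ms = 20,
                                           strength = 0.5),
                     noise_sd = 0.3)
  mm <- mixing_model(lay, source_positions = layout_coords(lay)[c(1, 6), ])
  a <- simulate_epochs(sm, mm, n_trials = 4, trial_s = 1, fs = 64, seed = 42)
  b <- simulate_epochs(sm, mm, n_trials = 4, trial_s = 1, fs = 64, seed = 42)
  c <- simulate_epochs(sm, mm, n_trials = 4, trial_s = 1, fs = 64, seed = 43)
  expect_identical(a$data, b$data)
  expect_false(identical(a$data, c$data))

  # single-subject cohort with no jitter equals simulate_epochs at seed + 1
  spec <- cohort_spec(1, "control_like", seed = 42)
  coh <- generate_cohort(spec, sm, mm, n_trials = 4, trial_s = 1, fs = 64)
  expect_identical(coh[[1]]$data,
                   simulate_epochs(sm, mm, 4, 1, 64, seed = 43)$data)

  # attenuation 1 leaves the generative law untouched
  ctrl <- generate_cohort(cohort_spec(2, "control_like", seed = 7),
                          sm, mm, 3, 1, 64)
  imp1 <- generate_cohort(cohort_spec(2, "impaired_like",
                                      coupling_attenuation = 1, seed = 7),
                          sm, mm, 3, 1, 64)
  expect_identical(lapply(ctrl, `[[`, "data"), lapply(imp1, `[[`, "data"))

  expect_error(simulate_epochs(sm, mm, 4, 1, fs = 20, seed = 1), "Nyquist|exceed")
  expect_error(source_model(c(10, 10),
                            coupling = data.frame(from = 1, to = 2,
                                                  lag_ms = -1, strength = 1)),
               "lag_ms")
})

test_that("instantaneous mixing correlates sensors without creating iCOH, unlike lagged coupling", {
  lay <- synthetic_layout(4)
  # one source spread instantaneously into all sensors
  sm1 <- source_model(10, noise_sd = 0.05)
  mm1 <- mixing_model(lay, weights = matrix(c(1, 0.8, 0.6, 0.9), ncol = 1))
  ep1 <- simulate_epochs(sm1, mm1, n_trials = 50, trial_s = 2, fs = 128,
                         seed = 3)
  alpha <- eeg_bands()$alpha
  r <- correlation_matrix(ep1, alpha)
  ic <- icoh_band(coherency(estimate_cross_spectra(ep1)), alpha)
  expect_true(all(r$W[upper.tri(r$W)] > 0.9))
  expect_true(all(ic$W[upper.tri(ic$W)] < 0.1))

  # two independent sources with disjoint mixing: no cross-group correlation
  sm2 <- source_model(c(9, 11), noise_sd = 0)
  mm2 <- mixing_model(lay, weights = rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1)))
  ep2 <- simulate_epochs(sm2, mm2, n_trials = 50, trial_s = 2, fs = 128,
                         seed = 4)
  r2 <- correlation_matrix(ep2, band_spec("wide", 1, 30))
  expect_lt(mean(r2$W[1:2, 3:4]), 0.1)
})

test_that("lagged coupling raises band iCOH only in the band containing the oscillation", {
  ep <- delayed_pair_epochs(freq = 10, lag_s = 0.025, n_trials = 60, seed = 5)
  coh <- coherency(estimate_cross_spectra(ep))
  bands <- eeg_bands()
  ic <- vapply(bands, function(b) icoh_band(coh, b)$W[1, 2], numeric(1))
  # the 10 Hz bins carry near-unit iCOH; the rest of the alpha band is at
  # the noise floor, so the band average sits well above the other bands
  expect_gt(ic[["alpha"]], 0.15)
  expect_gt(ic[["alpha"]], 2 * max(ic[c("delta", "theta", "beta")]))
  expect_true(all(ic[c("delta", "theta", "beta")] < 0.15))
})

test_that("planted communities have the prescribed weight structure and are recoverable from the embedding", {
  # noise-free two-community matrix: exactly two distinct off-diagonal values
  W0 <- planted_connectivity(10, rep(1:2, each = 5), 0.8, 0.2, 0, seed = 1)
  off <- W0$W[upper.tri(W0$W)]
  expect_setequal(unique(off), c(0.8, 0.2))

  # equal weights: exchangeable, so within/between angle distributions agree
  We <- planted_connectivity(20, rep(1:2, each = 10), 0.5, 0.5, 0.1, seed = 3)
  Ae <- eigenvector_alignment(We)
  grp <- rep(1:2, each = 10)
  same <- outer(grp, grp, "==")[upper.tri(diag(20))]
  th <- Ae$theta[upper.tri(Ae$theta)]
  expect_gt(suppressWarnings(stats::ks.test(th[same], th[!same]))$p.value, 0.01)

  # clustering of the embedding recovers three planted communities
  skip_if_not_installed("mclust")
  truth <- rep(1:3, each = 10)
  ari <- vapply(1:20, function(s) {
    W <- planted_connectivity(30, truth, 0.8, 0.1, 0.05, seed = s)
    emb <- embed_connectivity(W)
    U <- emb$coords / sqrt(rowSums(emb$coords^2))
    km <- kmeans(U, centers = 3, nstart = 10)
    mclust::adjustedRandIndex(km$cluster, truth)
  }, numeric(1))
  expect_gte(mean(ari), 0.9)
})

test_that("attenuating coupling strengths removes consistent alignments relative to controls", {
  ctrl <- cohort_sigmaps("control_like", atten = 1, seed = 10)
  imp <- cohort_sigmaps("impaired_like", atten = 0, seed = 20)
  n_ctrl <- sum(consistency_filter(ctrl$sigs)$consistent)
  n_imp <- sum(consistency_filter(imp$sigs)$consistent)
  expect_gt(n_ctrl, 0)
  expect_lt(n_imp, n_ctrl)
})
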