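# Shared fixtures, built in code. Heavier cohort computations are cached per
# session so several test files can reuse them.

.fixtures <- new.env(parent = emptyenv())

# Two-channel epochs: channel 2 is channel 1 delayed by lag_s, plus noise.
delayed_pair_epochs <- function(freq = 10, lag_s = 0.025, n_trials = 100,
                                fs = 128, trial_s = 2, noise_sd = 0.05,
                                seed = 1) {
  lay <- synthetic_layout(2)
  sm <- source_model(c(freq, freq),
                     coupling = data.frame(from = 1, to = 2,
                                           lag_ms = lag_s * 1000,
                                           strength = 1),
                     noise_sd = noise_sd, phase_drift_sd = 0)
  mm <- mixing_model(lay, weights = diag(2))
  simulate_epochs(sm, mm, n_trials, trial_s, fs, seed = seed)
}

# Per-band significance maps for a small multi-band-coupled cohort
# (16 channels, 8 subjects, oscillators in all four conventional bands).
cohort_sigmaps <- function(profile = "control_like", atten = 1, seed = 10,
                           n_null = 100) {
  key <- paste(profile, atten, seed, n_null, sep = "_")
  if (!is.null(.fixtures[[key]])) return(.fixtures[[key]])
  model <- coupled_cohort_model(n_channels = 16, n_sources = 6,
                                freq_hz = c(2.5, 5.5, 10, 15))
  spec <- cohort_spec(8, profile, coupling_attenuation = atten,
                      between_subject_jitter = 0.05, seed = seed)
  cohort <- generate_cohort(spec, model$sm, model$mm, n_trials = 30,
                            trial_s = 2, fs = 128)
  coh <- lapply(cohort, function(ep) coherency(estimate_cross_spectra(ep)))
  bands <- eeg_bands()
  groups <- list()
  sigs <- list()
  for (bi in seq_along(bands)) {
    group <- lapply(coh, icoh_band, band = bands[[bi]])
    thetas <- lapply(group, eigenvector_alignment)
    nulls <- build_null_ensemble(group, n_null = n_null,
                                 seed = seed + 1000L * bi)
    sigs[[names(bands)[bi]]] <- pairwise_welch_test(thetas, nulls)
    groups[[names(bands)[bi]]] <- group
  }
  out <- list(groups = groups, sigs = sigs, layout = model$layout)
  .fixtures[[key]] <- out
  out
}

# Significance maps recomputed from per-band connectivity groups (used for
# channel-subsetting comparisons).
sigmaps_from_groups <- function(groups, n_null = 100, seed = 10) {
  sigs <- list()
  for (bi in seq_along(groups)) {
    thetas <- lapply(groups[[bi]], eigenvector_alignment)
    nulls <- build_null_ensemble(groups[[bi]], n_null = n_null,
                                 seed = seed + 1000L * bi)
    sigs[[names(groups)[bi]]] <- pairwise_welch_test(thetas, nulls)
  }
  sigs
}

# Hand-built significance map over a fixed 3-channel set.
fake_sigmap <- function(directions) {
  pairs <- data.frame(chan_a = c("A", "A", "B"), chan_b = c("B", "C", "C"),
                      stringsAsFactors = FALSE)
  out <- data.frame(pairs, t = 0, p = 1, q = 1, direction = directions,
                    degenerate = FALSE, stringsAsFactors = FALSE)
  class(out) <- c("significance_map", "data.frame")
  out
}

# Minimal hand-built null ensemble over given per-pair angle samples.
fake_ensemble <- function(thetas, labels) {
  structure(list(values = thetas, thetas = thetas,
                 provenance = rep(1L, nrow(thetas)), n_null = nrow(thetas),
                 seed = 0L, eig_indices = 2:4, channel_labels = labels,
                 matrices = NULL),
            class = "null_ensemble")
}

# Alignment matrix with prescribed angles (upper triangle mirrored).
fake_alignment <- function(theta, labels = sprintf("ch%02d", seq_len(nrow(theta)))) {
  theta[lower.tri(theta)] <- t(theta)[lower.tri(theta)]
  diag(theta) <- 0
  dimnames(theta) <- list(labels, labels)
  structure(list(theta = theta, eig_indices = 2:4, channel_labels = labels),
            class = "alignment_matrix")
}
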