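#' Oscillatory source model
#'
#' Sources are noisy sinusoids with slowly drifting phase: source `i` is
#' `amplitude_i * sin(2*pi*f_i*t + phi0 + psi(t))` with a random initial
#' phase per trial and `psi` an Ornstein-Uhlenbeck process, which gives a
#' controllable coherence level between coupled sources. A coupling edge
#' `(from, to, lag_ms, strength)` mixes a delayed copy of the *from*
#' source's base oscillation into the *to* source:
#' `x_to = (1 - strength) * own + strength * delay(x_from, lag_ms)`,
#' guaranteeing a nonzero phase lag between the two (with `strength = 1`
#' the target is a pure delayed copy). Edges always read the uncoupled base
#' oscillation of their origin, so listed order does not matter.
#'
#' @param oscillator_freqs oscillation frequency in Hz per source (> 0).
#' @param coupling `NULL` or a data frame with columns `from`, `to`
#'   (source indices), `lag_ms` (>= 0) and `strength` (in `[0, 1]`).
#' @param amplitude scalar or per-source amplitudes.
#' @param noise_sd additive white sensor-noise standard deviation (>= 0),
#'   applied after mixing.
#' @param phase_drift_sd,phase_drift_tau_s Ornstein-Uhlenbeck phase-noise
#'   scale (rad/sqrt(s)) and relaxation time (s).
#' @return A `source_model` object.
#' @export
source_model <- function(oscillator_freqs, coupling = NULL, amplitude = 1,
                         noise_sd = 0, phase_drift_sd = 0.2,
                         phase_drift_tau_s = 0.5) {
  if (length(oscillator_freqs) < 1L || any(oscillator_freqs <= 0)) {
    stopf("`oscillator_freqs` must be positive frequencies in Hz")
  }
  ns <- length(oscillator_freqs)
  amplitude <- rep_len(amplitude, ns)
  if (any(amplitude < 0)) stopf("`amplitude` must be nonnegative")
  if (noise_sd < 0) stopf("`noise_sd` must be >= 0")
  if (!is.null(coupling)) {
    coupling <- as.data.frame(coupling)
    need <- c("from", "to", "lag_ms", "strength")
    if (!all(need %in% names(coupling))) {
      stopf("`coupling` needs columns: %s", paste(need, collapse = ", "))
    }
    if (any(coupling$from < 1L | coupling$from > ns |
            coupling$to < 1L | coupling$to > ns)) {
      stopf("coupling edge endpoints must be source indices in 1..%d", ns)
    }
    if (any(coupling$lag_ms < 0)) stopf("coupling `lag_ms` must be >= 0")
    if (any(coupling$strength < 0 | coupling$strength > 1)) {
      stopf("coupling `strength` must lie in [0, 1]")
    }
  }
  structure(list(n_sources = ns, oscillator_freqs = oscillator_freqs,
                 coupling = coupling, amplitude = amplitude,
                 noise_sd = noise_sd, phase_drift_sd = phase_drift_sd,
                 phase_drift_tau_s = phase_drift_tau_s),
            class = "source_model")
}

#' Instantaneous volume-conduction-like mixing
#'
#' Maps sources to sensors with nonnegative instantaneous weights,
#' emulating the spread of a source through tissue to many sensors at zero
#' lag. By default the weight of source `s` at sensor `c` is a Gaussian
#' kernel of their distance, `exp(-d^2 / (2 * spread_mm^2))` — a simple
#' smooth leadfield surrogate. An explicit `weights` matrix
#' (`sensors x sources`) may be given instead; every sensor must then have
#' at least one positive weight.
#'
#' @param layout a [sensor_layout()] (provides sensor positions and labels).
#' @param source_positions `n_sources x 3` matrix of mm coordinates
#'   (required unless `weights` is given).
#' @param spread_mm spatial decay scale of the kernel in mm (default 40).
#' @param weights optional explicit nonnegative mixing matrix.
#' @return A `mixing_model` with elements `weights`
#'   (`sensors x sources`), `channel_labels`.
#' @export
mixing_model <- function(layout, source_positions = NULL, spread_mm = 40,
                         weights = NULL) {
  stopifnot(inherits(layout, "sensor_layout"))
  if (is.null(weights)) {
    if (is.null(source_positions)) {
      stopf("give either `source_positions` or explicit `weights`")
    }
    sp <- matrix(as.numeric(source_positions), ncol = 3L)
    if (spread_mm <= 0) stopf("`spread_mm` must be positive")
    co <- layout_coords(layout)
    d2 <- outer(rowSums(co^2), rowSums(sp^2), "+") - 2 * co %*% t(sp)
    weights <- exp(-pmax(d2, 0) / (2 * spread_mm^2))
  } else {
    weights <- as.matrix(weights)
    if (nrow(weights) != nrow(layout)) {
      stopf("`weights` must have one row per sensor")
    }
    if (any(weights < 0)) stopf("mixing weights must be nonnegative")
    if (any(rowSums(weights) == 0)) {
      stopf("every sensor needs at least one positive mixing weight")
    }
  }
  structure(list(weights = weights, channel_labels = layout$label),
            class = "mixing_model")
}

# instantaneous phases of the base (uncoupled) oscillations,
# n_sources x n_total; the first (npre) columns are pre-trial history
base_phases <- function(sm, n_total, fs) {
  dt <- 1 / fs
  tt <- (seq_len(n_total) - 1L) * dt
  a <- 1 - dt / sm$phase_drift_tau_s
  P <- matrix(0, sm$n_sources, n_total)
  for (s in seq_len(sm$n_sources)) {
    phi0 <- runif(1, 0, 2 * pi)
    psi <- numeric(n_total)
    if (sm$phase_drift_sd > 0) {
      eps <- rnorm(n_total, 0, sm$phase_drift_sd * sqrt(dt))
      for (k in 2:n_total) psi[k] <- a * psi[k - 1L] + eps[k]
    }
    P[s, ] <- 2 * pi * sm$oscillator_freqs[s] * tt + phi0 + psi
  }
  P
}

# delayed copy of a source over the trial window, by linear interpolation of
# its instantaneous phase (supports lags that are not integer samples)
lagged_signal <- function(P, src, amplitude, npre, ns, fs, lag_s) {
  pos <- npre + seq_len(ns) - lag_s * fs
  i0 <- floor(pos)
  w <- pos - i0
  phase <- (1 - w) * P[src, i0] + w * P[src, pmin(i0 + 1L, ncol(P))]
  amplitude * sin(phase)
}

#' Simulate multi-trial sensor epochs
#'
#' Draws `n_trials` independent trials from a [source_model()]: base
#' oscillations with per-trial random initial phase and drifting phase are
#' coupled along the model's lagged edges, mixed instantaneously onto the
#' sensors of the [mixing_model()], and corrupted with white sensor noise.
#' Identical seeds give bit-identical output. Lagged coupling produces
#' nonzero-phase cross-channel synchrony (visible to iCOH); the
#' instantaneous mixing alone produces only zero-phase synchrony (invisible
#' to iCOH, but strongly correlated).
#'
#' @param sm a [source_model()].
#' @param mm a [mixing_model()].
#' @param n_trials number of trials (>= 1).
#' @param trial_s trial duration in seconds.
#' @param fs sampling rate in Hz; must exceed twice the fastest oscillator.
#' @param seed integer seed.
#' @return An [eeg_epochs()] object (`n_trials x sensors x samples`).
#' @export
simulate_epochs <- function(sm, mm, n_trials, trial_s, fs, seed = 1L) {
  stopifnot(inherits(sm, "source_model"), inherits(mm, "mixing_model"))
  if (ncol(mm$weights) != sm$n_sources) {
    stopf("mixing model has %d source column(s) for %d source(s)",
          ncol(mm$weights), sm$n_sources)
  }
  if (fs <= 2 * max(sm$oscillator_freqs)) {
    stopf("fs = %g Hz must exceed twice the fastest oscillator (%g Hz)",
          fs, max(sm$oscillator_freqs))
  }
  if (n_trials < 1L) stopf("`n_trials` must be >= 1")
  if (trial_s <= 0) stopf("`trial_s` must be positive")
  ns <- round(trial_s * fs)
  max_lag <- if (is.null(sm$coupling)) 0 else max(sm$coupling$lag_ms) / 1000
  npre <- ceiling(max_lag * fs) + 1L
  nc <- nrow(mm$weights)
  dat <- array(NA_real_, c(n_trials, nc, ns))
  with_seed(seed, {
    for (t in seq_len(n_trials)) {
      P <- base_phases(sm, npre + ns, fs)
      X <- sm$amplitude * sin(P[, npre + seq_len(ns), drop = FALSE])
      if (!is.null(sm$coupling)) {
        for (e in seq_len(nrow(sm$coupling))) {
          ed <- sm$coupling[e, ]
          lagged <- lagged_signal(P, ed$from, sm$amplitude[ed$from],
                                  npre, ns, fs, ed$lag_ms / 1000)
          X[ed$to, ] <- (1 - ed$strength) * X[ed$to, ] + ed$strength * lagged
        }
      }
      Y <- mm$weights %*% X
      if (sm$noise_sd > 0) Y <- Y + rnorm(length(Y), 0, sm$noise_sd)
      dat[t, , ] <- Y
    }
  })
  eeg_epochs(dat, fs = fs, channel_labels = mm$channel_labels)
}

#' Cohort specification
#'
#' @param n_subjects number of subjects (>= 1).
#' @param profile `"control_like"` (shared coupling pattern up to jitter)
#'   or `"impaired_like"` (coupling strengths attenuated).
#' @param coupling_attenuation factor in `[0, 1]` multiplying coupling
#'   strengths for `impaired_like` subjects (default 1 = no attenuation).
#' @param between_subject_jitter sd of the per-subject additive
#'   perturbation of coupling strengths (default 0).
#' @param seed integer base seed; subject `i` uses seed `seed + i`.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_subjects, profile = c("control_like", "impaired_like"),
                        coupling_attenuation = 1, between_subject_jitter = 0,
                        seed = 1L) {
  profile <- match.arg(profile)
  if (n_subjects < 1L) stopf("`n_subjects` must be >= 1")
  if (coupling_attenuation < 0 || coupling_attenuation > 1) {
    stopf("`coupling_attenuation` must lie in [0, 1]")
  }
  if (between_subject_jitter < 0) stopf("`between_subject_jitter` must be >= 0")
  structure(list(n_subjects = as.integer(n_subjects), profile = profile,
                 coupling_attenuation = coupling_attenuation,
                 between_subject_jitter = between_subject_jitter,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a cohort of subjects
#'
#' Simulates one [eeg_epochs()] per subject. Control-like subjects share
#' the source model's coupling pattern up to between-subject jitter;
#' impaired-like subjects additionally have every coupling strength
#' multiplied by `coupling_attenuation`. Subject `i`'s epochs (and its
#' strength jitter) are seeded with `spec$seed + i`, so cohorts are fully
#' reproducible from the spec alone.
#'
#' @param spec a [cohort_spec()].
#' @param sm,mm the shared [source_model()] and [mixing_model()].
#' @inheritParams simulate_epochs
#' @return List of [eeg_epochs()] objects, one per subject.
#' @export
generate_cohort <- function(spec, sm, mm, n_trials, trial_s, fs) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(sm, "source_model"))
  lapply(seq_len(spec$n_subjects), function(i) {
    subj_seed <- spec$seed + i
    sm_i <- sm
    if (!is.null(sm$coupling)) {
      s <- sm$coupling$strength
      if (spec$profile == "impaired_like") s <- s * spec$coupling_attenuation
      if (spec$between_subject_jitter > 0) {
        s <- s + with_seed(subj_seed,
                           rnorm(length(s), 0, spec$between_subject_jitter))
      }
      sm_i$coupling$strength <- pmin(1, pmax(0, s))
    }
    simulate_epochs(sm_i, mm, n_trials, trial_s, fs, seed = subj_seed)
  })
}

#' Planted-community connectivity matrix
#'
#' Test fixture: a symmetric nonnegative matrix with `within_w` weights
#' inside communities, `between_w` between them and Gaussian noise of sd
#' `noise_sd` added to the upper triangle (mirrored); negative draws are
#' clipped to 0, draws above 1 to 1, and the diagonal is zero. Eigenvector
#' alignment of such a matrix yields small in-community and large
#' between-community angles.
#'
#' @param n_channels number of channels (>= 2).
#' @param community_assignment community label per channel.
#' @param within_w,between_w weights with `1 >= within_w > between_w >= 0`.
#' @param noise_sd noise sd (>= 0).
#' @param seed integer seed.
#' @return A [connectivity_matrix()] with `measure = "planted"`.
#' @export
planted_connectivity <- function(n_channels, community_assignment, within_w,
                                 between_w, noise_sd = 0, seed = 1L) {
  if (n_channels < 2L) stopf("`n_channels` must be >= 2")
  if (length(community_assignment) != n_channels) {
    stopf("`community_assignment` must have one label per channel")
  }
  if (!(within_w >= between_w && between_w >= 0 && within_w <= 1)) {
    stopf("weights must satisfy 1 >= within_w >= between_w >= 0")
  }
  if (noise_sd < 0) stopf("`noise_sd` must be >= 0")
  same <- outer(community_assignment, community_assignment, "==")
  W <- ifelse(same, within_w, between_w)
  if (noise_sd > 0) {
    idx <- pair_index(n_channels)
    W[idx] <- W[idx] + with_seed(seed, rnorm(nrow(idx), 0, noise_sd))
    W[idx[, c(2L, 1L), drop = FALSE]] <- W[idx]
  }
  W <- pmin(pmax(W, 0), 1)
  diag(W) <- 0
  out <- connectivity_matrix(W, measure = "planted")
  attr(out, "community_assignment") <- community_assignment
  out
}
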