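#' Frequency band specification
#'
#' @param name band name (e.g. `"alpha"`).
#' @param f_lo,f_hi band edges in Hz, `0 <= f_lo < f_hi`. Band membership on
#'   a discrete frequency grid is the closed interval `[f_lo, f_hi]`.
#' @return A `band_spec` object.
#' @seealso [eeg_bands()] for the conventional EEG bands.
#' @export
band_spec <- function(name, f_lo, f_hi) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stopf("band `name` must be a non-empty string")
  }
  if (!(is.numeric(f_lo) && is.numeric(f_hi) && f_lo >= 0 && f_lo < f_hi)) {
    stopf("band edges must satisfy 0 <= f_lo < f_hi")
  }
  structure(list(name = name, f_lo = f_lo, f_hi = f_hi), class = "band_spec")
}

#' Conventional EEG frequency bands
#'
#' Delta 0.1-4 Hz, theta 4-7 Hz, alpha 7-13 Hz and beta 13-30 Hz. On a
#' 0.5 Hz grid the delta band therefore spans the bins 0.5 ... 4 Hz.
#'
#' @return Named list of four [band_spec()] objects.
#' @export
eeg_bands <- function() {
  list(delta = band_spec("delta", 0.1, 4),
       theta = band_spec("theta", 4, 7),
       alpha = band_spec("alpha", 7, 13),
       beta  = band_spec("beta", 13, 30))
}

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("band_spec: %s [%g, %g] Hz\n", x$name, x$f_lo, x$f_hi))
  invisible(x)
}

#' Trial-averaged cross-spectral density
#'
#' Estimates the cross-spectrum between every pair of channels on a regular
#' frequency grid: each trial is demeaned, Hann-tapered and zero-padded to a
#' length giving exactly `resolution_hz` bin spacing; per-trial
#' cross-periodograms are then averaged. Coherency from a single tapered
#' trial is degenerate (its magnitude is identically 1), so at least two
#' trials are required.
#'
#' @param epochs an [eeg_epochs()] object with >= 2 trials.
#' @param resolution_hz frequency grid step in Hz (default 0.5).
#' @return A `cross_spectrum` object: `freqs` (Hz grid from 0 to Nyquist),
#'   `S` (complex `channels x channels x freqs` array, Hermitian at each
#'   frequency), `n_est` (number of averaged estimates), `channel_labels`.
#' @export
estimate_cross_spectra <- function(epochs, resolution_hz = 0.5) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (!is.numeric(resolution_hz) || resolution_hz <= 0) {
    stopf("`resolution_hz` must be positive")
  }
  nt <- n_trials(epochs)
  if (nt < 2L) {
    stopf(paste("cross-spectral estimation needs >= 2 trials: coherency from",
                "a single tapered trial has magnitude identically 1"))
  }
  nc <- n_channels(epochs)
  ns <- n_samples(epochs)
  fs <- epochs$fs

  base <- fs / resolution_hz
  if (abs(base - round(base)) > 1e-8) {
    stopf("fs = %g Hz is not an integer multiple of resolution %g Hz",
          fs, resolution_hz)
  }
  base <- round(base)
  k <- max(1L, ceiling(ns / base))       # pad to k*base, subsample every k-th bin
  npad <- k * base
  bins <- seq(1L, npad %/% 2L + 1L, by = k)
  freqs <- (bins - 1L) * fs / npad

  taper <- 0.5 * (1 - cos(2 * pi * seq_len(ns) / (ns + 1)))
  nf <- length(bins)
  # FFT coefficients at the kept bins, per channel and trial
  X <- array(0 + 0i, c(nf, nc, nt))
  pad <- rep(0, npad - ns)
  for (t in seq_len(nt)) {
    for (c in seq_len(nc)) {
      x <- epochs$data[t, c, ]
      X[, c, t] <- stats::fft(c((x - mean(x)) * taper, pad))[bins]
    }
  }
  S <- array(0 + 0i, c(nc, nc, nf))
  for (b in seq_len(nf)) {
    M <- matrix(X[b, , ], nrow = nc, ncol = nt)
    S[, , b] <- (M %*% Conj(t(M))) / nt
  }
  structure(list(freqs = freqs, S = S, n_est = nt,
                 channel_labels = epochs$channel_labels),
            class = "cross_spectrum")
}

#' @export
print.cross_spectrum <- function(x, ...) {
  cat(sprintf("cross_spectrum: %d channels, %d bins (%g-%g Hz, step %g), %d estimates\n",
              dim(x$S)[1L], length(x$freqs), min(x$freqs), max(x$freqs),
              x$freqs[2L] - x$freqs[1L], x$n_est))
  invisible(x)
}

#' Complex coherency
#'
#' Normalizes the cross-spectrum: `COH_ij(f) = S_ij(f) / sqrt(S_ii(f) S_jj(f))`.
#' The magnitude lies in `[0, 1]` up to numerical tolerance and the phase is
#' the relative lag at that frequency. Frequency bins where any autospectrum
#' is zero are flagged `NA` with a warning and excluded downstream.
#'
#' @param cs a `cross_spectrum` from [estimate_cross_spectra()].
#' @return A `coherency` object: `freqs`, complex array `C`
#'   (`channels x channels x freqs`), `channel_labels`.
#' @export
coherency <- function(cs) {
  stopifnot(inherits(cs, "cross_spectrum"))
  nc <- dim(cs$S)[1L]
  nf <- length(cs$freqs)
  C <- array(NA_complex_, dim(cs$S))
  bad <- logical(nf)
  for (b in seq_len(nf)) {
    auto <- Re(diag(cs$S[, , b]))
    if (any(auto <= 0)) {
      bad[b] <- TRUE
      next
    }
    norm <- sqrt(auto)
    C[, , b] <- cs$S[, , b] / tcrossprod(norm)
  }
  if (any(bad)) {
    warnf("%d frequency bin(s) with zero autospectrum flagged NA and excluded",
          sum(bad))
  }
  structure(list(freqs = cs$freqs, C = C, channel_labels = cs$channel_labels),
            class = "coherency")
}

#' Connectivity matrix
#'
#' Symmetric nonnegative channel-by-channel weights for one measure and one
#' frequency band, with zero diagonal and entries in `[0, 1]`.
#'
#' @param W symmetric numeric matrix.
#' @param measure `"icoh"` or `"correlation_abs"` (or another short label).
#' @param band a [band_spec()] or `NULL`.
#' @param channel_labels channel names (defaults to `rownames(W)`).
#' @return A `connectivity_matrix` object with elements `W`, `measure`,
#'   `band`, `channel_labels`.
#' @export
connectivity_matrix <- function(W, measure, band = NULL, channel_labels = NULL) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stopf("connectivity matrix must be square")
  if (!all(is.finite(W))) stopf("connectivity weights must be finite")
  if (max(abs(W - t(W))) > 1e-8) stopf("connectivity matrix must be symmetric")
  W <- (W + t(W)) / 2
  diag(W) <- 0
  if (min(W) < -1e-12 || max(W) > 1 + 1e-12) {
    stopf("connectivity weights must lie in [0, 1]")
  }
  W[W < 0] <- 0
  W[W > 1] <- 1
  if (is.null(channel_labels)) channel_labels <- rownames(W)
  if (is.null(channel_labels)) channel_labels <- sprintf("ch%02d", seq_len(nrow(W)))
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(W) || anyDuplicated(channel_labels)) {
    stopf("channel labels must be unique and match the matrix dimension")
  }
  dimnames(W) <- list(channel_labels, channel_labels)
  structure(list(W = W, measure = measure, band = band,
                 channel_labels = channel_labels),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("connectivity_matrix: %d channels, measure %s%s\n",
              nrow(x$W), x$measure,
              if (!is.null(x$band)) sprintf(", band %s [%g, %g] Hz",
                                            x$band$name, x$band$f_lo,
                                            x$band$f_hi) else ""))
  invisible(x)
}

#' Band-averaged iCOH connectivity
#'
#' The imaginary part of coherency discards zero- and pi-phase coupling, so
#' instantaneous volume-conducted signal spread does not register while
#' lagged synchrony does. The band weight for a channel pair is the mean of
#' `|Im(COH_ij(f))|` over the grid bins falling in the closed interval
#' `[f_lo, f_hi]`; the diagonal is forced to zero.
#'
#' @param coh a `coherency` object.
#' @param band a [band_spec()]; must overlap the frequency grid.
#' @return A [connectivity_matrix()] with `measure = "icoh"`.
#' @export
icoh_band <- function(coh, band) {
  stopifnot(inherits(coh, "coherency"), inherits(band, "band_spec"))
  sel <- which(coh$freqs >= band$f_lo & coh$freqs <= band$f_hi)
  sel <- sel[apply(coh$C[, , sel, drop = FALSE], 3L,
                   function(m) !anyNA(m))]
  if (length(sel) == 0L) {
    stopf("band '%s' [%g, %g] Hz contains no usable frequency grid bins",
          band$name, band$f_lo, band$f_hi)
  }
  A <- abs(Im(coh$C[, , sel, drop = FALSE]))
  W <- apply(A, c(1L, 2L), mean)
  diag(W) <- 0
  connectivity_matrix(W, measure = "icoh", band = band,
                      channel_labels = coh$channel_labels)
}

#' Band-limited absolute Pearson correlation connectivity
#'
#' Each trial is band-pass filtered with a zero-phase (forward-backward)
#' 4th-order Butterworth filter, the Pearson coefficient is computed per
#' channel pair per trial and averaged across trials, and the absolute value
#' of the trial average is taken so the weights are nonnegative (keeping the
#' leading eigenvector of the matrix Perron-Frobenius). Constant channels
#' have undefined correlations; their pairs are set to 0 with a warning.
#'
#' @param epochs an [eeg_epochs()] object.
#' @param band a [band_spec()] with `f_hi` below the Nyquist frequency.
#' @return A [connectivity_matrix()] with `measure = "correlation_abs"`.
#' @export
correlation_matrix <- function(epochs, band) {
  stopifnot(inherits(epochs, "eeg_epochs"), inherits(band, "band_spec"))
  fs <- epochs$fs
  if (band$f_hi >= fs / 2) {
    stopf("band '%s' upper edge %g Hz is not below Nyquist (%g Hz)",
          band$name, band$f_hi, fs / 2)
  }
  if (n_samples(epochs) < 2L) stopf("need >= 2 samples per trial")
  f_lo <- max(band$f_lo, 1e-4)           # Butterworth band edge must be > 0
  bf <- signal::butter(4, c(f_lo, band$f_hi) / (fs / 2), type = "pass")
  nt <- n_trials(epochs)
  nc <- n_channels(epochs)
  acc <- matrix(0, nc, nc)
  n_const <- 0L
  for (t in seq_len(nt)) {
    raw <- matrix(epochs$data[t, , ], nrow = nc)
    filt <- apply(raw, 1L,
                  function(x) signal::filtfilt(bf, x))   # samples x channels
    sds <- pmin(apply(raw, 1L, stats::sd), apply(filt, 2L, stats::sd))
    r <- suppressWarnings(stats::cor(filt))
    if (any(sds == 0)) {
      n_const <- n_const + 1L
      r[sds == 0, ] <- 0
      r[, sds == 0] <- 0
    }
    acc <- acc + r
  }
  if (n_const > 0L) {
    warnf("constant channel(s) in %d trial(s): undefined correlations set to 0",
          n_const)
  }
  W <- abs(acc / nt)
  diag(W) <- 0
  connectivity_matrix(W, measure = "correlation_abs", band = band,
                      channel_labels = epochs$channel_labels)
}
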