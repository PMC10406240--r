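# k lowest-reference pairs, ties broken deterministically by (row, col)
lowest_pairs <- function(ref, k) {
  idx <- pair_index(nrow(ref))
  v <- ref[idx]
  ord <- order(v, idx[, 1L], idx[, 2L])
  idx[ord[seq_len(k)], , drop = FALSE]
}

#' Erase the weakest-reference connections from a matrix
#'
#' Sets to zero, in `target`, the `k` unordered channel pairs carrying the
#' smallest weights in `reference_icoh` (the connections most likely to be
#' instantaneous activity erased by iCOH). Both triangle entries are zeroed,
#' i.e. `2k` directional edges. Ties in the reference are broken by
#' ascending (row, column) index so the selection is deterministic.
#'
#' @param target [connectivity_matrix()] to alter (e.g. a correlation matrix).
#' @param reference_icoh [connectivity_matrix()] over the same channels whose
#'   smallest values select the pairs (e.g. the matching band iCOH matrix).
#' @param k number of unordered pairs to erase, `0 <= k <= n_pairs`.
#' @return The altered [connectivity_matrix()].
#' @export
erase_lowest <- function(target, reference_icoh, k) {
  stopifnot(inherits(target, "connectivity_matrix"),
            inherits(reference_icoh, "connectivity_matrix"))
  if (!identical(target$channel_labels, reference_icoh$channel_labels)) {
    stopf("target and reference matrices must share the same channels")
  }
  n <- nrow(target$W)
  npairs <- n * (n - 1L) / 2L
  if (k < 0L || k > npairs) stopf("`k` must lie in [0, %d]", npairs)
  W <- target$W
  if (k > 0L) {
    sel <- lowest_pairs(reference_icoh$W, k)
    W[sel] <- 0
    W[sel[, c(2L, 1L), drop = FALSE]] <- 0
  }
  connectivity_matrix(W, measure = target$measure, band = target$band,
                      channel_labels = target$channel_labels)
}

#' Create connections at the weakest pairs of an iCOH matrix
#'
#' Sets the `k` lowest-valued unordered pairs of `icoh` to the maximum
#' off-diagonal entry of the matrix, emulating the restoration of
#' connections that iCOH may have erased. Symmetry is preserved and the
#' matrix maximum is unchanged. An all-zero matrix has maximum 0, so the
#' operation is the identity there (a warning is emitted).
#'
#' @param icoh [connectivity_matrix()] to alter.
#' @param k number of unordered pairs to set, `0 <= k <= n_pairs`.
#' @return The altered [connectivity_matrix()].
#' @export
create_lowest <- function(icoh, k) {
  stopifnot(inherits(icoh, "connectivity_matrix"))
  n <- nrow(icoh$W)
  npairs <- n * (n - 1L) / 2L
  if (k < 0L || k > npairs) stopf("`k` must lie in [0, %d]", npairs)
  W <- icoh$W
  mx <- max(W[upper.tri(W)])
  if (k > 0L) {
    if (mx == 0) {
      warnf("matrix maximum is 0; connection creation is the identity")
    } else {
      sel <- lowest_pairs(W, k)
      W[sel] <- mx
      W[sel[, c(2L, 1L), drop = FALSE]] <- mx
    }
  }
  connectivity_matrix(W, measure = icoh$measure, band = icoh$band,
                      channel_labels = icoh$channel_labels)
}

#' Mean absolute alignment difference (Delta EA)
#'
#' The robustness readout: mean over unordered channel pairs of the absolute
#' difference in alignment angle between two alignment matrices, in degrees.
#' Pairs undefined in either matrix are excluded jointly; it is an error if
#' no defined pair is shared.
#'
#' @param theta_a,theta_b `alignment_matrix` objects over the same channels
#'   and eigenvector ranks.
#' @return Nonnegative scalar, degrees; 0 iff the matrices agree on every
#'   defined pair.
#' @export
delta_ea <- function(theta_a, theta_b) {
  stopifnot(inherits(theta_a, "alignment_matrix"),
            inherits(theta_b, "alignment_matrix"))
  if (!identical(theta_a$channel_labels, theta_b$channel_labels)) {
    stopf("alignment matrices must share the same channels")
  }
  if (!identical(theta_a$eig_indices, theta_b$eig_indices)) {
    stopf("alignment matrices must use the same eigenvector ranks")
  }
  a <- pair_values(theta_a)
  b <- pair_values(theta_b)
  ok <- !(is.na(a) | is.na(b))
  if (!any(ok)) stopf("no channel pair is defined in both alignment matrices")
  mean(abs(a[ok] - b[ok]))
}

#' Sweep of alignment robustness to connection alteration
#'
#' For each alteration percentage, alters `k = round(percent * n_pairs /
#' 100)` connections per subject (rounding half away from zero), recomputes
#' the eigenvector alignment and reports the mean and standard deviation of
#' [delta_ea()] across subjects. Two modes:
#'
#' * `"erase_correlation"` — zero the pairs with the smallest reference iCOH
#'   in the target (correlation) matrix via [erase_lowest()];
#' * `"create_icoh"` — raise the smallest pairs of the target iCOH matrix to
#'   its maximum via [create_lowest()] (the `reference` entry is ignored).
#'
#' @param subjects list of per-subject `list(target = , reference = )`
#'   pairs of [connectivity_matrix()] objects (`reference` may be omitted
#'   for `"create_icoh"`).
#' @param percents alteration percentages in `[0, 100]`.
#' @param mode `"erase_correlation"` or `"create_icoh"`.
#' @param eig_indices eigenvector ranks (default `2:4`).
#' @return A data frame of class `robustness_result`: `mode`, `band`,
#'   `percent`, `k`, `delta_ea_mean`, `delta_ea_sd`, `n_subjects`.
#' @export
robustness_sweep <- function(subjects, percents,
                             mode = c("erase_correlation", "create_icoh"),
                             eig_indices = 2:4) {
  mode <- match.arg(mode)
  if (!is.list(subjects) || length(subjects) == 0L) {
    stopf("`subjects` must be a nonempty list")
  }
  if (any(percents < 0 | percents > 100)) {
    stopf("`percents` must lie in [0, 100]")
  }
  subjects <- lapply(subjects, function(s) {
    if (inherits(s, "connectivity_matrix")) s <- list(target = s)
    stopifnot(inherits(s$target, "connectivity_matrix"))
    if (mode == "erase_correlation" &&
        !inherits(s$reference, "connectivity_matrix")) {
      stopf("mode 'erase_correlation' needs a `reference` iCOH matrix per subject")
    }
    s
  })
  n <- nrow(subjects[[1L]]$target$W)
  npairs <- n * (n - 1L) / 2L
  base_theta <- lapply(subjects, function(s) {
    eigenvector_alignment(s$target, eig_indices)
  })
  band <- subjects[[1L]]$target$band
  band_name <- if (is.null(band)) NA_character_ else band$name
  rows <- lapply(percents, function(pct) {
    k <- floor(pct * npairs / 100 + 0.5)   # round half away from zero
    d <- vapply(seq_along(subjects), function(i) {
      s <- subjects[[i]]
      altered <- if (mode == "erase_correlation") {
        erase_lowest(s$target, s$reference, k)
      } else {
        create_lowest(s$target, k)
      }
      delta_ea(base_theta[[i]], eigenvector_alignment(altered, eig_indices))
    }, numeric(1L))
    data.frame(mode = mode, band = band_name, percent = pct, k = k,
               delta_ea_mean = mean(d),
               delta_ea_sd = if (length(d) > 1L) stats::sd(d) else 0,
               n_subjects = length(subjects), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("robustness_result", "data.frame")
  out
}
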