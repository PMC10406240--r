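# Per-pair values (upper triangle, i < j in column-major order) of a
# connectivity or alignment matrix; names "a|b" from channel labels.
pair_values <- function(x) {
  M <- if (inherits(x, "alignment_matrix")) x$theta
       else if (inherits(x, "connectivity_matrix")) x$W
       else as.matrix(x)
  labels <- rownames(M)
  idx <- pair_index(nrow(M))
  v <- M[idx]
  names(v) <- paste(labels[idx[, 1L]], labels[idx[, 2L]], sep = "|")
  v
}

#' Distribution-preserving randomization of a connectivity matrix
#'
#' Permutes the upper-triangle weights uniformly at random and mirrors them
#' to the lower triangle, leaving the diagonal at zero. The sorted multiset
#' of off-diagonal values is exactly preserved, so the randomized matrix
#' shares the subject's connectivity-value distribution while destroying its
#' structure — the null model used by [build_null_ensemble()].
#'
#' @param W a [connectivity_matrix()].
#' @param seed integer seed; the same seed reproduces the same permutation.
#' @return A [connectivity_matrix()] of the same measure/band/labels.
#' @export
randomize_connectivity <- function(W, seed) {
  stopifnot(inherits(W, "connectivity_matrix"))
  n <- nrow(W$W)
  idx <- pair_index(n)
  v <- W$W[idx]
  perm <- with_seed(seed, sample.int(length(v)))
  R <- matrix(0, n, n)
  R[idx] <- v[perm]
  R <- R + t(R)
  connectivity_matrix(R, measure = W$measure, band = W$band,
                      channel_labels = W$channel_labels)
}

#' Randomized null ensemble with matching alignments
#'
#' Builds `n_null` randomized connectivity matrices by cycling round-robin
#' through the subject matrices of a group (so every subject's value
#' distribution is represented equally, with per-subject counts differing by
#' at most one) and computes the eigenvector alignment of each null with the
#' same eigenvector ranks as used for the subjects. Null `i` derives from
#' subject `((i - 1) mod n_subjects) + 1` with seed `seed + i`.
#'
#' @param group nonempty list of [connectivity_matrix()] objects with
#'   identical channel labels.
#' @param n_null number of null models (default 1000).
#' @param eig_indices eigenvector ranks for the alignments (default `2:4`).
#' @param seed integer base seed.
#' @param keep_matrices keep the randomized matrices themselves (memory
#'   heavy for large ensembles; the per-pair value and angle samples are
#'   always kept).
#' @return A `null_ensemble`: `values` and `thetas` (`n_null x n_pairs`
#'   matrices of connectivity values / alignment angles), `provenance`
#'   (source subject per null), `n_null`, `seed`, `eig_indices`,
#'   `channel_labels`, and `matrices` if requested.
#' @export
build_null_ensemble <- function(group, n_null = 1000L, eig_indices = 2:4,
                                seed = 1L, keep_matrices = FALSE) {
  if (!is.list(group) || length(group) == 0L) {
    stopf("`group` must be a nonempty list of connectivity matrices")
  }
  if (n_null < 1L) stopf("`n_null` must be >= 1")
  labels <- group[[1L]]$channel_labels
  for (g in group) {
    stopifnot(inherits(g, "connectivity_matrix"))
    if (!identical(g$channel_labels, labels)) {
      stopf("all group matrices must share the same channel labels")
    }
  }
  n_sub <- length(group)
  np <- length(labels) * (length(labels) - 1L) / 2L
  values <- matrix(NA_real_, n_null, np)
  thetas <- matrix(NA_real_, n_null, np)
  provenance <- integer(n_null)
  mats <- if (keep_matrices) vector("list", n_null) else NULL
  for (i in seq_len(n_null)) {
    s <- ((i - 1L) %% n_sub) + 1L
    provenance[i] <- s
    R <- randomize_connectivity(group[[s]], seed = seed + i)
    values[i, ] <- pair_values(R)
    thetas[i, ] <- pair_values(eigenvector_alignment(R, eig_indices))
    if (keep_matrices) mats[[i]] <- R
  }
  colnames(values) <- colnames(thetas) <- names(pair_values(group[[1L]]))
  structure(list(values = values, thetas = thetas, provenance = provenance,
                 n_null = n_null, seed = seed, eig_indices = eig_indices,
                 channel_labels = labels, matrices = mats),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("null_ensemble: %d randomized models over %d subject(s), %d pairs, seed %d\n",
              x$n_null, length(unique(x$provenance)), ncol(x$thetas), x$seed))
  invisible(x)
}

#' Per-pair Welch tests of a group against a null ensemble
#'
#' For each unordered channel pair, the group's per-subject values (one per
#' subject) are compared with the null ensemble's values by an
#' unequal-variance t-test (Welch-Satterthwaite degrees of freedom; the
#' Behrens-Fisher setting), two-sided. The p-values are converted to
#' q-values with [bh_fdr()] and a pair is labeled directionally where
#' `q < q_threshold`:
#'
#' * for alignments, *increased* alignment means the subject angles are
#'   significantly **smaller** than the null angles (closer alignment), and
#'   *decreased* means larger;
#' * for connectivity values, *increased* means significantly larger weights.
#'
#' Pairs with undefined values (e.g. alignment angles of zero-norm
#' embeddings) are dropped before testing and do not count toward the FDR
#' family size. Pairs with zero variance in both samples get `p = 1` when
#' the means agree and `p = 0` (flagged degenerate) when they differ.
#'
#' @param group list of per-subject `alignment_matrix` or
#'   [connectivity_matrix()] objects (>= 2 subjects).
#' @param nulls a `null_ensemble` (>= 2 models) over the same channels.
#' @param value `"alignment"` (compare angles; default) or `"connectivity"`
#'   (compare weights directly).
#' @param q_threshold FDR threshold for direction labels (default 0.05).
#' @return A `significance_map`: data frame with `chan_a`, `chan_b`, `t`,
#'   `p`, `q`, `direction` (`increased`/`decreased`/`none`), `degenerate`;
#'   attributes `group_size`, `n_null`, `value`, `q_threshold`,
#'   `n_dropped`, `artificially_expanded`.
#' @export
pairwise_welch_test <- function(group, nulls,
                                value = c("alignment", "connectivity"),
                                q_threshold = 0.05) {
  value <- match.arg(value)
  stopifnot(inherits(nulls, "null_ensemble"))
  if (!is.list(group) || length(group) < 2L) {
    stopf("`group` must contain >= 2 subjects")
  }
  if (nulls$n_null < 2L) stopf("need >= 2 null models")
  labels <- nulls$channel_labels
  wanted <- if (value == "alignment") "alignment_matrix" else "connectivity_matrix"
  X <- do.call(rbind, lapply(group, function(g) {
    if (!inherits(g, wanted)) {
      stopf("`group` elements must be of class %s for value = '%s'",
            wanted, value)
    }
    if (!identical(g$channel_labels, labels)) {
      stopf("group and null ensemble channel labels differ")
    }
    pair_values(g)
  }))
  N <- if (value == "alignment") nulls$thetas else nulls$values

  keep <- !(apply(X, 2L, anyNA) | apply(N, 2L, anyNA))
  n_dropped <- sum(!keep)
  Xk <- X[, keep, drop = FALSE]
  Nk <- N[, keep, drop = FALSE]
  n1 <- nrow(Xk); n2 <- nrow(Nk)
  m1 <- colMeans(Xk); m2 <- colMeans(Nk)
  v1 <- apply(Xk, 2L, stats::var); v2 <- apply(Nk, 2L, stats::var)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  degenerate <- rep(FALSE, length(p))
  zero_se <- se2 == 0
  if (any(zero_se)) {
    eq <- zero_se & (m1 == m2)
    tstat[eq] <- 0; p[eq] <- 1
    ne <- zero_se & (m1 != m2)
    tstat[ne] <- sign(m1[ne] - m2[ne]) * Inf
    p[ne] <- 0
    degenerate[ne] <- TRUE
  }
  q <- bh_fdr(p)
  sig <- q < q_threshold
  higher <- m1 > m2
  direction <- rep("none", length(p))
  if (value == "alignment") {
    direction[sig & !higher] <- "increased"   # smaller angle = closer alignment
    direction[sig & higher] <- "decreased"
  } else {
    direction[sig & higher] <- "increased"
    direction[sig & !higher] <- "decreased"
  }
  idx <- pair_index(length(labels))[keep, , drop = FALSE]
  out <- data.frame(chan_a = labels[idx[, 1L]], chan_b = labels[idx[, 2L]],
                    t = tstat, p = p, q = q, direction = direction,
                    degenerate = degenerate, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "group_size") <- length(group)
  attr(out, "n_null") <- nulls$n_null
  attr(out, "value") <- value
  attr(out, "q_threshold") <- q_threshold
  attr(out, "n_dropped") <- n_dropped
  attr(out, "artificially_expanded") <- isTRUE(attr(group, "artificially_expanded"))
  class(out) <- c("significance_map", "data.frame")
  out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: on sorted p-values,
#' `q_(i) = min_{j >= i} p_(j) * m / j`, mapped back to the original order
#' and capped at 1. Thin wrapper over [stats::p.adjust()] with input
#' validation; discoveries are conventionally `q < 0.05`.
#'
#' @param p vector of p-values in `[0, 1]` (may be empty).
#' @return q-values in the original order.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stopf("p-values must be finite numbers in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Cross-band consistency of significant findings
#'
#' A pair is a *consistent* finding when it is significant with the same
#' direction in at least `min_bands` of the supplied per-band significance
#' maps (default: 3 of the 4 conventional bands). Bands significant in
#' opposite directions do not combine.
#'
#' @param maps named list of `significance_map` objects, one per band, all
#'   over identical channel sets.
#' @param min_bands minimum number of same-direction significant bands
#'   (default 3; must not exceed `length(maps)`).
#' @return A `consistency_set`: data frame with `chan_a`, `chan_b`,
#'   `n_increased`, `n_decreased`, `bands_significant` (comma-joined band
#'   names), `direction` and `consistent`; rows are the pairs significant
#'   in at least one band.
#' @export
consistency_filter <- function(maps, min_bands = 3L) {
  if (!is.list(maps) || length(maps) < min_bands) {
    stopf("need at least `min_bands` (%d) significance maps", min_bands)
  }
  if (is.null(names(maps)) || any(!nzchar(names(maps)))) {
    stopf("`maps` must be a named list (band names)")
  }
  chans <- lapply(maps, function(m) sort(unique(c(m$chan_a, m$chan_b))))
  for (i in seq_along(maps)[-1L]) {
    if (!identical(chans[[i]], chans[[1L]])) {
      stopf("significance maps cover different channel sets ('%s' vs '%s')",
            names(maps)[1L], names(maps)[i])
    }
  }
  tabs <- lapply(names(maps), function(b) {
    m <- maps[[b]]
    m <- m[m$direction != "none", c("chan_a", "chan_b", "direction")]
    if (nrow(m) > 0L) m$band <- b
    m
  })
  all_sig <- do.call(rbind, tabs[vapply(tabs, nrow, 1L) > 0L])
  if (is.null(all_sig) || nrow(all_sig) == 0L) {
    out <- data.frame(chan_a = character(), chan_b = character(),
                      n_increased = integer(), n_decreased = integer(),
                      bands_significant = character(),
                      direction = character(), consistent = logical())
  } else {
    key <- paste(all_sig$chan_a, all_sig$chan_b, sep = "|")
    out <- do.call(rbind, lapply(split(all_sig, key), function(g) {
      ni <- sum(g$direction == "increased")
      nd <- sum(g$direction == "decreased")
      dir <- if (ni >= min_bands && ni >= nd) "increased"
             else if (nd >= min_bands) "decreased"
             else "none"
      data.frame(chan_a = g$chan_a[1L], chan_b = g$chan_b[1L],
                 n_increased = ni, n_decreased = nd,
                 bands_significant = paste(g$band, collapse = ","),
                 direction = dir, consistent = dir != "none",
                 stringsAsFactors = FALSE)
    }))
    out <- out[order(out$chan_a, out$chan_b), ]
    rownames(out) <- NULL
  }
  attr(out, "min_bands") <- as.integer(min_bands)
  attr(out, "n_bands") <- length(maps)
  attr(out, "artificially_expanded") <-
    any(vapply(maps, function(m) isTRUE(attr(m, "artificially_expanded")),
               logical(1L)))
  class(out) <- c("consistency_set", "data.frame")
  out
}

#' Artificial cohort expansion by duplication
#'
#' Repeats each subject's connectivity matrix `factor` times. Duplication
#' inflates the apparent sample size and hence the significance of every
#' downstream test; the output is flagged and every report derived from it
#' carries the flag. Use only as an illustrative device when comparing
#' groups of unequal size.
#'
#' @param group list of [connectivity_matrix()] objects.
#' @param factor repetition factor (>= 1; default 2).
#' @return The expanded list, with attribute `artificially_expanded = TRUE`
#'   when `factor > 1`.
#' @export
expand_cohort <- function(group, factor = 2L) {
  if (!is.list(group)) stopf("`group` must be a list of connectivity matrices")
  if (factor < 1L) stopf("`factor` must be >= 1")
  if (factor == 1L) return(group)
  out <- rep(group, each = as.integer(factor))
  attr(out, "artificially_expanded") <- TRUE
  out
}
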