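#' Embed channels in the space of dominant eigenvectors
#'
#' Channels are placed in a Euclidean space whose axes are selected
#' eigenvectors of the symmetric connectivity matrix; channel `i`'s position
#' vector is `(v_2[i], v_3[i], v_4[i])` for the default selection. For a
#' nonnegative matrix the leading (Perron-Frobenius) eigenvector has entries
#' of a single sign and cannot express network division, so ranks start at 2
#' by default.
#'
#' Eigenvalues are ordered by descending algebraic value by default (for
#' nonnegative weights this puts the Perron-Frobenius vector first);
#' `order = "magnitude"` orders by descending `|lambda|` instead. Each
#' eigenvector's sign is fixed so that its first loading above `1e-8` in
#' absolute value is positive, which makes degenerate and near-degenerate
#' spectra reproducible; alignment angles are invariant to this choice.
#'
#' @param W a [connectivity_matrix()] or symmetric numeric matrix.
#' @param eig_indices ranks of eigenvectors to use (default `2:4`).
#' @param order `"algebraic"` (default) or `"magnitude"` eigenvalue ordering.
#' @return An `eigen_embedding`: `coords` (`channels x k`), `eig_indices`,
#'   `eigenvalues` (the selected ones), `channel_labels`.
#' @export
embed_connectivity <- function(W, eig_indices = 2:4,
                               order = c("algebraic", "magnitude")) {
  order <- match.arg(order)
  labels <- NULL
  if (inherits(W, "connectivity_matrix")) {
    labels <- W$channel_labels
    W <- W$W
  }
  W <- as.matrix(W)
  if (nrow(W) != ncol(W) || !all(is.finite(W))) {
    stopf("`W` must be a square finite matrix")
  }
  if (max(abs(W - t(W))) > 1e-8) stopf("`W` must be symmetric")
  eig_indices <- sort(unique(as.integer(eig_indices)))
  if (length(eig_indices) < 1L || any(eig_indices < 1L)) {
    stopf("`eig_indices` must be positive ranks")
  }
  if (max(eig_indices) > nrow(W)) {
    stopf("requested eigenvector rank %d exceeds matrix dimension %d",
          max(eig_indices), nrow(W))
  }
  ed <- eigen((W + t(W)) / 2, symmetric = TRUE)
  ord <- if (order == "magnitude") {
    order(abs(ed$values), decreasing = TRUE)
  } else {
    seq_along(ed$values)                  # eigen() already sorts descending
  }
  vals <- ed$values[ord][eig_indices]
  V <- ed$vectors[, ord, drop = FALSE][, eig_indices, drop = FALSE]
  # deterministic sign convention per eigenvector
  for (j in seq_len(ncol(V))) {
    lead <- which(abs(V[, j]) > 1e-8)
    if (length(lead) > 0L && V[lead[1L], j] < 0) V[, j] <- -V[, j]
  }
  if (is.null(labels)) labels <- rownames(W)
  if (is.null(labels)) labels <- sprintf("ch%02d", seq_len(nrow(W)))
  rownames(V) <- labels
  structure(list(coords = V, eig_indices = eig_indices, eigenvalues = vals,
                 channel_labels = labels),
            class = "eigen_embedding")
}

#' Pairwise alignment angles of an embedding
#'
#' The alignment angle between channels `i` and `j` is the angle between
#' their position vectors `r` and `s` in the eigenvector-defined space:
#' `theta = acos(r . s / (|r| |s|))`, reported in degrees in `[0, 180]`.
#' Channels whose position vector norm is below `1e-12` have no direction;
#' their angles are flagged `NA` (undefined) rather than zeroed, and an
#' error is raised if every channel is degenerate.
#'
#' @param emb an `eigen_embedding` from [embed_connectivity()].
#' @return An `alignment_matrix`: `theta` (`channels x channels` degrees,
#'   zero diagonal, `NA` where undefined), `eig_indices`, `channel_labels`.
#' @export
alignment_angles <- function(emb) {
  stopifnot(inherits(emb, "eigen_embedding"))
  V <- emb$coords
  nrm <- sqrt(rowSums(V^2))
  ok <- nrm > 1e-12
  if (!any(ok)) stopf("all embedding rows have zero norm; angles undefined")
  U <- V
  U[ok, ] <- V[ok, , drop = FALSE] / nrm[ok]
  cosang <- tcrossprod(U)
  cosang[cosang > 1] <- 1
  cosang[cosang < -1] <- -1
  theta <- acos(cosang) * 180 / pi
  theta[!ok, ] <- NA_real_
  theta[, !ok] <- NA_real_
  diag(theta) <- ifelse(ok, 0, NA_real_)
  dimnames(theta) <- list(emb$channel_labels, emb$channel_labels)
  structure(list(theta = theta, eig_indices = emb$eig_indices,
                 channel_labels = emb$channel_labels),
            class = "alignment_matrix")
}

#' Eigenvector alignment of a connectivity matrix
#'
#' Composition of [embed_connectivity()] and [alignment_angles()]: embeds
#' the channels in the space of the selected dominant eigenvectors (ranks
#' 2-4 by default) and returns all pairwise alignment angles. Small angles
#' mark channels with similar global connectivity patterns — two channels
#' can be closely aligned even when their direct weight is low.
#'
#' @inheritParams embed_connectivity
#' @return An `alignment_matrix` (see [alignment_angles()]).
#' @examples
#' W <- planted_connectivity(12, rep(1:2, each = 6), 0.8, 0.1, 0, seed = 1)
#' A <- eigenvector_alignment(W)
#' A$theta[1, 2] < A$theta[1, 7]   # in-group pairs align more closely
#' @export
eigenvector_alignment <- function(W, eig_indices = 2:4,
                                  order = c("algebraic", "magnitude")) {
  alignment_angles(embed_connectivity(W, eig_indices, order))
}

#' @export
print.alignment_matrix <- function(x, ...) {
  cat(sprintf("alignment_matrix: %d channels, eigenvectors [%s], %d undefined pair(s)\n",
              nrow(x$theta), paste(x$eig_indices, collapse = ","),
              sum(is.na(x$theta[upper.tri(x$theta)]))))
  invisible(x)
}
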