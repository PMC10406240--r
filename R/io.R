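#' Read / write square labelled matrices as TSV
#'
#' Connectivity and alignment matrices are exchanged as tab-separated text
#' with channel labels as the header row and first column.
#'
#' @param x a [connectivity_matrix()] or `alignment_matrix`.
#' @param path file path.
#' @return `write_matrix_tsv()` returns `path` invisibly.
#' @export
write_matrix_tsv <- function(x, path) {
  M <- if (inherits(x, "alignment_matrix")) x$theta
       else if (inherits(x, "connectivity_matrix")) x$W
       else stopf("`x` must be a connectivity or alignment matrix")
  df <- data.frame(label = rownames(M),
                   format(M, digits = 17, scientific = TRUE, trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @param measure,band metadata attached to the matrix on reading
#'   (`read_connectivity_tsv()` only).
#' @export
read_connectivity_tsv <- function(path, measure = "icoh", band = NULL) {
  M <- read_square_tsv(path)
  connectivity_matrix(M, measure = measure, band = band,
                      channel_labels = rownames(M))
}

#' @rdname write_matrix_tsv
#' @param eig_indices eigenvector ranks recorded on the alignment matrix
#'   (`read_alignment_tsv()` only).
#' @export
read_alignment_tsv <- function(path, eig_indices = 2:4) {
  M <- read_square_tsv(path)
  structure(list(theta = M, eig_indices = as.integer(eig_indices),
                 channel_labels = rownames(M)),
            class = "alignment_matrix")
}

read_square_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                         stringsAsFactors = FALSE)
  labels <- as.character(d[[1L]])
  M <- as.matrix(d[, -1L, drop = FALSE])
  if (nrow(M) != ncol(M) || !identical(labels, colnames(M))) {
    stopf("'%s' is not a square labelled matrix TSV", path)
  }
  storage.mode(M) <- "double"
  rownames(M) <- labels
  M
}

#' Write an edge table (significance map, consistency set, sweep) as TSV
#'
#' @param x a data frame (e.g. `significance_map`, `consistency_set` or
#'   `robustness_result`).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_edges_tsv <- function(x, path) {
  stopifnot(is.data.frame(x))
  utils::write.table(as.data.frame(x), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
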