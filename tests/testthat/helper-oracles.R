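# Independent oracles, kept deliberately naive.

# Alignment angles by full eigendecomposition and explicit arccos loops.
ea_oracle <- function(W, eig_indices = 2:4) {
  ed <- eigen(W, symmetric = TRUE)
  V <- ed$vectors[, eig_indices, drop = FALSE]
  n <- nrow(W)
  theta <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      r <- V[i, ] / sqrt(sum(V[i, ]^2))
      s <- V[j, ] / sqrt(sum(V[j, ]^2))
      cosang <- sum(r * s)
      theta[i, j] <- acos(min(1, max(-1, cosang))) * 180 / pi
    }
  }
  diag(theta) <- 0
  theta
}

# Benjamini-Hochberg step-up, written out longhand.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * m / seq_len(m)
  if (m >= 2) {
    for (i in (m - 1):1) q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  }
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# Mean absolute alignment difference by explicit pair loop.
delta_ea_oracle <- function(A, B) {
  n <- nrow(A)
  acc <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) acc <- c(acc, abs(A[i, j] - B[i, j]))
  mean(acc)
}
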