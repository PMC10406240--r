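test_that("randomization preserves the connectivity-value multiset exactly", {
  # constant off-diagonal: any permutation is the identity
  K <- connectivity_matrix(matrix(0.3, 6, 6) - diag(0.3, 6), "icoh")
  expect_equal(randomize_connectivity(K, seed = 1)$W, K$W)

  W <- planted_connectivity(12, rep(1:2, each = 6), 0.8, 0.2, 0.1, seed = 5)
  R1 <- randomize_connectivity(W, seed = 11)
  R2 <- randomize_connectivity(W, seed = 11)
  R3 <- randomize_connectivity(W, seed = 12)
  up <- upper.tri(W$W)
  expect_identical(sort(R1$W[up]), sort(W$W[up]))
  expect_identical(R1$W, R2$W)
  expect_false(identical(R1$W, R3$W))
  expect_identical(R1$W, t(R1$W))
  expect_identical(unname(diag(R1$W)), rep(0, 12))
})

test_that("null ensembles cycle round-robin and their alignments are less structured than the data", {
  W <- planted_connectivity(16, rep(1:2, each = 8), 0.8, 0.1, 0.05, seed = 2)
  ne1 <- build_null_ensemble(list(W), n_null = 3, seed = 7, keep_matrices = TRUE)
  expect_length(ne1$matrices, 3)
  for (i in 1:3) {
    expect_equal(ne1$matrices[[i]]$W,
                 randomize_connectivity(W, seed = 7 + i)$W)
  }

  group <- lapply(1:3, function(i) {
    planted_connectivity(16, rep(1:2, each = 8), 0.8, 0.1, 0.05, seed = i)
  })
  ne <- build_null_ensemble(group, n_null = 8, seed = 1)
  expect_lte(diff(range(table(ne$provenance))), 1)

  # planted structure gives a strongly multimodal angle distribution
  # (structure spanning eigenvector ranks 2-4); nulls do not
  W4 <- planted_connectivity(24, rep(1:4, each = 6), 0.8, 0.1, 0.05, seed = 2)
  ne100 <- build_null_ensemble(list(W4), n_null = 100, seed = 3)
  subj <- eegalign:::pair_values(eigenvector_alignment(W4))
  ks <- suppressWarnings(stats::ks.test(subj, as.vector(ne100$thetas)))
  expect_gt(ks$statistic, 0)
  expect_lt(ks$p.value, 0.01)
})

test_that("Welch tests match the closed form and label directions correctly", {
  labels <- c("a", "b", "c")
  # group identical to nulls: t = 0, p = 1
  th <- matrix(rep(c(40, 90, 120), each = 4), nrow = 4)
  colnames(th) <- c("a|b", "a|c", "b|c")
  group <- lapply(1:4, function(i) {
    fake_alignment(rbind(c(0, 40, 90), c(0, 0, 120), c(0, 0, 0)), labels)
  })
  sig0 <- pairwise_welch_test(group, fake_ensemble(th, labels))
  expect_equal(sig0$t, rep(0, 3))
  expect_equal(sig0$p, rep(1, 3))
  expect_true(all(sig0$direction == "none"))

  # subject angles 20 degrees below a tight null: overwhelming evidence of
  # increased (closer) alignment
  set.seed(21)
  nulls <- matrix(rnorm(1000 * 3, mean = 90, sd = 2), 1000, 3)
  group13 <- lapply(1:13, function(i) {
    a <- 70 + rnorm(3, sd = 2)
    fake_alignment(rbind(c(0, a[1], a[2]), c(0, 0, a[3]), c(0, 0, 0)), labels)
  })
  sig <- pairwise_welch_test(group13, fake_ensemble(nulls, labels))
  expect_true(all(sig$p < 1e-6))
  expect_true(all(sig$direction == "increased"))

  # agreement with stats::t.test per pair
  for (j in 1:3) {
    x <- vapply(group13, function(g) g$theta[c(1, 1, 2)[j], c(2, 3, 3)[j]],
                numeric(1))
    tt <- stats::t.test(x, nulls[, j])
    expect_equal(sig$t[j], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(sig$p[j], tt$p.value, tolerance = 1e-9)
  }

  # zero variance with unequal means: degenerate, p -> 0
  thc <- matrix(90, 10, 3, dimnames = list(NULL, colnames(th)))
  groupc <- lapply(1:3, function(i) {
    fake_alignment(rbind(c(0, 50, 50), c(0, 0, 50), c(0, 0, 0)), labels)
  })
  sigc <- pairwise_welch_test(groupc, fake_ensemble(thc, labels))
  expect_true(all(sigc$degenerate))
  expect_equal(sigc$p, rep(0, 3))
})

test_that("Benjamini-Hochberg adjustment matches the step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_identical(bh_fdr(numeric(0)), numeric(0))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(31)
  for (rep in 1:5) {
    p <- runif(50)^2
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
  }

  # discoveries are monotone in the threshold
  p <- runif(200)^3
  q <- bh_fdr(p)
  expect_true(all(which(q < 0.05) %in% which(q < 0.10)))
})

test_that("consistency requires the same direction in at least min_bands bands", {
  maps <- list(delta = fake_sigmap(c("increased", "none", "decreased")),
               theta = fake_sigmap(c("increased", "none", "decreased")),
               alpha = fake_sigmap(c("increased", "decreased", "increased")),
               beta  = fake_sigmap(c("none", "decreased", "decreased")))
  cs <- consistency_filter(maps, min_bands = 3)
  row <- function(a, b) cs[cs$chan_a == a & cs$chan_b == b, ]
  # A-B: increased in delta, theta, alpha -> consistent increased
  expect_true(row("A", "B")$consistent)
  expect_equal(row("A", "B")$direction, "increased")
  # A-C: significant in only 2 bands -> not consistent
  expect_false(row("A", "C")$consistent)
  # B-C: 2 decreased + 1 increased + 1 decreased = 3 decreased -> consistent
  expect_true(row("B", "C")$consistent)

  # direction split 2-2 is never consistent
  maps2 <- list(delta = fake_sigmap(c("increased", "none", "none")),
                theta = fake_sigmap(c("increased", "none", "none")),
                alpha = fake_sigmap(c("decreased", "none", "none")),
                beta  = fake_sigmap(c("decreased", "none", "none")))
  cs2 <- consistency_filter(maps2, min_bands = 3)
  expect_false(any(cs2$consistent))

  bad <- maps
  bad$beta$chan_a <- c("X", "X", "B")
  expect_error(consistency_filter(bad), "different channel sets")
})

test_that("artificial expansion duplicates subjects and inflates significance", {
  group <- lapply(1:10, function(i) {
    planted_connectivity(12, rep(1:2, each = 6), 0.7, 0.2, 0.1, seed = i)
  })
  expect_identical(expand_cohort(group, 1), group)
  ex <- expand_cohort(group, 2)
  expect_length(ex, 20)
  expect_identical(ex[[1]], ex[[2]])
  expect_true(attr(ex, "artificially_expanded"))

  ne <- build_null_ensemble(group, n_null = 100, seed = 5)
  th <- lapply(group, eigenvector_alignment)
  th_ex <- expand_cohort(th, 2)
  sig <- pairwise_welch_test(th, ne)
  sig_ex <- pairwise_welch_test(th_ex, ne)
  expect_lt(mean(sig_ex$p), mean(sig$p))
  expect_true(attr(sig_ex, "artificially_expanded"))
  expect_false(attr(sig, "artificially_expanded"))
})

test_that("type-I error is controlled when subjects follow the null law", {
  base <- planted_connectivity(14, rep(1:2, each = 7), 0.7, 0.2, 0.15,
                               seed = 99)
  frac <- vapply(1:20, function(rep) {
    subj <- lapply(1:8, function(i) {
      randomize_connectivity(base, seed = 10000 + rep * 100 + i)
    })
    th <- lapply(subj, eigenvector_alignment)
    ne <- build_null_ensemble(subj, n_null = 100, seed = 20000 + rep)
    sig <- pairwise_welch_test(th, ne)
    mean(sig$q < 0.05)
  }, numeric(1))
  se <- stats::sd(frac) / sqrt(length(frac))
  expect_lte(mean(frac), 0.05 + 3 * se)
})
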