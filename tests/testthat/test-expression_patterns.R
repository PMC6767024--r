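test_that("pairwise_call applies the Welch test and fold-change gate", {
  expect_equal(pairwise_call(c(10, 10, 10), c(10, 10, 10))$call, "similar")
  # reference Welch t on log2 values
  a <- c(100, 110, 90); b <- c(10, 11, 9)
  ref_p <- t.test(log2(a + 0.1), log2(b + 0.1), var.equal = FALSE)$p.value
  res <- pairwise_call(a, b)
  expect_equal(res$p, ref_p)
  expect_lt(res$p, 0.05)
  expect_equal(res$call, "higher")
  # tiny p but fold change below the gate -> similar
  res2 <- pairwise_call(c(100, 101, 99), c(60, 61, 59))
  expect_lt(res2$p, 0.05)
  expect_equal(res2$call, "similar")
  expect_error(pairwise_call(c(1), c(1, 2)), "replicates")
  # all-zero both sides: similar with p = 1
  res3 <- pairwise_call(c(0, 0, 0), c(0, 0, 0))
  expect_equal(res3$call, "similar")
  expect_equal(res3$p, 1)
})

test_that("reversing the groups flips higher/lower and preserves similar", {
  set.seed(11)
  for (i in 1:50) {
    a <- rlnorm(3, meanlog = runif(1, 0, 6), sdlog = 0.3)
    b <- rlnorm(3, meanlog = runif(1, 0, 6), sdlog = 0.3)
    ab <- pairwise_call(a, b)$call
    ba <- pairwise_call(b, a)$call
    expected <- switch(ab, higher = "lower", lower = "higher", "similar")
    expect_equal(ba, expected)
  }
})

test_that("an externally supplied p-value replaces the Welch test", {
  a <- c(100, 110, 90); b <- c(10, 11, 9)
  expect_equal(pairwise_call(a, b, p_value = 0.9)$call, "similar")
  expect_equal(pairwise_call(a, b, p_value = 1e-6)$call, "higher")
})

test_that("classify_gene implements the joint decision over both hybrids", {
  mk <- function(...) {
    v <- c(...)
    names(v) <- c("parent1.parent2", "parent1.hybrid1", "parent1.hybrid2",
                  "parent2.hybrid1", "parent2.hybrid2", "hybrid1.hybrid2")
    v
  }
  # P1 = H1 = H2 > P2 -> C5 higher-parent dominance
  r <- classify_gene(mk("higher", "similar", "similar", "lower", "lower", "similar"))
  expect_equal(r$cluster, "C5")
  expect_equal(r$category, "higher-parent dominance")
  # both hybrids above both parents -> C9
  r <- classify_gene(mk("similar", "lower", "lower", "lower", "lower", "similar"))
  expect_equal(r$cluster, "C9")
  expect_equal(r$category, "up-overdominance")
  # all similar -> unclassified
  r <- classify_gene(mk("similar", "similar", "similar", "similar", "similar", "similar"))
  expect_equal(r$cluster, "unclassified")
  # conflicting hybrids (H1 over, H2 additive-ish) -> unclassified
  r <- classify_gene(mk("higher", "lower", "similar", "lower", "lower", "higher"))
  expect_equal(r$cluster, "unclassified")
  expect_error(classify_gene(c(parent1.parent2 = "higher")), "missing pairwise call")
})

test_that("zero-noise classification equals the mean-ordering oracle on exhaustive grids", {
  grid <- c(1, 2, 4, 8, 16)
  combos <- expand.grid(p1 = grid, p2 = grid, h1 = grid, h2 = grid)
  ems <- em_from_means(1, 1, 1, 1, n_genes = nrow(combos))
  # build one matrix with all combinations as genes
  vals <- ems$values
  for (r in seq_len(nrow(combos)))
    vals[r, ] <- rep(as.numeric(combos[r, c("p1", "p2", "h1", "h2")]), each = 3)
  em <- expression_matrix(vals, ems$design)
  got <- classify_matrix(em)
  want <- mapply(ordering_oracle, combos$p1, combos$p2, combos$h1, combos$h2)
  expect_equal(got$cluster, unname(want))
})

test_that("classify_matrix and classify_gene agree gene by gene", {
  lm <- generate_expression(simulation_config(n_genes = 60, seed = 9))
  asg <- classify_matrix(lm$matrix)
  pairs <- combn(c("parent1", "parent2", "hybrid1", "hybrid2"), 2)
  design <- lm$matrix$design
  for (i in seq(1, 60, by = 7)) {
    calls <- character(ncol(pairs))
    names(calls) <- paste(pairs[1, ], pairs[2, ], sep = ".")
    for (k in seq_len(ncol(pairs))) {
      va <- lm$matrix$values[i, design$sample_id[design$genotype_role == pairs[1, k]]]
      vb <- lm$matrix$values[i, design$sample_id[design$genotype_role == pairs[2, k]]]
      calls[k] <- pairwise_call(va, vb)$call
    }
    expect_equal(classify_gene(calls)$cluster, asg$cluster[i])
  }
})

test_that("calls and assignments are invariant to a global scale factor", {
  lm <- generate_expression(simulation_config(n_genes = 100, seed = 5))
  a1 <- classify_matrix(lm$matrix)
  # scale the matrix and the pseudocount together (log2 FC is then unchanged)
  em2 <- expression_matrix(lm$matrix$values * 7, lm$matrix$design)
  a2 <- classify_matrix(em2, pseudocount = 0.7)
  expect_equal(a1$cluster, a2$cluster)
})

test_that("summarize_patterns partitions genes and computes the three fraction bases", {
  clusters <- c(rep("C5", 30), rep("C9", 10), rep("C1", 20), rep("unclassified", 40))
  s <- summarize_patterns(clusters)
  expect_equal(s$n_genes, 100)
  expect_equal(sum(s$cluster_counts), 100)
  expect_equal(s$n_classified, 60)
  expect_equal(s$n_non_additive, 40)
  f <- s$category_fractions
  expect_equal(f$pct_of_all[f$category == "higher-parent dominance"], 30)
  expect_equal(f$pct_of_non_additive[f$category == "higher-parent dominance"], 75)
  expect_equal(f$pct_of_classified[f$category == "additive"], 100 * 20 / 60)
  # all unclassified: fractions zero, no division error
  s0 <- summarize_patterns(rep("unclassified", 5))
  expect_equal(s0$n_non_additive, 0)
  expect_true(all(s0$category_fractions$pct_of_all[
    s0$category_fractions$category != "unclassified"] == 0))
})

test_that("2^-ddCt relative expression follows the defining arithmetic", {
  expect_equal(delta_delta_ct(20, 18, 20, 18), 1)   # calibrator itself
  expect_equal(delta_delta_ct(21, 18, 20, 18), 0.5) # one extra cycle
  expect_equal(delta_delta_ct(20, 18, 24, 18), 16)
  expect_error(delta_delta_ct(Inf, 18, 24, 18), "finite")
})
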