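# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Brute-force upper-tail hypergeometric probability by direct enumeration of
# the sampling distribution.
hyper_tail_bruteforce <- function(overlap, term_size, query_size, background_size) {
  ks <- overlap:min(term_size, query_size)
  sum(choose(term_size, ks) * choose(background_size - term_size, query_size - ks)) /
    choose(background_size, query_size)
}

# Mean-ordering oracle for the zero-noise classifier: classifies a gene
# directly from its four true group means, where "A above B" requires the
# pseudocounted mean ratio to reach the fold threshold (with zero replicate
# noise any difference in means is statistically certain).
ordering_oracle <- function(p1, p2, h1, h2, fc_min = 2, pc = 0.1) {
  above <- function(a, b) a != b && (a + pc) / (b + pc) >= fc_min
  same <- function(a, b) !above(a, b) && !above(b, a)
  if (above(h1, p1) && above(h1, p2) && above(h2, p1) && above(h2, p2)) return("C9")
  if (above(p1, h1) && above(p2, h1) && above(p1, h2) && above(p2, h2)) return("C10")
  if (same(p1, p2)) return("unclassified")
  hi <- if (above(p1, p2)) p1 else p2
  lo <- if (above(p1, p2)) p2 else p1
  p1_high <- above(p1, p2)
  if (same(h1, hi) && same(h2, hi) && !same(h1, lo) && !same(h2, lo))
    return(if (p1_high) "C5" else "C6")
  if (same(h1, lo) && same(h2, lo) && !same(h1, hi) && !same(h2, hi))
    return(if (p1_high) "C7" else "C8")
  if (above(hi, h1) && above(h1, lo) && above(hi, h2) && above(h2, lo)) {
    if (p1_high) return(if (same(h1, h2)) "C2" else "C1")
    return(if (same(h1, h2)) "C4" else "C3")
  }
  "unclassified"
}

# Build a noise-free ExpressionMatrix from four group means.
em_from_means <- function(p1, p2, h1, h2, nrep = 3, n_genes = 1) {
  means <- c(parent1 = p1, parent2 = p2, hybrid1 = h1, hybrid2 = h2)
  samples <- paste(rep(names(means), each = nrep), 1:nrep, sep = "_")
  vals <- matrix(rep(rep(means, each = nrep), times = n_genes),
                 nrow = n_genes, byrow = TRUE,
                 dimnames = list(paste0("g", seq_len(n_genes)), samples))
  design <- data.frame(sample_id = samples,
                       genotype_role = rep(names(means), each = nrep),
                       replicate = rep(1:nrep, 4))
  expression_matrix(vals, design)
}

# Category of a planted class label ("none" plants no regulation).
truth_category <- function(cls) {
  map <- c(C1 = "additive", C2 = "additive", C3 = "additive", C4 = "additive",
           C5 = "higher-parent dominance", C6 = "higher-parent dominance",
           C7 = "lower-parent dominance", C8 = "lower-parent dominance",
           C9 = "up-overdominance", C10 = "down-overdominance",
           none = "unclassified")
  unname(map[cls])
}
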