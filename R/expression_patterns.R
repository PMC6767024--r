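#' @title Expression-level dominance classification
#' @name expression_patterns
#' @description
#' Genes in a two-parent / two-hybrid design are assigned to one of ten
#' pattern classes from six statistical pairwise comparisons among the four
#' genotype groups: C1-C4 additive (hybrids between the parents), C5-C6
#' higher-parent dominance, C7-C8 lower-parent dominance, C9 up-regulated
#' overdominance (hybrids above both parents), C10 down-regulated
#' overdominance. "Higher"/"lower" means statistically different (two-sided
#' Welch t-test on log2(x + pseudocount), p < alpha) AND mean fold change
#' >= fc_min.
NULL

ROLES <- c("parent1", "parent2", "hybrid1", "hybrid2")

CLUSTER_LEVELS <- c(paste0("C", 1:10), "unclassified")

CATEGORY_OF_CLUSTER <- c(
  C1 = "additive", C2 = "additive", C3 = "additive", C4 = "additive",
  C5 = "higher-parent dominance", C6 = "higher-parent dominance",
  C7 = "lower-parent dominance", C8 = "lower-parent dominance",
  C9 = "up-overdominance", C10 = "down-overdominance",
  unclassified = "unclassified")

# Welch t-test p-value from group summaries; handles zero-variance groups:
# both variances zero -> p = 0 if means differ else 1 (noise-free data).
welch_p <- function(m1, v1, n1, m2, v2, n2) {
  se2 <- v1 / n1 + v2 / n2
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  t <- (m1 - m2) / sqrt(se2)
  p <- 2 * stats::pt(-abs(t), df)
  degenerate <- se2 == 0
  p[degenerate] <- ifelse(m1[degenerate] == m2[degenerate], 1, 0)
  p
}

#' Pairwise statistical call between two genotype groups
#'
#' Two-sided Welch t-test on log2(value + pseudocount) combined with a fold
#' change gate on the (pseudocounted) group means. The call is `higher` iff
#' p < alpha and mean_a/mean_b >= fc_min, `lower` iff p < alpha and
#' mean_b/mean_a >= fc_min, otherwise `similar`.
#'
#' @param values_a,values_b Numeric replicate vectors (each >= 2 values,
#'   non-negative).
#' @param alpha Significance threshold (default 0.05).
#' @param fc_min Minimal fold change for a differential call (default 2).
#' @param pseudocount Added before log2 and to the means for the fold change,
#'   to handle zeros (default 0.1).
#' @param p_value Optional externally computed p-value (e.g. from a count
#'   model such as DESeq); when supplied it replaces the Welch p-value and
#'   only the fold-change gate is applied on top.
#' @return A list with `call` ("higher", "lower" or "similar"), `log2_fc`
#'   (log2 of pseudocounted mean ratio a/b) and `p`.
#' @export
pairwise_call <- function(values_a, values_b, alpha = 0.05, fc_min = 2,
                          pseudocount = 0.1, p_value = NULL) {
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("each group needs >= 2 replicates")
  if (any(values_a < 0) || any(values_b < 0))
    stop("expression values must be non-negative")
  la <- log2(values_a + pseudocount); lb <- log2(values_b + pseudocount)
  p <- if (is.null(p_value)) {
    welch_p(mean(la), stats::var(la), length(la),
            mean(lb), stats::var(lb), length(lb))
  } else p_value
  ratio <- (mean(values_a) + pseudocount) / (mean(values_b) + pseudocount)
  call <- "similar"
  if (p < alpha && ratio >= fc_min) call <- "higher"
  if (p < alpha && 1 / ratio >= fc_min) call <- "lower"
  list(call = call, log2_fc = log2(ratio), p = p)
}

# Decide the cluster from the six pairwise calls given as a named character
# vector with names "A.B" for ordered pairs; cmp(A, B) returns the call of A
# relative to B.
classify_from_calls <- function(cmp) {
  gt <- function(a, b) cmp(a, b) == "higher"
  lt <- function(a, b) cmp(a, b) == "lower"
  eq <- function(a, b) cmp(a, b) == "similar"

  # (1) both hybrids above both parents
  if (gt("hybrid1", "parent1") && gt("hybrid1", "parent2") &&
      gt("hybrid2", "parent1") && gt("hybrid2", "parent2")) return("C9")
  # (2) both hybrids below both parents
  if (lt("hybrid1", "parent1") && lt("hybrid1", "parent2") &&
      lt("hybrid2", "parent1") && lt("hybrid2", "parent2")) return("C10")

  if (eq("parent1", "parent2")) return("unclassified")
  hi <- if (gt("parent1", "parent2")) "parent1" else "parent2"
  lo <- setdiff(c("parent1", "parent2"), hi)

  # (3) higher-parent dominance: hybrids sit on the high parent
  if (eq("hybrid1", hi) && eq("hybrid2", hi) &&
      !eq("hybrid1", lo) && !eq("hybrid2", lo))
    return(if (hi == "parent1") "C5" else "C6")
  # (4) lower-parent dominance: hybrids sit on the low parent
  if (eq("hybrid1", lo) && eq("hybrid2", lo) &&
      !eq("hybrid1", hi) && !eq("hybrid2", hi))
    return(if (hi == "parent1") "C7" else "C8")
  # (5) additive: each hybrid strictly between the parents
  if (lt("hybrid1", hi) && gt("hybrid1", lo) &&
      lt("hybrid2", hi) && gt("hybrid2", lo)) {
    ordered <- !eq("hybrid1", "hybrid2")
    if (hi == "parent1") return(if (ordered) "C1" else "C2")
    return(if (ordered) "C3" else "C4")
  }
  "unclassified"
}

#' Classify one gene from its six pairwise calls
#'
#' @param calls Named list or character vector of calls for the six unordered
#'   genotype pairs, named `"A.B"` with roles among parent1, parent2,
#'   hybrid1, hybrid2 (either orientation); each call is the comparison of A
#'   relative to B ("higher", "lower", "similar").
#' @return A list with `cluster` (C1..C10 or "unclassified") and `category`.
#' @export
classify_gene <- function(calls) {
  calls <- unlist(calls)
  cmp <- function(a, b) {
    k1 <- paste(a, b, sep = "."); k2 <- paste(b, a, sep = ".")
    if (k1 %in% names(calls)) return(calls[[k1]])
    if (k2 %in% names(calls)) {
      v <- calls[[k2]]
      return(switch(v, higher = "lower", lower = "higher", "similar"))
    }
    stop(sprintf("missing pairwise call for pair %s vs %s", a, b))
  }
  # require all six pairs up front
  for (i in 1:3) for (j in (i + 1):4) cmp(ROLES[i], ROLES[j])
  cl <- classify_from_calls(cmp)
  list(cluster = cl, category = unname(CATEGORY_OF_CLUSTER[cl]))
}

# vectorised call matrix for one ordered pair across all genes
vector_calls <- function(mlog, vlog, mraw, n, a, b, alpha, fc_min, pseudocount) {
  p <- welch_p(mlog[, a], vlog[, a], n[a], mlog[, b], vlog[, b], n[b])
  ratio <- (mraw[, a] + pseudocount) / (mraw[, b] + pseudocount)
  call <- rep("similar", nrow(mlog))
  call[p < alpha & ratio >= fc_min] <- "higher"
  call[p < alpha & (1 / ratio) >= fc_min] <- "lower"
  list(call = call, log2_fc = log2(ratio), p = p)
}

#' Classify every gene of an expression matrix
#'
#' Applies [pairwise_call()] logic to all six genotype pairs for every gene,
#' then assigns the pattern cluster and category.
#'
#' @param em An `ExpressionMatrix` as returned by [expression_matrix()] or
#'   [read_expression()].
#' @param alpha,fc_min,pseudocount See [pairwise_call()].
#' @return Data frame with one row per gene: `gene_id`, `cluster`,
#'   `category`, plus `call`, `log2_fc` and `p` columns for the six pairs
#'   (e.g. `call.hybrid1.parent1`).
#' @export
classify_matrix <- function(em, alpha = 0.05, fc_min = 2, pseudocount = 0.1) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  x <- em$values
  design <- em$design
  lmat <- log2(x + pseudocount)

  groups <- lapply(ROLES, function(r) design$sample_id[design$genotype_role == r])
  names(groups) <- ROLES
  n <- vapply(groups, length, 1L)
  if (any(n < 2)) stop("every genotype role needs >= 2 replicates")

  mlog <- sapply(ROLES, function(r) rowMeans(lmat[, groups[[r]], drop = FALSE]))
  vlog <- sapply(ROLES, function(r) apply(lmat[, groups[[r]], drop = FALSE], 1, stats::var))
  mraw <- sapply(ROLES, function(r) rowMeans(x[, groups[[r]], drop = FALSE]))
  if (nrow(x) == 1L) {  # sapply drops to vector for a single gene
    mlog <- matrix(mlog, 1, dimnames = list(NULL, ROLES))
    vlog <- matrix(vlog, 1, dimnames = list(NULL, ROLES))
    mraw <- matrix(mraw, 1, dimnames = list(NULL, ROLES))
  }

  pairs <- t(utils::combn(ROLES, 2))
  callmat <- matrix("", nrow(x), nrow(pairs))
  extras <- list()
  for (k in seq_len(nrow(pairs))) {
    a <- pairs[k, 1]; b <- pairs[k, 2]
    vc <- vector_calls(mlog, vlog, mraw, n, a, b, alpha, fc_min, pseudocount)
    callmat[, k] <- vc$call
    extras[[paste("call", a, b, sep = ".")]] <- vc$call
    extras[[paste("log2_fc", a, b, sep = ".")]] <- vc$log2_fc
    extras[[paste("p", a, b, sep = ".")]] <- vc$p
  }
  colnames(callmat) <- paste(pairs[, 1], pairs[, 2], sep = ".")

  clusters <- vapply(seq_len(nrow(x)), function(i) {
    calls <- stats::setNames(callmat[i, ], colnames(callmat))
    cmp <- function(a, b) {
      k1 <- paste(a, b, sep = ".")
      if (k1 %in% names(calls)) return(calls[[k1]])
      v <- calls[[paste(b, a, sep = ".")]]
      switch(v, higher = "lower", lower = "higher", "similar")
    }
    classify_from_calls(cmp)
  }, "")

  out <- data.frame(gene_id = em$gene_ids, cluster = clusters,
                    category = unname(CATEGORY_OF_CLUSTER[clusters]),
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(extras, optional = TRUE))
}

#' Summarise pattern assignments
#'
#' Counts and fractions per cluster and per category. Non-additive means
#' clusters C5-C10. Fractions are reported against three denominators: all
#' genes, classified genes (any C1-C10) and non-additive genes.
#'
#' @param assignments Data frame with columns `cluster` and `category` (as
#'   from [classify_matrix()]), or a character vector of clusters.
#' @return A list with `n_genes`, `cluster_counts`, `category_counts`,
#'   `n_classified`, `n_additive`, `n_non_additive`, and data frame
#'   `category_fractions` with fractions of all / classified / non-additive
#'   genes per category.
#' @export
summarize_patterns <- function(assignments) {
  cl <- if (is.data.frame(assignments)) assignments$cluster else assignments
  if (length(cl) == 0) stop("no assignments given")
  cl <- factor(cl, levels = CLUSTER_LEVELS)
  if (anyNA(cl)) stop("unknown cluster label")
  cluster_counts <- table(cl)
  cat <- factor(unname(CATEGORY_OF_CLUSTER[as.character(cl)]),
                levels = unique(unname(CATEGORY_OF_CLUSTER)))
  category_counts <- table(cat)
  non_additive_clusters <- paste0("C", 5:10)
  n_non_add <- sum(cluster_counts[non_additive_clusters])
  n_classified <- sum(cluster_counts[paste0("C", 1:10)])
  n <- length(cl)

  cats <- levels(cat)
  counts <- as.numeric(category_counts[cats])
  frac <- function(den) if (den > 0) counts / den * 100 else rep(0, length(counts))
  non_add_counts <- counts
  non_add_counts[cats %in% c("additive", "unclassified")] <- NA
  category_fractions <- data.frame(
    category = cats, count = counts,
    pct_of_all = frac(n),
    pct_of_classified = ifelse(cats == "unclassified", NA,
                               if (n_classified > 0) counts / n_classified * 100 else 0),
    pct_of_non_additive = if (n_non_add > 0) non_add_counts / n_non_add * 100
                          else ifelse(is.na(non_add_counts), NA, 0),
    stringsAsFactors = FALSE)

  list(n_genes = n,
       cluster_counts = cluster_counts,
       category_counts = category_counts,
       n_classified = n_classified,
       n_additive = as.numeric(category_counts["additive"]),
       n_non_additive = n_non_add,
       category_fractions = category_fractions)
}

#' Relative qPCR expression by the 2^-ddCt method
#'
#' ddCt = (Ct_target,test - Ct_ref,test) - (Ct_target,cal - Ct_ref,cal);
#' relative expression of the target in the test sample, normalised to the
#' reference gene and the calibrator sample, is 2^-ddCt.
#'
#' @param ct_target_test,ct_ref_test Ct of target and reference gene in the
#'   test sample (cycles).
#' @param ct_target_cal,ct_ref_cal Ct of target and reference gene in the
#'   calibrator sample.
#' @return Relative expression (fold, dimensionless).
#' @examples
#' delta_delta_ct(20, 18, 24, 18) # 16
#' @export
delta_delta_ct <- function(ct_target_test, ct_ref_test, ct_target_cal, ct_ref_cal) {
  cts <- c(ct_target_test, ct_ref_test, ct_target_cal, ct_ref_cal)
  if (any(!is.finite(cts))) stop("Ct values must be finite")
  if (any(cts <= 0)) stop("Ct values must be positive")
  ddct <- (ct_target_test - ct_ref_test) - (ct_target_cal - ct_ref_cal)
  2^-ddct
}
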