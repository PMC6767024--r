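#' @title Synthetic data with known ground truth
#' @name synthetic_data
#' @description
#' Generators for labeled expression matrices (genes planted in the ten
#' dominance/additivity pattern classes), volatile tables with known MPV/OPV,
#' and term-to-gene maps, so every analysis stage can be validated against
#' ground truth without any external data.
NULL

# group-mean multipliers (units of baseline) per planted class, in role order
# parent1, parent2, hybrid1, hybrid2; `f` is the effect fold.
class_mean_multipliers <- function(f) {
  list(
    C1   = c(f^3, 1, f^2, f),    # P1 > H1 > H2 > P2
    C2   = c(f^2, 1, f, f),      # P1 > H1 = H2 > P2
    C3   = c(1, f^3, f, f^2),    # P2 > H2 > H1 > P1
    C4   = c(1, f^2, f, f),      # P2 > H1 = H2 > P1
    C5   = c(f, 1, f, f),        # hybrids on the high parent (P1 high)
    C6   = c(1, f, f, f),        # hybrids on the high parent (P2 high)
    C7   = c(f, 1, 1, 1),        # hybrids on the low parent (P1 high)
    C8   = c(1, f, 1, 1),        # hybrids on the low parent (P2 high)
    C9   = c(1, 1, f, f),        # both hybrids above both parents
    C10  = c(f, f, 1, 1),        # both hybrids below both parents
    none = c(1, 1, 1, 1))
}

#' Simulation configuration
#'
#' @param n_genes Number of genes to simulate.
#' @param class_proportions Named numeric vector over
#'   `c("C1".."C10", "none")` summing to 1; classes omitted get 0. Default:
#'   0.08 for each of C1-C10 and 0.2 unregulated ("none").
#' @param baseline_mean Baseline group mean in expression units (default 50).
#' @param effect_fold True fold separation between "different" group means
#'   (default 4; must be >= 2).
#' @param replicate_cv Coefficient of variation of the multiplicative
#'   log-normal replicate noise, in (0, 1); use 0 for noise-free data.
#' @param n_replicates Replicates per genotype (>= 2, default 3).
#' @param seed Integer seed; all draws flow from one generator seeded here.
#' @return A `SimulationConfig` list (validated).
#' @export
simulation_config <- function(n_genes = 2000,
                              class_proportions = NULL,
                              baseline_mean = 50,
                              effect_fold = 4,
                              replicate_cv = 0.05,
                              n_replicates = 3,
                              seed = 1) {
  classes <- c(paste0("C", 1:10), "none")
  if (is.null(class_proportions))
    class_proportions <- stats::setNames(c(rep(0.08, 10), 0.2), classes)
  props <- stats::setNames(numeric(length(classes)), classes)
  bad <- setdiff(names(class_proportions), classes)
  if (length(bad)) stop(sprintf("unknown pattern class '%s'", bad[1]))
  props[names(class_proportions)] <- class_proportions
  if (abs(sum(props) - 1) > 1e-9)
    stop("class proportions must sum to 1")
  if (any(props < 0)) stop("class proportions must be non-negative")
  if (n_genes < 1) stop("n_genes must be positive")
  if (baseline_mean <= 0) stop("baseline_mean must be positive")
  if (effect_fold < 2)
    warning("effect_fold below the default fold-change threshold (2); planted classes will not be recoverable")
  if (replicate_cv < 0 || replicate_cv >= 1)
    stop("replicate_cv must be in [0, 1)")
  if (n_replicates < 2) stop("n_replicates must be >= 2 (pairwise tests undefined otherwise)")
  structure(list(n_genes = as.integer(n_genes), class_proportions = props,
                 baseline_mean = baseline_mean, effect_fold = effect_fold,
                 replicate_cv = replicate_cv,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

# log-normal draws with mean `m` and coefficient of variation `cv`
rlnorm_cv <- function(n, m, cv) {
  if (cv == 0) return(rep_len(m, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a labeled expression matrix
#'
#' Genes are planted in the ten pattern classes (plus unregulated "none") at
#' the configured proportions; group means follow each class's ordering with
#' the configured fold separation, and replicates are log-normal around the
#' group means with the configured CV. Deterministic given the seed.
#'
#' @param config A `SimulationConfig` from [simulation_config()].
#' @return A list of class `LabeledMatrix` with elements `matrix` (an
#'   [expression_matrix()]) and `truth` (named character vector gene -> class).
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  mult <- class_mean_multipliers(config$effect_fold)
  counts <- round(config$class_proportions * config$n_genes)
  # fix rounding drift on the largest class
  drift <- config$n_genes - sum(counts)
  counts[which.max(counts)] <- counts[which.max(counts)] + drift
  truth <- rep(names(counts), times = counts)

  nrep <- config$n_replicates
  samples <- paste(rep(ROLES, each = nrep), rep(seq_len(nrep), 4), sep = "_")
  design <- data.frame(sample_id = samples,
                       genotype_role = rep(ROLES, each = nrep),
                       replicate = rep(seq_len(nrep), 4),
                       stringsAsFactors = FALSE)

  drawn <- with_seed(config$seed, {
    truth <- sample(truth)  # shuffle class blocks over gene ids
    vals <- matrix(0, config$n_genes, length(samples))
    for (i in seq_len(config$n_genes)) {
      means <- mult[[truth[i]]] * config$baseline_mean
      vals[i, ] <- rlnorm_cv(length(samples), rep(means, each = nrep),
                             config$replicate_cv)
    }
    list(vals = vals, truth = truth)
  })
  vals <- drawn$vals
  truth <- drawn$truth
  gene_ids <- sprintf("gene_%05d", seq_len(config$n_genes))
  dimnames(vals) <- list(gene_ids, samples)
  structure(list(matrix = expression_matrix(vals, design),
                 truth = stats::setNames(truth, gene_ids)),
            class = "LabeledMatrix")
}

#' Generate a volatile table with known heterosis
#'
#' Each compound class is given true per-genotype mean concentrations; the
#' replicate concentrations are log-normal around those means, so the true
#' MPV/OPV of every class sum is known by construction.
#'
#' @param per_class_means Named list: class -> numeric vector of positive
#'   means `c(parent1, parent2, hybrid1, hybrid2)` (or named with those
#'   roles). One compound per class is generated per entry unless
#'   `n_compounds` is set.
#' @param cv Coefficient of variation of replicate noise (0 for noise-free).
#' @param n_replicates Replicates per genotype (default 3).
#' @param seed Integer seed.
#' @param n_compounds Compounds per class (true class means are split evenly
#'   across compounds; default 1).
#' @return Data frame with columns `compound`, `class`, `genotype`,
#'   `replicate`, `concentration`, with attribute `true_means` (the input).
#' @export
generate_volatile_table <- function(per_class_means, cv = 0.05,
                                    n_replicates = 3, seed = 1,
                                    n_compounds = 1) {
  stopifnot(is.list(per_class_means), length(per_class_means) >= 1)
  roles <- c("parent1", "parent2", "hybrid1", "hybrid2")
  out <- with_seed(seed, {
    rows <- list()
    for (cl in names(per_class_means)) {
      m <- per_class_means[[cl]]
      if (!is.null(names(m))) m <- m[roles]
      if (length(m) != 4 || any(!is.finite(m)) || any(m <= 0))
        stop(sprintf("class '%s': need 4 positive genotype means", cl))
      for (j in seq_len(n_compounds)) {
        cmp_means <- m / n_compounds
        for (g in seq_along(roles)) {
          conc <- rlnorm_cv(n_replicates, cmp_means[g], cv)
          rows[[length(rows) + 1]] <- data.frame(
            compound = sprintf("%s_cmp%d", cl, j), class = cl,
            genotype = roles[g], replicate = seq_len(n_replicates),
            concentration = conc, stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })
  attr(out, "true_means") <- per_class_means
  out
}

#' Generate a term-to-gene map with a planted enriched term
#'
#' @param background Character vector of background gene ids.
#' @param n_terms Number of terms.
#' @param term_size Genes per term (sampled from the background).
#' @param seed Integer seed.
#' @return A `TermMap` as from [term_map()].
#' @export
generate_term_map <- function(background, n_terms = 20, term_size = 15, seed = 1) {
  stopifnot(length(background) > term_size)
  terms <- with_seed(seed, {
    lapply(seq_len(n_terms), function(i) sample(background, term_size))
  })
  names(terms) <- sprintf("TERM:%04d", seq_len(n_terms))
  term_map(terms, background,
           term_names = stats::setNames(sprintf("synthetic term %d", seq_len(n_terms)),
                                        names(terms)))
}

# evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
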