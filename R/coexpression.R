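#' @title SOM co-expression modules and correlation screening
#' @name coexpression
#' @description
#' A deterministic batch self-organizing map clusters z-scored genotype-mean
#' expression profiles into a small grid of modules; transcription factors
#' sharing a module with anchor pathway genes are candidate regulators, and
#' Pearson correlation with exact small-n p-values quantifies their
#' association.
NULL

som_grid_coords <- function(rows, cols) {
  # unit index increases column-fastest: unit (r, c) -> (r-1)*cols + c
  cbind(row = rep(seq_len(rows), each = cols),
        col = rep(seq_len(cols), times = rows))
}

#' Train a batch self-organizing map
#'
#' Batch SOM with a Gaussian neighborhood whose radius decays linearly from
#' `radius0` (in grid units) to zero over the epochs, so the final epochs
#' reduce to a k-means refinement. The codebook is initialized by
#' farthest-point sampling of the input profiles: the first unit is a
#' profile drawn with the run seed and each further unit is the profile
#' farthest from all units chosen so far. This spreads the initial codebook
#' over the data so well-separated expression clusters are not folded onto a
#' single unit, and training is fully deterministic given inputs and seed.
#'
#' @param profiles Numeric matrix, rows = genes (row names = gene ids),
#'   columns = profile dimensions (e.g. z-scored genotype means).
#' @param rows,cols Grid dimensions (default 2 x 4 = 8 modules).
#' @param epochs Training epochs (default 50).
#' @param seed Integer seed for codebook initialization.
#' @param radius0 Initial neighborhood radius in grid units (default 0.6:
#'   adjacent units receive about a quarter of the central weight at the
#'   start of training, keeping the map locally ordered without letting the
#'   early smoothing collapse distinct clusters).
#' @return A `SomModel`: list with `codebook` (units x dims), `grid`
#'   (rows, cols), unit coordinates, `qe` (per-epoch mean quantization
#'   error), and the training metadata.
#' @export
train_som <- function(profiles, rows = 2, cols = 4, epochs = 50, seed = 1,
                      radius0 = 0.6) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 1) stop("no profiles to cluster")
  if (ncol(profiles) < 2) stop("profile dimension must be >= 2")
  if (any(!is.finite(profiles))) {
    bad <- rownames(profiles)[!stats::complete.cases(profiles) |
                                apply(!is.finite(profiles), 1, any)][1]
    stop(sprintf("non-finite profile for gene %s", bad))
  }
  stopifnot(rows >= 1, cols >= 1, epochs >= 1)
  n_units <- rows * cols
  coords <- som_grid_coords(rows, cols)
  # squared grid distances between units
  gd2 <- as.matrix(stats::dist(coords))^2

  # farthest-point init: seeded first pick, then maximin spread
  codebook <- with_seed(seed, {
    idx <- sample(nrow(profiles), 1)
    while (length(idx) < n_units) {
      d2 <- unit_distances2(profiles, profiles[idx, , drop = FALSE])
      cand <- which.max(apply(d2, 1, min))
      idx <- c(idx, cand)
    }
    profiles[idx, , drop = FALSE]
  })
  rownames(codebook) <- NULL

  qe <- numeric(epochs)
  for (e in seq_len(epochs)) {
    d2 <- unit_distances2(profiles, codebook)
    bmu <- max.col(-d2, ties.method = "first")
    qe[e] <- mean(sqrt(d2[cbind(seq_len(nrow(profiles)), bmu)]))
    radius <- radius0 * (1 - (e - 1) / epochs)
    h <- exp(-gd2 / (2 * max(radius, 1e-9)^2))      # units x units
    w <- h[, bmu, drop = FALSE]                     # units x genes
    denom <- rowSums(w)
    upd <- (w %*% profiles) / denom
    nonzero <- denom > 0
    codebook[nonzero, ] <- upd[nonzero, , drop = FALSE]
  }
  structure(list(codebook = codebook, grid = c(rows = rows, cols = cols),
                 coords = coords, qe = qe,
                 meta = list(epochs = epochs, radius0 = radius0, seed = seed)),
            class = "SomModel")
}

# squared Euclidean distances, genes x units
unit_distances2 <- function(profiles, codebook) {
  pn <- rowSums(profiles^2)
  cn <- rowSums(codebook^2)
  d2 <- outer(pn, cn, "+") - 2 * profiles %*% t(codebook)
  pmax(d2, 0)
}

#' Assign genes to their best-matching SOM unit
#'
#' Each gene maps to the unit with minimal Euclidean distance to its
#' profile; ties break to the lowest unit index.
#'
#' @param model A `SomModel` from [train_som()].
#' @param profiles Numeric matrix of profiles (columns must match the
#'   codebook dimension), row names = gene ids.
#' @return A `ModuleAssignment`: list with `unit` (named integer vector
#'   gene -> unit index), `module` (named character "Cluster_<row>_<col>")
#'   and `counts` (per-unit member counts).
#' @export
assign_modules <- function(model, profiles) {
  stopifnot(inherits(model, "SomModel"))
  profiles <- as.matrix(profiles)
  if (ncol(profiles) != ncol(model$codebook))
    stop("profile dimension does not match codebook")
  d2 <- unit_distances2(profiles, model$codebook)
  unit <- max.col(-d2, ties.method = "first")
  names(unit) <- rownames(profiles)
  module <- sprintf("Cluster_%d_%d", model$coords[unit, "row"],
                    model$coords[unit, "col"])
  names(module) <- rownames(profiles)
  counts <- tabulate(unit, nbins = nrow(model$codebook))
  structure(list(unit = unit, module = module, counts = counts),
            class = "ModuleAssignment")
}

#' Transcription factors sharing a module with anchor genes
#'
#' For each anchor gene (e.g. a volatile-pathway structural gene) returns the
#' transcription factors assigned to the same SOM unit. Empty sets are
#' legitimate (an anchor can sit in a module with no TF).
#'
#' @param assignment A `ModuleAssignment` from [assign_modules()].
#' @param anchors Character vector of anchor gene ids (must be assigned).
#' @param tf_ids Character vector of transcription-factor gene ids.
#' @return Named list: anchor -> character vector of co-module TF ids.
#' @export
co_module_candidates <- function(assignment, anchors, tf_ids) {
  stopifnot(inherits(assignment, "ModuleAssignment"))
  missing <- setdiff(anchors, names(assignment$unit))
  if (length(missing))
    stop(sprintf("anchor %s is not in the module assignment", missing[1]))
  tf_ids <- intersect(tf_ids, names(assignment$unit))
  out <- lapply(anchors, function(a) {
    u <- assignment$unit[[a]]
    mates <- names(assignment$unit)[assignment$unit == u]
    setdiff(intersect(mates, tf_ids), a)
  })
  stats::setNames(out, anchors)
}

#' Two-sided p-value for a Pearson correlation
#'
#' Uses the exact t transformation t = r * sqrt(n - 2) / sqrt(1 - r^2) with
#' n - 2 degrees of freedom, valid for small n.
#'
#' @param r Pearson correlation coefficient in [-1, 1].
#' @param n Number of paired observations (>= 3).
#' @return Two-sided p-value.
#' @examples
#' correlation_p(0.978, 4) # 0.022
#' @export
correlation_p <- function(r, n) {
  if (any(n < 3)) stop("need n >= 3 observations")
  if (any(abs(r) > 1)) stop("|r| must be <= 1")
  p <- ifelse(abs(r) == 1, 0, {
    t <- r * sqrt(n - 2) / sqrt(1 - r^2)
    2 * stats::pt(-abs(t), df = n - 2)
  })
  unname(p)
}

#' Pairwise Pearson correlation matrix with p-values
#'
#' @param profiles Numeric matrix, rows = entities (genes/TFs/traits),
#'   columns = observations (all the same length n >= 3).
#' @return A `CorrelationMatrix`: list with `r` (symmetric, unit diagonal),
#'   `p` (two-sided via [correlation_p()], diagonal 0) and `n`.
#' @export
correlation_matrix <- function(profiles) {
  profiles <- as.matrix(profiles)
  n <- ncol(profiles)
  if (n < 3) stop("need >= 3 observations per entity")
  r <- stats::cor(t(profiles))
  r <- pmin(pmax(r, -1), 1)
  p <- matrix(correlation_p(as.vector(r), n), nrow(r), ncol(r),
              dimnames = dimnames(r))
  diag(p) <- 0
  structure(list(r = r, p = p, n = n, ids = rownames(profiles)),
            class = "CorrelationMatrix")
}

#' Long-format export of a correlation matrix
#'
#' @param cm A `CorrelationMatrix`.
#' @return Data frame with columns `a`, `b`, `r`, `p`, `n` for each unordered
#'   pair.
#' @export
correlation_long <- function(cm) {
  stopifnot(inherits(cm, "CorrelationMatrix"))
  ids <- cm$ids
  idx <- which(upper.tri(cm$r), arr.ind = TRUE)
  data.frame(a = ids[idx[, 1]], b = ids[idx[, 2]],
             r = cm$r[idx], p = cm$p[idx], n = cm$n,
             stringsAsFactors = FALSE)
}
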