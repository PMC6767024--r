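#' Construct an ExpressionMatrix
#'
#' Lightweight container for a genes x samples non-negative expression matrix
#' (FPKM-like) with a sample design mapping each sample to a genotype role
#' (parent1, parent2, hybrid1, hybrid2) and a replicate index.
#'
#' @param values Numeric matrix, genes in rows, samples in columns; column
#'   names are sample ids, row names gene ids.
#' @param design Data frame with columns `sample_id`, `genotype_role`,
#'   `replicate` covering every column of `values`.
#' @return An object of class `ExpressionMatrix`: a list with `values`
#'   (matrix), `gene_ids`, `sample_ids`, `design`.
#' @export
expression_matrix <- function(values, design) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values))) stop("values must have gene ids as row names")
  if (is.null(colnames(values))) stop("values must have sample ids as column names")
  if (anyDuplicated(rownames(values)))
    stop(sprintf("duplicate gene id: %s",
                 rownames(values)[duplicated(rownames(values))][1]))
  if (anyNA(values)) stop("missing expression values are not allowed")
  if (any(values < 0)) stop("expression values must be non-negative")
  stopifnot(is.data.frame(design),
            all(c("sample_id", "genotype_role", "replicate") %in% names(design)))
  design$sample_id <- as.character(design$sample_id)
  design$genotype_role <- as.character(design$genotype_role)
  if (!setequal(design$sample_id, colnames(values)))
    stop("design sample ids must match matrix column names")
  bad_roles <- setdiff(design$genotype_role, ROLES)
  if (length(bad_roles))
    stop(sprintf("unknown genotype role: %s", bad_roles[1]))
  missing_roles <- setdiff(ROLES, design$genotype_role)
  if (length(missing_roles))
    stop(sprintf("role %s absent from sample sheet",
                 paste(missing_roles, collapse = ", ")))
  reps <- table(design$genotype_role)
  if (any(reps < 2))
    stop("every genotype role needs >= 2 replicates")
  design <- design[match(colnames(values), design$sample_id), , drop = FALSE]
  rownames(design) <- NULL
  structure(list(values = values,
                 gene_ids = rownames(values),
                 sample_ids = colnames(values),
                 design = design),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  print(table(x$design$genotype_role))
  invisible(x)
}

#' Per-genotype mean expression profiles
#'
#' @param em An `ExpressionMatrix`.
#' @param genes Optional subset of gene ids.
#' @param zscore If TRUE (default), z-score each gene's 4-genotype profile
#'   (mean 0, sd 1); genes with zero profile variance get an all-zero profile.
#' @return Numeric matrix, genes x genotype roles.
#' @export
genotype_profiles <- function(em, genes = NULL, zscore = TRUE) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  x <- em$values
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(x))
    if (length(missing)) stop(sprintf("unknown gene id: %s", missing[1]))
    x <- x[genes, , drop = FALSE]
  }
  prof <- sapply(ROLES, function(r) {
    cols <- em$design$sample_id[em$design$genotype_role == r]
    rowMeans(x[, cols, drop = FALSE])
  })
  if (nrow(x) == 1L) prof <- matrix(prof, 1, dimnames = list(rownames(x), ROLES))
  if (zscore) {
    mu <- rowMeans(prof)
    s <- apply(prof, 1, stats::sd)
    prof <- (prof - mu) / ifelse(s == 0, 1, s)
  }
  prof
}
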