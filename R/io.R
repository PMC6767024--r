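#' Read an expression matrix and sample sheet from TSV
#'
#' The matrix TSV has gene ids in the first column and sample ids as the
#' header; the sample sheet TSV has columns `sample_id`, `genotype_role`,
#' `replicate`. Validation covers the four genotype roles, duplicate gene
#' ids and non-numeric cells.
#'
#' @param matrix_path Path to the expression TSV.
#' @param sample_sheet_path Path to the sample sheet TSV.
#' @return An `ExpressionMatrix`.
#' @export
read_expression <- function(matrix_path, sample_sheet_path) {
  raw <- utils::read.delim(matrix_path, check.names = FALSE,
                           colClasses = "character", sep = "\t")
  if (ncol(raw) < 2) stop("expression TSV needs a gene id column plus samples")
  gene_ids <- raw[[1]]
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup)) stop(sprintf("duplicate gene id: %s", dup[1]))
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric expression value at gene %s, sample %s",
                 gene_ids[bad[1]], colnames(vals)[bad[2]]))
  }
  dimnames(num) <- list(gene_ids, colnames(vals))
  sheet <- utils::read.delim(sample_sheet_path, sep = "\t",
                             stringsAsFactors = FALSE)
  expression_matrix(num, sheet)
}

#' Write an expression matrix (and its sample sheet) to TSV
#'
#' @param em An `ExpressionMatrix`.
#' @param matrix_path,sample_sheet_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_expression <- function(em, matrix_path, sample_sheet_path) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  df <- data.frame(gene_id = em$gene_ids, em$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(em$design, sample_sheet_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(matrix_path, sample_sheet_path))
}

#' Write a generic table to TSV
#' @param df Data frame.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a one-id-per-line gene list
#' @param path Path to the file.
#' @return Character vector of ids.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  trimws(x[nzchar(trimws(x))])
}

#' Validate a pipeline run configuration
#'
#' @param alpha Significance threshold in (0, 1).
#' @param fc_min Fold-change threshold (>= 1).
#' @param pseudocount Pseudocount added before log2 (>= 0).
#' @param som_rows,som_cols,som_epochs SOM settings (used when co-expression
#'   screening is requested).
#' @param seed Integer seed.
#' @return Validated `RunConfig` list.
#' @export
run_config <- function(alpha = 0.05, fc_min = 2, pseudocount = 0.1,
                       som_rows = 2, som_cols = 4, som_epochs = 50, seed = 1) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  if (fc_min < 1) stop("fc_min must be >= 1")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (som_epochs < 1) stop("epochs must be >= 1")
  if (som_rows < 1 || som_cols < 1) stop("SOM grid must have >= 1 unit")
  structure(list(alpha = alpha, fc_min = fc_min, pseudocount = pseudocount,
                 som_rows = as.integer(som_rows), som_cols = as.integer(som_cols),
                 som_epochs = as.integer(som_epochs), seed = as.integer(seed)),
            class = "RunConfig")
}

#' Run the full analysis pipeline on an expression matrix
#'
#' Chains pattern classification, pattern summary, optional SOM co-module
#' screening of F1-upregulated genes (categories C5, C6, C9), optional
#' correlation matrix of anchor + TF profiles and optional ORA, writing all
#' result TSVs plus a JSON run manifest into `out_dir`. Identical inputs and
#' config give identical outputs.
#'
#' @param em An `ExpressionMatrix`.
#' @param out_dir Output directory (created if needed).
#' @param config A `RunConfig` from [run_config()].
#' @param anchors,tf_ids Optional gene id vectors enabling the SOM co-module
#'   and correlation stages.
#' @param tm Optional `TermMap` enabling ORA of the non-additive gene set.
#' @return Invisibly, a list with the stage results (`assignments`,
#'   `summary`, and when enabled `som`, `modules`, `candidates`,
#'   `correlations`, `enrichment`).
#' @export
run_pipeline <- function(em, out_dir, config = run_config(),
                         anchors = NULL, tf_ids = NULL, tm = NULL) {
  stopifnot(inherits(em, "ExpressionMatrix"), inherits(config, "RunConfig"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()

  message(sprintf("classify: %d genes, %d samples",
                  length(em$gene_ids), length(em$sample_ids)))
  res$assignments <- classify_matrix(em, alpha = config$alpha,
                                     fc_min = config$fc_min,
                                     pseudocount = config$pseudocount)
  write_tsv(res$assignments, file.path(out_dir, "pattern_assignments.tsv"))

  res$summary <- summarize_patterns(res$assignments)
  write_tsv(res$summary$category_fractions,
            file.path(out_dir, "pattern_summary.tsv"))
  message(sprintf("summary: %d classified, %d non-additive of %d genes",
                  res$summary$n_classified, res$summary$n_non_additive,
                  res$summary$n_genes))

  if (!is.null(anchors)) {
    up_ids <- res$assignments$gene_id[
      res$assignments$cluster %in% c("C5", "C6", "C9")]
    keep <- union(intersect(up_ids, em$gene_ids), anchors)
    message(sprintf("som: %d F1-upregulated genes (+%d anchors)",
                    length(up_ids), length(anchors)))
    prof <- genotype_profiles(em, genes = keep, zscore = TRUE)
    res$som <- train_som(prof, rows = config$som_rows, cols = config$som_cols,
                         epochs = config$som_epochs, seed = config$seed)
    res$modules <- assign_modules(res$som, prof)
    write_tsv(data.frame(gene_id = names(res$modules$module),
                         module = unname(res$modules$module),
                         unit = unname(res$modules$unit)),
              file.path(out_dir, "som_modules.tsv"))
    write_tsv(as.data.frame(res$som$codebook),
              file.path(out_dir, "som_codebook.tsv"))
    if (!is.null(tf_ids)) {
      res$candidates <- co_module_candidates(res$modules, anchors, tf_ids)
      cand_df <- do.call(rbind, lapply(names(res$candidates), function(a) {
        tfs <- res$candidates[[a]]
        data.frame(anchor = a,
                   tf = if (length(tfs)) tfs else NA_character_,
                   stringsAsFactors = FALSE)
      }))
      write_tsv(cand_df, file.path(out_dir, "co_module_tfs.tsv"))
      ids <- union(anchors, unlist(res$candidates))
      if (length(ids) >= 2) {
        res$correlations <- correlation_matrix(
          genotype_profiles(em, genes = ids, zscore = FALSE))
        write_tsv(correlation_long(res$correlations),
                  file.path(out_dir, "correlations.tsv"))
      }
    }
  }

  if (!is.null(tm)) {
    non_add <- res$assignments$gene_id[
      res$assignments$category %in% c("higher-parent dominance",
                                      "lower-parent dominance",
                                      "up-overdominance", "down-overdominance")]
    message(sprintf("ora: %d non-additive query genes", length(non_add)))
    res$enrichment <- ora(intersect(non_add, tm$background), tm)
    write_tsv(res$enrichment, file.path(out_dir, "enrichment.tsv"))
  }

  manifest <- list(
    package = "teaheterosis",
    version = as.character(utils::packageVersion("teaheterosis")),
    n_genes = length(em$gene_ids),
    samples = em$design,
    config = unclass(config),
    stages = names(res))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}
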