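#' Construct a term-to-gene map
#'
#' @param terms Named list: term id -> character vector of member gene ids.
#' @param background Character vector: the gene universe. Every term member
#'   must belong to it.
#' @param term_names Optional named character vector of human-readable term
#'   names.
#' @return A `TermMap` list with `terms`, `background`, `term_names`.
#' @export
term_map <- function(terms, background, term_names = NULL) {
  stopifnot(is.list(terms), length(terms) >= 1, !is.null(names(terms)))
  background <- unique(as.character(background))
  terms <- lapply(terms, function(g) unique(as.character(g)))
  outside <- unlist(lapply(terms, function(g) setdiff(g, background)))
  if (length(outside))
    stop(sprintf("term member '%s' is not in the background", outside[1]))
  if (is.null(term_names))
    term_names <- stats::setNames(names(terms), names(terms))
  structure(list(terms = terms, background = background,
                 term_names = term_names),
            class = "TermMap")
}

#' Read a GMT-format term map
#'
#' GMT: one term per line, tab-separated: term id, description, members...
#'
#' @param path Path to the GMT file.
#' @param background Gene universe; defaults to the union of all term
#'   members.
#' @return A `TermMap`.
#' @export
read_gmt <- function(path, background = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(fields, `[[`, "", 1)
  descs <- vapply(fields, function(f) if (length(f) >= 2) f[[2]] else "", "")
  members <- lapply(fields, function(f) if (length(f) >= 3) f[-(1:2)] else character())
  if (is.null(background)) background <- unique(unlist(members))
  term_map(stats::setNames(members, ids), background,
           term_names = stats::setNames(descs, ids))
}

#' Upper-tail hypergeometric p-value for a term overlap
#'
#' P(X >= overlap) where X ~ Hypergeometric(background_size, term_size,
#' query_size): the probability of drawing at least `overlap` term members
#' when sampling `query_size` genes without replacement from the background.
#'
#' @param overlap Observed overlap between query and term.
#' @param term_size Number of term member genes.
#' @param query_size Number of query genes.
#' @param background_size Size of the gene universe.
#' @return One-sided (enrichment) p-value.
#' @export
hypergeom_tail <- function(overlap, term_size, query_size, background_size) {
  if (any(overlap < 0) || any(overlap > pmin(term_size, query_size)))
    stop("overlap must be between 0 and min(term_size, query_size)")
  if (any(term_size > background_size) || any(query_size > background_size))
    stop("term and query cannot exceed the background")
  stats::phyper(overlap - 1, term_size, background_size - term_size,
                query_size, lower.tail = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment: adj_i = min over ranks j >= rank(i) of (m/j) p_(j),
#' clipped at 1; the output is in the input order.
#'
#' @param pvalues Numeric vector of p-values in [0, 1].
#' @return Adjusted values, same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) stop("empty p-value list")
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must be in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Over-representation analysis of a gene set
#'
#' One row per term with at least `min_term_size` members: overlap count
#' ("gene ratio"), upper-tail hypergeometric p-value and BH FDR over all
#' tested terms, sorted by ascending p.
#'
#' @param query Character vector of query gene ids; ids outside the
#'   background are dropped with a message.
#' @param tm A `TermMap`.
#' @param min_term_size Smallest term tested (default 2).
#' @return Data frame with columns `term_id`, `term_name`, `gene_ratio`,
#'   `term_size`, `p`, `fdr`.
#' @export
ora <- function(query, tm, min_term_size = 2) {
  stopifnot(inherits(tm, "TermMap"))
  query <- unique(as.character(query))
  if (length(query) == 0) stop("empty query gene set")
  dropped <- setdiff(query, tm$background)
  if (length(dropped)) {
    message(sprintf("dropping %d query gene(s) not in the background", length(dropped)))
    query <- intersect(query, tm$background)
    if (length(query) == 0) stop("no query genes remain in the background")
  }
  sizes <- vapply(tm$terms, length, 1L)
  keep <- names(tm$terms)[sizes >= min_term_size]
  if (length(keep) == 0) stop("no terms of at least min_term_size members")
  N <- length(tm$background)
  q <- length(query)
  rows <- lapply(keep, function(id) {
    members <- tm$terms[[id]]
    k <- length(intersect(query, members))
    data.frame(term_id = id,
               term_name = unname(tm$term_names[id]),
               gene_ratio = k, term_size = length(members),
               p = hypergeom_tail(k, length(members), q, N),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$fdr <- bh_adjust(res$p)
  res <- res[order(res$p, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
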