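# Tab-separated readers/writers, prior-score transforms, source merging,
# and differential-expression preselection.

#' Read an expression matrix
#'
#' Expects tab-separated text: first column gene identifiers, header row
#' of sample identifiers, numeric body (genes in rows).
#'
#' @param path file path.
#' @return numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression file needs a gene column and data")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicated gene identifier(s): ",
         paste(utils::head(unique(ids[duplicated(ids)]), 5), collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m) || anyNA(m))
    stop("expression body must be numeric with no missing values")
  rownames(m) <- ids
  m
}

#' Write an expression matrix
#'
#' @param x matrix with genes in rows.
#' @param path destination file.
#' @param id_column header name for the gene-id column.
#' @export
write_expression <- function(x, path, id_column = "gene") {
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a prior-pair table
#'
#' Tab-separated with header \code{gene_a gene_b score source}; scores
#' are raw database scores transformed by
#' \code{\link{transform_prior_score}} downstream, or ready probabilities
#' with source "probability".
#'
#' @param path file path.
#' @return data frame of raw prior records.
#' @export
read_prior_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("gene_a", "gene_b", "score", "source")
  if (!all(need %in% names(df)))
    stop("prior table must have columns: ", paste(need, collapse = ", "))
  df
}

#' Transform a raw prior score to an enforcement probability
#'
#' Source-specific maps into (0, 1):
#' \itemize{
#'   \item \code{ppi_lpr}: protein-interaction reliability via the lpr
#'     ("lowest PMID re-use") score — low lpr means low-throughput, more
#'     reliable evidence. Maps x to sigmoid(1/x); lpr = 1 gives 0.73. An
#'     lpr of 0 is mapped to 0.5 (the non-informative midpoint; the
#'     inverse is undefined there).
#'   \item \code{tf_score}: transcription-factor binding prediction
#'     score, mapped by sigmoid(score).
#'   \item \code{seq_similarity}: percent sequence identity (0-100); a
#'     raw sigmoid saturates immediately, so a centred, scaled sigmoid
#'     sigmoid(scale * (score - center)) is used (defaults 0.1 and 50).
#'   \item \code{probability}: passed through unchanged.
#' }
#'
#' @param score numeric score(s).
#' @param source one of "ppi_lpr", "tf_score", "seq_similarity",
#'   "probability".
#' @param similarity_scale,similarity_center parameters of the
#'   sequence-similarity sigmoid.
#' @return probabilities the same length as \code{score}.
#' @export
transform_prior_score <- function(score,
                                  source = c("ppi_lpr", "tf_score",
                                             "seq_similarity", "probability"),
                                  similarity_scale = 0.1,
                                  similarity_center = 50) {
  source <- match.arg(source)
  switch(source,
    ppi_lpr = {
      if (any(score < 0)) stop("lpr scores must be non-negative")
      ifelse(score == 0, 0.5, stats::plogis(1 / score))
    },
    tf_score = stats::plogis(score),
    seq_similarity = stats::plogis(similarity_scale *
                                     (score - similarity_center)),
    probability = {
      if (any(score < 0 | score > 1))
        stop("probability scores must lie in [0, 1]")
      score
    })
}

#' Merge prior sources into a single acyclic pair set
#'
#' Per source, transforms scores to probabilities and keeps the
#' \code{top_k_per_source} highest (stable order on ties); duplicate
#' unordered pairs across sources resolve to the maximum probability;
#' pairs naming genes outside the expression matrix are dropped with a
#' warning; cycles are removed (largest-p spanning forest).
#'
#' @param records data frame with gene_a, gene_b, score, source.
#' @param genes gene universe (e.g. rownames of the expression matrix).
#' @param top_k_per_source pairs retained per source (default 50).
#' @param ... passed to \code{\link{transform_prior_score}}.
#' @return a \code{\link{prior_set}}; attribute \code{audit} carries the
#'   per-record bookkeeping (probability, kept/dropped and why).
#' @export
merge_prior_sources <- function(records, genes, top_k_per_source = 50, ...) {
  genes <- as.character(genes)
  if (is.null(records) || nrow(records) == 0L)
    return(prior_set(NULL, genes))
  records$gene_a <- as.character(records$gene_a)
  records$gene_b <- as.character(records$gene_b)
  records$p <- NA_real_
  for (src in unique(records$source)) {
    sel <- records$source == src
    records$p[sel] <- transform_prior_score(records$score[sel], src, ...)
  }
  records$status <- "kept"
  unknown <- !(records$gene_a %in% genes) | !(records$gene_b %in% genes)
  if (any(unknown)) {
    warning(sum(unknown), " prior pair(s) referenced genes absent from ",
            "the expression matrix and were dropped")
    records$status[unknown] <- "unknown_gene"
  }
  work <- records[!unknown, , drop = FALSE]
  work_idx <- which(!unknown)
  keep <- unlist(lapply(split(seq_len(nrow(work)), work$source),
                        function(ix) {
                          ix[utils::head(order(-work$p[ix]),
                                         top_k_per_source)]
                        }), use.names = FALSE)
  records$status[work_idx[setdiff(seq_len(nrow(work)), keep)]] <-
    "below_top_k"
  work <- work[sort(keep), , drop = FALSE]
  # max-p merge of duplicate unordered pairs across sources
  key <- paste(pmin(work$gene_a, work$gene_b),
               pmax(work$gene_a, work$gene_b))
  best <- vapply(split(seq_len(nrow(work)), key),
                 function(ix) ix[which.max(work$p[ix])], integer(1))
  work <- work[sort(best), , drop = FALSE]
  rc <- remove_cycles(work)
  ps <- prior_set(rc$kept[, c("gene_a", "gene_b", "p", "source")], genes)
  attr(ps, "audit") <- list(records = records, removed_cycles = rc$removed)
  ps
}

#' Select differentially expressed genes
#'
#' Per-gene Welch two-sample t-test on log-scale expression,
#' Benjamini-Hochberg adjustment, FDR filter, then the \code{top_n}
#' genes by absolute log fold change (difference of group means).
#'
#' @param x expression matrix, genes in rows, samples in columns
#'   (log scale).
#' @param labels vector/factor of two conditions, one per sample
#'   (column).
#' @param fdr_cutoff BH-adjusted p-value threshold (default 0.05).
#' @param top_n genes retained among those passing (default 400).
#' @param pooled_variance use the pooled-variance t-test instead of
#'   Welch's.
#' @return character vector of selected gene ids, in original row order.
#' @export
select_de_genes <- function(x, labels, fdr_cutoff = 0.05, top_n = 400,
                            pooled_variance = FALSE) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L)
    stop("'labels' must define exactly two conditions")
  if (length(labels) != ncol(x))
    stop("'labels' length must equal the number of samples")
  if (min(table(labels)) < 2L)
    stop("each condition needs at least 2 samples")
  a <- x[, labels == levels(labels)[1L], drop = FALSE]
  b <- x[, labels == levels(labels)[2L], drop = FALSE]
  pv <- vapply(seq_len(nrow(x)), function(i) {
    stats::t.test(a[i, ], b[i, ], var.equal = pooled_variance)$p.value
  }, numeric(1))
  padj <- stats::p.adjust(pv, method = "BH")
  lfc <- rowMeans(a) - rowMeans(b)
  pass <- which(padj < fdr_cutoff)
  top <- pass[utils::head(order(-abs(lfc[pass])), top_n)]
  rownames(x)[sort(top)]
}

#' Write / read a posterior similarity matrix
#'
#' Tab-separated square matrix with a gene-id header column and row.
#'
#' @param psm matrix with gene-id dimnames.
#' @param path file path.
#' @export
write_psm <- function(psm, path) {
  df <- data.frame(rownames(psm), psm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- "gene"
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_psm
#' @export
read_psm <- function(path) {
  m <- read_expression(path)
  if (nrow(m) != ncol(m)) stop("stored matrix is not square")
  colnames(m) <- rownames(m)
  m
}

#' Write a gene-to-cluster table
#'
#' @param labels membership vector named by gene id.
#' @param path file path.
#' @export
write_clusters <- function(labels, path) {
  utils::write.table(data.frame(gene = names(labels),
                                cluster = as.integer(labels)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
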