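# Scoring of inferred partitions: adjusted Rand index against a truth
# labelling, and pair-level confusion statistics against a reference
# pair network.

#' Adjusted Rand index
#'
#' Hubert-Arabie chance-corrected agreement between two partitions of the
#' same genes: 1 for identical partitions, expected 0 for random
#' labellings.
#'
#' @param a,b membership vectors over the same genes.
#' @return the adjusted Rand index.
#' @export
adjusted_rand <- function(a, b) {
  if (length(a) != length(b))
    stop("partitions must cover the same gene set")
  if (anyNA(a) || anyNA(b)) stop("membership vectors must not contain NA")
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(ifelse(sum_ij == expected, 1, 0))
  (sum_ij - expected) / (max_index - expected)
}

#' Pair-level confusion against a reference network
#'
#' Every unordered gene pair is classified: "positive" if co-grouped in
#' the partition, "true" if present in the reference pair list.
#' Sensitivity = TP / (TP + FN) (reference pairs recovered in the same
#' group), specificity = TN / (TN + FP), PPV = TP / (TP + FP).
#'
#' @param labels membership vector, named by gene id (or supply
#'   \code{gene_ids}).
#' @param reference_pairs two-column matrix or data frame of gene-id
#'   pairs (deduplicated, unordered).
#' @param gene_ids gene identifiers matching \code{labels}.
#' @return list of class \code{pair_confusion} with counts and rates.
#' @export
pair_confusion <- function(labels, reference_pairs,
                           gene_ids = names(labels)) {
  if (is.null(gene_ids))
    stop("gene identifiers required (name 'labels' or pass 'gene_ids')")
  n <- length(labels)
  ref <- as.matrix(reference_pairs)[, 1:2, drop = FALSE]
  ia <- match(ref[, 1L], gene_ids)
  ib <- match(ref[, 2L], gene_ids)
  if (anyNA(ia) || anyNA(ib)) {
    bad <- unique(c(ref[is.na(ia), 1L], ref[is.na(ib), 2L]))
    stop("reference pair gene(s) not in the gene universe: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  key <- paste(pmin(ia, ib), pmax(ia, ib))
  if (anyDuplicated(key)) stop("duplicate unordered reference pairs")
  if (any(ia == ib)) stop("self-pairs in reference list")
  in_ref <- matrix(FALSE, n, n)
  in_ref[cbind(ia, ib)] <- TRUE
  in_ref[cbind(ib, ia)] <- TRUE
  together <- outer(labels, labels, "==")
  up <- upper.tri(together)
  TP <- sum(together[up] & in_ref[up])
  FP <- sum(together[up] & !in_ref[up])
  FN <- sum(!together[up] & in_ref[up])
  TN <- sum(!together[up] & !in_ref[up])
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN,
                 sensitivity = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
                 specificity = if (TN + FP > 0) TN / (TN + FP) else NA_real_,
                 ppv = if (TP + FP > 0) TP / (TP + FP) else NA_real_),
            class = "pair_confusion")
}

#' @export
print.pair_confusion <- function(x, ...) {
  cat("Pair confusion over", x$TP + x$FP + x$TN + x$FN, "gene pairs\n")
  cat(sprintf("  TP=%d FP=%d TN=%d FN=%d\n", x$TP, x$FP, x$TN, x$FN))
  cat(sprintf("  sensitivity=%.3f specificity=%.3f PPV=%.4f AUC=%.3f\n",
              x$sensitivity, x$specificity, x$ppv,
              auc_single_point(x$sensitivity, x$specificity)))
  invisible(x)
}

#' AUC from a single operating point
#'
#' A hard clustering yields one (sensitivity, specificity) operating
#' point; the ROC curve through (0,0), (1-specificity, sensitivity),
#' (1,1) has trapezoidal area (sensitivity + specificity) / 2.
#'
#' @param sensitivity,specificity values in [0, 1].
#' @return the area under the two-segment ROC curve.
#' @export
auc_single_point <- function(sensitivity, specificity) {
  if (any(sensitivity < 0 | sensitivity > 1) ||
      any(specificity < 0 | specificity > 1))
    stop("'sensitivity' and 'specificity' must lie in [0, 1]")
  (sensitivity + specificity) / 2
}

#' ROC sweep over posterior similarity thresholds
#'
#' Richer alternative to the single-point AUC available when a posterior
#' similarity matrix is at hand: thresholding p_ij at every observed
#' value traces a full ROC against the reference pair network.
#'
#' @param psm posterior similarity matrix with gene-id dimnames.
#' @param reference_pairs two-column gene-id pair list.
#' @return data frame with threshold, sensitivity, specificity, plus an
#'   \code{auc} attribute (trapezoidal).
#' @export
psm_roc <- function(psm, reference_pairs) {
  gene_ids <- rownames(psm)
  if (is.null(gene_ids)) stop("'psm' must carry gene ids as rownames")
  n <- nrow(psm)
  ref <- as.matrix(reference_pairs)[, 1:2, drop = FALSE]
  ia <- match(ref[, 1L], gene_ids); ib <- match(ref[, 2L], gene_ids)
  if (anyNA(ia) || anyNA(ib)) stop("reference pair gene(s) not in psm")
  in_ref <- matrix(FALSE, n, n)
  in_ref[cbind(ia, ib)] <- TRUE; in_ref[cbind(ib, ia)] <- TRUE
  up <- upper.tri(psm)
  score <- psm[up]; truth <- in_ref[up]
  ths <- sort(unique(c(0, score, 1)))
  sens <- vapply(ths, function(t) mean(score[truth] >= t), numeric(1))
  spec <- vapply(ths, function(t) mean(score[!truth] < t), numeric(1))
  ord <- order(1 - spec, sens)
  xs <- c(0, (1 - spec)[ord], 1)
  ys <- c(0, sens[ord], 1)
  auc <- sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
  out <- data.frame(threshold = ths, sensitivity = sens,
                    specificity = spec)
  attr(out, "auc") <- auc
  out
}
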