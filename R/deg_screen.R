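## Differential-expression screen: quantile normalisation, per-gene
## Welch t-tests with Benjamini-Hochberg adjustment, hard-threshold DEG
## selection, cross-dataset intersection and intersection with the FRG
## catalog.

#' Quantile-normalise an expression matrix
#'
#' Forces every sample column to the same empirical distribution: the
#' row-wise mean of the column-sorted values, assigned back in each
#' column's rank order. Ties within a column receive the mean of the
#' quantile values they span, so the result is invariant to the order in
#' which tied entries are listed.
#'
#' @param x numeric matrix (genes x samples) with >= 2 samples.
#' @return matrix of the same shape and dimnames; column distributions
#'   identical, column means equal.
#' @export
quantile_normalize <- function(x) {
  if (!is.matrix(x) || ncol(x) < 2L)
    stop("quantile normalisation needs a matrix with >= 2 samples")
  if (!all(is.finite(x)))
    stop("matrix contains non-finite values")
  ref <- rowMeans(apply(x, 2L, sort))
  out <- apply(x, 2L, function(col) {
    r <- rank(col, ties.method = "average")   # fractional rank for ties
    lo <- floor(r); hi <- ceiling(r)
    (ref[lo] + ref[hi]) / 2
  })
  dimnames(out) <- dimnames(x)
  if (inherits(x, "expression_matrix"))
    out <- expression_matrix(out, scale = attr(x, "scale"))
  out
}

#' Per-gene two-group differential expression (Welch t-test)
#'
#' For every gene: Welch two-sample t-test between the two groups and
#' `log2FoldChange = mean(alt) - mean(ref)` on the log2 scale, with
#' Benjamini-Hochberg adjustment across all tested genes. Genes with
#' zero variance in both groups cannot be tested; they are kept with
#' `p_value = 1` and flagged.
#'
#' @param x numeric log2 matrix (genes x samples).
#' @param groups character/factor vector of length `ncol(x)` with
#'   exactly two distinct labels.
#' @param ref,alt group labels fixing the fold-change orientation;
#'   default: first and second level in `sort(unique(groups))`.
#' @return data.frame of class `deg_table`: `gene`, `log2FoldChange`,
#'   `p_value`, `p_adj`, `flagged`.
#' @export
differential_expression <- function(x, groups, ref = NULL, alt = NULL) {
  if (!is.matrix(x)) stop("'x' must be a genes x samples matrix")
  groups <- as.character(groups)
  if (length(groups) != ncol(x))
    stop("'groups' must have one label per sample column")
  labs <- sort(unique(groups))
  if (length(labs) != 2L) stop("exactly two group labels are required")
  ref <- ref %||% labs[1L]; alt <- alt %||% labs[2L]
  if (!all(c(ref, alt) %in% labs) || ref == alt)
    stop("'ref' and 'alt' must be the two distinct group labels")
  i1 <- which(groups == ref); i2 <- which(groups == alt)
  if (length(i1) < 2L || length(i2) < 2L)
    stop("both groups need >= 2 samples")
  n1 <- length(i1); n2 <- length(i2)
  m1 <- rowMeans(x[, i1, drop = FALSE]); m2 <- rowMeans(x[, i2, drop = FALSE])
  v1 <- rowSums((x[, i1, drop = FALSE] - m1)^2) / (n1 - 1)
  v2 <- rowSums((x[, i2, drop = FALSE] - m2)^2) / (n2 - 1)
  lfc <- m2 - m1
  se2 <- v1 / n1 + v2 / n2
  flagged <- se2 == 0
  tstat <- ifelse(flagged, 0, lfc / sqrt(se2))
  # Welch-Satterthwaite degrees of freedom (flagged genes bypass it)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- ifelse(flagged, 1, 2 * stats::pt(-abs(tstat), df))
  res <- data.frame(gene = rownames(x), log2FoldChange = lfc,
                    p_value = p, p_adj = stats::p.adjust(p, method = "BH"),
                    flagged = flagged, row.names = NULL)
  class(res) <- c("deg_table", "data.frame")
  res
}

#' Select DEGs by adjusted p-value and absolute fold change
#'
#' The screening thresholds are strict inequalities: a gene is retained
#' when `p_adj < p_adj_max` and `|log2FoldChange| > abs_lfc_min`
#' (defaults 0.05 and 1). `one_sided = TRUE` restricts to positive fold
#' changes only.
#'
#' @param records a `deg_table` from [differential_expression()].
#' @param p_adj_max adjusted-p threshold (strict).
#' @param abs_lfc_min absolute log2 fold-change threshold (strict).
#' @param one_sided if `TRUE`, require `log2FoldChange > abs_lfc_min`
#'   instead of the absolute value.
#' @return character vector of gene symbols ordered by ascending `p_adj`.
#' @export
select_degs <- function(records, p_adj_max = 0.05, abs_lfc_min = 1,
                        one_sided = FALSE) {
  stopifnot(is.data.frame(records),
            all(c("gene", "log2FoldChange", "p_adj") %in% names(records)))
  if (!nrow(records)) return(character())
  lfc_ok <- if (one_sided) records$log2FoldChange > abs_lfc_min
            else abs(records$log2FoldChange) > abs_lfc_min
  keep <- records$p_adj < p_adj_max & lfc_ok
  sel <- records[keep, , drop = FALSE]
  sel$gene[order(sel$p_adj)]
}

#' Intersect DEG lists across datasets
#'
#' @param lists a list of >= 2 character vectors of gene symbols.
#' @return the sorted (lexicographic) intersection.
#' @export
intersect_deg_sets <- function(lists) {
  stopifnot(is.list(lists), length(lists) >= 2L)
  out <- Reduce(intersect, lists)
  sort(unique(out))
}

#' Intersect a gene list with the FRG catalog
#'
#' @param genes character vector of gene symbols.
#' @param catalog an `frg_catalog` (see [load_frg_catalog()]).
#' @return data.frame `symbol`, `direction`, `source` for the genes found
#'   in the catalog (case-insensitive), in catalog order.
#' @export
intersect_frgs <- function(genes, catalog) {
  stopifnot(inherits(catalog, "frg_catalog"))
  hit <- catalog$symbol %in% toupper(genes)
  out <- catalog[hit, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- "data.frame"
  out
}
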