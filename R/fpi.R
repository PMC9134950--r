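## Ferroptosis potential index (FPI): per sample, the difference between
## the ssGSEA enrichment of positive (pro-ferroptotic) and negative
## (suppressor) regulator sets from the FRG catalog. Because the scores
## are rank-based, the FPI depends only on where the regulator genes sit
## in each sample's ranking and is invariant under monotone transforms
## of the expression values.

#' Compute the ferroptosis potential index per sample
#'
#' `FPI = ssGSEA(positive regulators) - ssGSEA(negative regulators)`,
#' both scored unnormalised at the same `alpha` (a global rescaling
#' would change the index's scale without reordering samples; the raw
#' difference is the conventional construction). Catalog entries with
#' direction `unassigned` are excluded and reported via a message.
#'
#' @param x log2 expression matrix (genes x samples).
#' @param catalog an `frg_catalog` (see [load_frg_catalog()]).
#' @param alpha ssGSEA rank-weight exponent (default 0.25).
#' @param min_coverage minimum fraction of each direction set that must
#'   be present in the matrix (default 0.8); below it the computation
#'   stops naming the missing symbols.
#' @param normalize_first if `TRUE`, globally normalise the two-score
#'   matrix before differencing (off by default).
#' @return data.frame of class `fpi_result`: `sample`, `positive_score`,
#'   `negative_score`, `fpi`.
#' @export
compute_fpi <- function(x, catalog, alpha = 0.25, min_coverage = 0.8,
                        normalize_first = FALSE) {
  stopifnot(is.matrix(x), inherits(catalog, "frg_catalog"))
  n_un <- sum(catalog$direction == "unassigned")
  if (n_un > 0)
    message(sprintf("%d unassigned catalog entr%s excluded from FPI",
                    n_un, if (n_un == 1L) "y" else "ies"))
  dirs <- frg_direction_sets(catalog)
  genes_upper <- toupper(rownames(x))
  for (nm in names(dirs)) {
    missing <- dirs[[nm]][!(toupper(dirs[[nm]]) %in% genes_upper)]
    if (length(missing) / length(dirs[[nm]]) > 1 - min_coverage)
      stop(sprintf("%s coverage below %.2f; missing: %s", nm, min_coverage,
                   paste(missing, collapse = ", ")))
  }
  sc <- ssgsea_matrix(x, dirs, alpha = alpha, normalize = normalize_first,
                      min_coverage = 0)
  res <- data.frame(sample = colnames(x),
                    positive_score = sc["FRG_positive", ],
                    negative_score = sc["FRG_negative", ],
                    row.names = NULL)
  res$fpi <- res$positive_score - res$negative_score
  class(res) <- c("fpi_result", "data.frame")
  res
}

#' Compare FPI between sample groups
#'
#' Two groups: two-sided Wilcoxon rank-sum (default) or Welch t; three
#' or more groups: one-way ANOVA.
#'
#' @param results an `fpi_result` from [compute_fpi()].
#' @param groups named vector or data.frame (`sample`, `group`) mapping
#'   samples to groups, or a plain label vector aligned with
#'   `results$sample`.
#' @param test `"wilcoxon"`, `"t"` or `"anova"`.
#' @return a one-row `group_comparison` data.frame (set = `"FPI"`).
#' @export
compare_fpi <- function(results, groups, test = c("wilcoxon", "t", "anova")) {
  test <- match.arg(test)
  stopifnot(inherits(results, "fpi_result"))
  if (is.data.frame(groups))
    groups <- stats::setNames(as.character(groups$group), groups$sample)
  if (!is.null(names(groups))) groups <- groups[results$sample]
  groups <- as.character(groups)
  if (length(unique(groups)) < 2L) stop("need >= 2 groups to compare FPI")
  m <- matrix(results$fpi, nrow = 1,
              dimnames = list("FPI", results$sample))
  compare_groups(m, groups, test = test)
}
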