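## Single-sample GSEA (ssGSEA): rank-weighted running-sum enrichment of a
## gene set within one sample's expression profile. This is the single
## scoring backend feeding LICA/TME scoring, the FPI and the single-cell
## cytolytic score.
##
## Algorithm (integral running-sum variant): genes are ranked by
## decreasing expression (ties broken by stable gene-symbol order, so
## results are platform-independent); walking down the ranking, in-set
## genes ("hits") add |rank weight|^alpha normalised over all in-set
## genes, out-of-set genes ("misses") subtract a uniform 1/(N - n_set);
## the score is the sum of the running sum over all N positions, not its
## maximum deviation.

#' ssGSEA score of one gene set in one sample
#'
#' @param expr named numeric vector of expression values for one sample
#'   (>= 2 genes). Only the ranking of the values matters: the score is
#'   invariant under strictly monotone transforms.
#' @param gene_set character vector of gene symbols (matched
#'   case-insensitively against `names(expr)`).
#' @param alpha rank-weight exponent; `alpha = 0` weights all hits
#'   equally (Kolmogorov-Smirnov-like walk), the default 0.25 is the
#'   conventional ssGSEA weighting.
#' @return a single numeric enrichment score.
#' @examples
#' x <- c(g1 = 3, g2 = 2, g3 = 1)
#' ssgsea_sample(x, "g1", alpha = 0)   #  1.5
#' ssgsea_sample(x, "g3", alpha = 0)   # -1.5
#' @export
ssgsea_sample <- function(expr, gene_set, alpha = 0.25) {
  if (length(expr) < 2L) stop("need at least 2 genes in the expression vector")
  if (is.null(names(expr))) stop("'expr' must be a named vector")
  assert_scalar_number(alpha, "alpha")
  hit <- toupper(names(expr)) %in% toupper(gene_set)
  if (!any(hit))
    stop("gene set has empty intersection with the expression vector")
  if (all(hit))
    stop("gene set covers every gene; miss normalisation undefined")
  ord <- order(-expr, names(expr), method = "radix")
  ssgsea_core(hit[ord], alpha)
}

# running-sum core on the hit indicator in ranking order.
# weights: position i (1 = highest expression) carries rank weight
# N - i + 1, exponentiated by alpha and normalised over hits.
ssgsea_core <- function(hit_ranked, alpha) {
  n <- length(hit_ranked)
  w <- (n - seq_len(n) + 1)^alpha
  inc <- numeric(n)
  inc[hit_ranked] <- w[hit_ranked] / sum(w[hit_ranked])
  inc[!hit_ranked] <- -1 / (n - sum(hit_ranked))
  sum(cumsum(inc))
}

#' ssGSEA scores for a gene-set collection across samples
#'
#' Applies [ssgsea_sample()] to every sample column and every set,
#' producing the set x sample enrichment-score matrix consumed by the
#' correlation, FPI and OSS stages. Sets whose coverage (fraction of set
#' genes present among the matrix genes) falls below `min_coverage` are
#' skipped with a warning; per-set coverage is always attached to the
#' result so downstream reports can state how complete the matching was.
#'
#' @param x an [expression_matrix()] or named numeric matrix
#'   (genes x samples, log scale).
#' @param collection a [gene_set_collection()] (or named list of gene
#'   vectors).
#' @param alpha rank-weight exponent (see [ssgsea_sample()]).
#' @param normalize if `TRUE`, divide all scores by the global
#'   `max - min` over the whole score matrix (the common ssGSEA
#'   rescaling); per-set rescaling via `normalize = "per_set"`.
#' @param min_coverage minimum fraction of a set's genes that must be
#'   present in the matrix (default 0.8).
#' @return an `enrichment_scores` matrix (sets x samples) with
#'   attributes `alpha`, `normalized` and `coverage`.
#' @export
ssgsea_matrix <- function(x, collection, alpha = 0.25, normalize = FALSE,
                          min_coverage = 0.8) {
  if (!is.matrix(x)) stop("'x' must be a genes x samples matrix")
  if (!is.list(collection)) stop("'collection' must be a gene-set collection")
  genes_upper <- toupper(rownames(x))
  coverage <- vapply(collection, function(g)
    mean(toupper(g) %in% genes_upper), 0)
  keep <- coverage >= min_coverage & coverage > 0
  if (!any(keep))
    stop("all gene sets fall below min_coverage; nothing to score")
  if (any(!keep))
    warning(sprintf("skipping %d set(s) below coverage %.2f: %s",
                    sum(!keep), min_coverage,
                    paste(names(collection)[!keep], collapse = ", ")))
  sets <- collection[keep]
  hit_idx <- lapply(sets, function(g) which(genes_upper %in% toupper(g)))
  n <- nrow(x)
  full <- vapply(hit_idx, length, 0L) == n
  if (any(full))
    stop("set(s) covering every matrix gene are unscorable: ",
         paste(names(sets)[full], collapse = ", "))
  scores <- matrix(NA_real_, nrow = length(sets), ncol = ncol(x),
                   dimnames = list(names(sets), colnames(x)))
  for (s in seq_len(ncol(x))) {
    ord <- order(-x[, s], rownames(x), method = "radix")
    pos <- integer(n); pos[ord] <- seq_len(n)   # gene row -> rank position
    for (k in seq_along(hit_idx)) {
      hit <- logical(n)
      hit[pos[hit_idx[[k]]]] <- TRUE
      scores[k, s] <- ssgsea_core(hit, alpha)
    }
  }
  norm_mode <- if (isTRUE(normalize)) "global" else
    if (identical(normalize, "per_set")) "per_set" else "none"
  if (norm_mode == "global") {
    rng <- max(scores) - min(scores)
    if (rng > 0) scores <- scores / rng
  } else if (norm_mode == "per_set") {
    rng <- apply(scores, 1L, function(v) max(v) - min(v))
    rng[rng == 0] <- 1
    scores <- sweep(scores, 1L, rng, "/")
  }
  structure(scores, alpha = alpha, normalized = norm_mode,
            coverage = coverage,
            class = c("enrichment_scores", "matrix", "array"))
}

#' @export
print.enrichment_scores <- function(x, ...) {
  cat(sprintf("enrichment_scores: %d sets x %d samples (alpha = %g, normalized = %s)\n",
              nrow(x), ncol(x), attr(x, "alpha"), attr(x, "normalized")))
  invisible(x)
}
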