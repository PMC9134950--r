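## FRG / enrichment-score association analysis: Pearson correlation of
## each ferroptosis-related gene's expression with each gene-set score
## within a cohort, median-split comparisons, and per-set group tests
## with the star convention used in the figures.

#' Correlate FRG expression with gene-set enrichment scores
#'
#' Within one cohort, computes the Pearson correlation between each
#' FRG's expression vector and each gene set's score vector, with the
#' two-sided p-value from the t transform of r. Cells with fewer than 3
#' samples or a zero-variance FRG are flagged missing rather than
#' dropped.
#'
#' @param x log2 expression matrix (genes x samples).
#' @param scores enrichment-score matrix (sets x samples) on the same
#'   samples.
#' @param frgs character vector of FRG symbols to correlate.
#' @param cohort optional logical/index vector selecting the cohort's
#'   samples (default: all samples).
#' @return data.frame of class `frg_correlation`: `frg`, `set`, `r`,
#'   `p_value`, `n`, `flagged`.
#' @export
correlate_frg_scores <- function(x, scores, frgs, cohort = NULL) {
  stopifnot(is.matrix(x), is.matrix(scores))
  if (is.null(cohort)) cohort <- seq_len(ncol(x))
  xs <- x[, cohort, drop = FALSE]
  ss <- scores[, colnames(xs), drop = FALSE]
  n <- ncol(xs)
  if (n < 3L) stop("cohort must contain >= 3 samples")
  idx <- match(toupper(frgs), toupper(rownames(xs)))
  if (anyNA(idx))
    stop("FRG(s) absent from the matrix: ",
         paste(frgs[is.na(idx)], collapse = ", "))
  out <- expand.grid(frg = frgs, set = rownames(ss),
                     stringsAsFactors = FALSE)
  out$r <- NA_real_; out$p_value <- NA_real_; out$n <- n; out$flagged <- FALSE
  for (k in seq_len(nrow(out))) {
    g <- xs[idx[match(out$frg[k], frgs)], ]
    s <- ss[out$set[k], ]
    if (stats::sd(g) == 0 || stats::sd(s) == 0) {
      out$flagged[k] <- TRUE
      next
    }
    r <- stats::cor(g, s)
    tt <- r * sqrt((n - 2) / (1 - r^2))
    out$r[k] <- r
    out$p_value[k] <- if (abs(r) >= 1) 0 else 2 * stats::pt(-abs(tt), n - 2)
  }
  class(out) <- c("frg_correlation", "data.frame")
  out
}

#' Split samples at the median of a vector
#'
#' Values less than or equal to the median are labelled `"low"`, the
#' rest `"high"`; samples exactly at the median therefore always land in
#' the low group.
#'
#' @param values numeric vector.
#' @return character vector of `"low"` / `"high"` labels.
#' @export
median_split <- function(values) {
  med <- stats::median(values)
  ifelse(values <= med, "low", "high")
}

# Wilcoxon rank-sum with explicit handling of fully tied data (normal
# approximation breaks down there; a constant response carries no
# evidence, so p = 1)
wilcox_safe <- function(a, b) {
  if (length(unique(c(a, b))) == 1L)
    return(list(statistic = c(W = length(a) * length(b) / 2), p.value = 1))
  suppressWarnings(stats::wilcox.test(a, b))
}

#' Median-split comparison of enrichment scores by one gene's expression
#'
#' Samples are split at the median of the gene's expression; samples
#' exactly at the median go to the low group (a fixed, documented tie
#' rule). Each gene set's scores are then compared high vs low with a
#' two-sided test.
#'
#' @param x log2 expression matrix (genes x samples), >= 4 samples.
#' @param gene gene symbol to split on.
#' @param scores enrichment-score matrix (sets x samples).
#' @param test `"wilcoxon"` (default) or `"t"`.
#' @return a `group_comparison` data.frame (see [compare_groups()]) with
#'   groups `low` / `high`.
#' @export
median_split_compare <- function(x, gene, scores, test = c("wilcoxon", "t")) {
  test <- match.arg(test)
  stopifnot(is.matrix(x), is.matrix(scores))
  if (ncol(x) < 4L) stop("median split needs >= 4 samples")
  i <- match(toupper(gene), toupper(rownames(x)))
  if (is.na(i)) stop("gene not in matrix: ", gene)
  g <- x[i, ]
  split <- median_split(g)
  if (length(unique(split)) < 2L)
    stop(sprintf("median split undefined: '%s' has (near-)constant expression",
                 gene))
  compare_groups(scores[, colnames(x), drop = FALSE], split, test = test)
}

#' Per-set group comparison of enrichment scores
#'
#' Compares each gene set's score vector between sample groups: Wilcoxon
#' rank-sum or Student/Welch t for two groups, one-way ANOVA for three
#' or more (requesting t/wilcoxon with > 2 groups is an error).
#' Significance stars follow `*` p < 0.05 through `****` p < 0.0001; an
#' additional Benjamini-Hochberg column is emitted across sets.
#'
#' @param scores enrichment-score matrix (sets x samples).
#' @param groups group label per sample column.
#' @param test `"wilcoxon"` (default), `"t"`, or `"anova"`.
#' @return data.frame of class `group_comparison`: `set`, one
#'   `mean_<group>` column per group, `statistic`, `p_value`, `p_adj`,
#'   `stars`, `test`.
#' @export
compare_groups <- function(scores, groups, test = c("wilcoxon", "t", "anova")) {
  test <- match.arg(test)
  stopifnot(is.matrix(scores))
  groups <- as.character(groups)
  if (length(groups) != ncol(scores))
    stop("'groups' must have one label per score column")
  labs <- sort(unique(groups))
  if (any(table(groups) < 2L)) stop("each group needs >= 2 samples")
  if (length(labs) > 2L && test != "anova")
    stop("more than two groups: use test = 'anova'")
  if (length(labs) < 2L) stop("need >= 2 groups")
  res <- lapply(rownames(scores), function(s) {
    v <- scores[s, ]
    means <- vapply(labs, function(g) mean(v[groups == g]), 0)
    ht <- switch(test,
      wilcoxon = wilcox_safe(v[groups == labs[2L]], v[groups == labs[1L]]),
      t = stats::t.test(v[groups == labs[2L]], v[groups == labs[1L]]),
      anova = {
        fit <- stats::aov(v ~ factor(groups))
        tab <- summary(fit)[[1L]]
        list(statistic = tab[1L, "F value"], p.value = tab[1L, "Pr(>F)"])
      })
    c(means, statistic = unname(ht$statistic), p_value = ht$p.value)
  })
  res <- as.data.frame(do.call(rbind, res))
  names(res) <- c(paste0("mean_", labs), "statistic", "p_value")
  out <- data.frame(set = rownames(scores), res, row.names = NULL,
                    check.names = FALSE)
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out$stars <- significance_stars(out$p_value)
  out$test <- test
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' Flag FRG-set correlation sign disagreements between datasets
#'
#' Given correlation tables from two cohorts/datasets, reports the
#' (FRG, set) cells whose significant correlations have opposite signs —
#' the package takes no side on which dataset is right.
#'
#' @param tab1,tab2 `frg_correlation` tables over the same (frg, set)
#'   grid.
#' @param p_max significance threshold applied to both cells.
#' @return data.frame of disagreeing cells with both r values.
#' @export
correlation_sign_disagreements <- function(tab1, tab2, p_max = 0.05) {
  key <- function(t) paste(t$frg, t$set, sep = "\r")
  m <- match(key(tab1), key(tab2))
  ok <- !is.na(m) & !tab1$flagged & !tab2$flagged[m] &
    tab1$p_value < p_max & tab2$p_value[m] < p_max &
    sign(tab1$r) != sign(tab2$r[m])
  data.frame(frg = tab1$frg[ok], set = tab1$set[ok],
             r1 = tab1$r[ok], r2 = tab2$r[m][ok])
}
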