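## Single-cell stage: library-size normalisation, subset marker
## screening at the p < 0.05 / log2FC > 0.5 thresholds, per-cell
## cytolytic activity (geometric mean of GZMA and PRF1, or per-cell
## ssGSEA of a cytolytic set), and subset-wise condition tests.

#' Construct a single-cell count table
#'
#' @param counts genes x cells matrix of non-negative integer counts
#'   (dense or `Matrix` sparse), with gene rownames and barcode colnames.
#' @param annotation data.frame with columns `barcode`, `subset`,
#'   `condition` covering every cell.
#' @param truth optional data.frame of planted ground truth (used by the
#'   simulator).
#' @return an object of class `cell_table`.
#' @export
cell_table <- function(counts, annotation, truth = NULL) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("'counts' needs gene rownames and barcode colnames")
  stopifnot(is.data.frame(annotation),
            all(c("barcode", "subset", "condition") %in% names(annotation)))
  if (!setequal(annotation$barcode, colnames(counts)))
    stop("annotation barcodes must match count columns exactly")
  v <- if (inherits(counts, "Matrix")) counts@x else counts
  if (any(v < 0) || any(v != floor(v)))
    stop("counts must be non-negative integers")
  annotation <- annotation[match(colnames(counts), annotation$barcode), ]
  rownames(annotation) <- NULL
  structure(list(counts = counts, annotation = annotation, truth = truth),
            class = "cell_table")
}

#' @export
print.cell_table <- function(x, ...) {
  cat(sprintf("cell_table: %d genes x %d cells; %d subsets, %d conditions\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$annotation$subset)),
              length(unique(x$annotation$condition))))
  invisible(x)
}

#' Write a cell table as an MTX triplet plus annotation TSV
#'
#' Writes `matrix.mtx`, `genes.tsv`, `barcodes.tsv` and
#' `annotation.tsv` (barcode, subset, condition) into `dir`.
#'
#' @param table a [cell_table()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cell_table <- function(table, dir) {
  stopifnot(inherits(table, "cell_table"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(Matrix::Matrix(table$counts, sparse = TRUE),
                              "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(table$counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(table$counts), file.path(dir, "barcodes.tsv"))
  utils::write.table(table$annotation, file.path(dir, "annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a cell table from an MTX triplet directory
#'
#' @param dir directory holding `matrix.mtx`, `genes.tsv`,
#'   `barcodes.tsv`, `annotation.tsv` as written by
#'   [write_cell_table()].
#' @return a [cell_table()].
#' @export
read_cell_table <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                        "CsparseMatrix")
  rownames(counts) <- readLines(file.path(dir, "genes.tsv"))
  colnames(counts) <- readLines(file.path(dir, "barcodes.tsv"))
  ann <- utils::read.delim(file.path(dir, "annotation.tsv"),
                           colClasses = "character")
  cell_table(counts, ann)
}

#' Library-size log-normalise single-cell counts
#'
#' `value = log2(1 + count / cell_total * scale_factor)`: each cell is
#' scaled to a common library size before the log, so doubling all of a
#' cell's counts leaves its normalised vector unchanged.
#'
#' @param table a [cell_table()] (or genes x cells count matrix).
#' @param scale_factor target library size (default 1e4).
#' @return dense genes x cells matrix of log2-normalised values.
#' @export
normalize_cells <- function(table, scale_factor = 1e4) {
  counts <- if (inherits(table, "cell_table")) table$counts else table
  totals <- Matrix::colSums(counts)
  if (any(totals == 0))
    stop("cell(s) with zero total count: ",
         paste(colnames(counts)[totals == 0], collapse = ", "))
  dense <- as.matrix(counts)
  log2(1 + sweep(dense, 2L, totals, "/") * scale_factor)
}

#' Screen subset marker genes
#'
#' For every annotated subset, each gene is tested in-subset vs all
#' other cells with a two-sided Wilcoxon rank-sum test, and the log2
#' fold change is computed Seurat-style on de-logged means:
#' `log2FC = log2((mean(2^x - 1) in + 1) / (mean(2^x - 1) out + 1))`.
#' Reported markers satisfy `p_value < p_max` and `log2FC > lfc_min`
#' (positive markers only); a Benjamini-Hochberg column over all tests
#' within the subset is emitted alongside.
#'
#' @param normalized genes x cells log2-normalised matrix (see
#'   [normalize_cells()]).
#' @param annotation data.frame with `barcode` and `subset` covering the
#'   columns.
#' @param p_max marker p-value threshold (default 0.05).
#' @param lfc_min marker log2 fold-change threshold (default 0.5).
#' @param min_cells subsets with fewer cells are skipped with a warning
#'   (default 3).
#' @return data.frame of class `marker_table`: `gene`, `subset`,
#'   `log2FC`, `p_value`, `p_adj`.
#' @export
cluster_markers <- function(normalized, annotation, p_max = 0.05,
                            lfc_min = 0.5, min_cells = 3L) {
  stopifnot(is.matrix(normalized))
  subs <- annotation$subset[match(colnames(normalized), annotation$barcode)]
  if (anyNA(subs)) stop("annotation does not cover every cell")
  tab <- table(subs)
  usable <- names(tab)[tab >= min_cells]
  if (length(unique(subs)) < 2L || length(usable) < 2L)
    stop("need >= 2 subsets with >= min_cells cells each")
  if (length(usable) < length(tab))
    warning("skipping subset(s) below min_cells: ",
            paste(setdiff(names(tab), usable), collapse = ", "))
  expm <- 2^normalized - 1   # de-logged expression for fold changes
  out <- list()
  for (s in usable) {
    inm <- subs == s
    e_in <- rowMeans(expm[, inm, drop = FALSE])
    e_out <- rowMeans(expm[, !inm, drop = FALSE])
    lfc <- log2((e_in + 1) / (e_out + 1))
    p <- rep(1, nrow(normalized))
    candidate <- which(lfc != 0)   # identical expression everywhere -> excluded
    for (i in candidate)
      p[i] <- wilcox_safe(normalized[i, inm], normalized[i, !inm])$p.value
    padj <- stats::p.adjust(p, method = "BH")
    keep <- p < p_max & lfc > lfc_min
    if (any(keep))
      out[[s]] <- data.frame(gene = rownames(normalized)[keep], subset = s,
                             log2FC = lfc[keep], p_value = p[keep],
                             p_adj = padj[keep])
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(gene = character(), subset = character(), log2FC = numeric(),
               p_value = numeric(), p_adj = numeric())
  rownames(res) <- NULL
  class(res) <- c("marker_table", "data.frame")
  res
}

#' Per-cell cytolytic activity score
#'
#' Two interchangeable estimators of cytolytic activity from the two
#' effector genes GZMA and PRF1 (granzyme A, perforin-1):
#' `geometric_mean` — `exp(mean(log(x + eps)))` of the two normalised
#' values per cell (the classical construction); `ssgsea` — per-cell
#' ssGSEA score of a cytolytic gene set (defaults to `{GZMA, PRF1}`),
#' reusing the bulk scoring engine verbatim.
#'
#' @param normalized genes x cells log2-normalised matrix.
#' @param method `"geometric_mean"` (default) or `"ssgsea"`.
#' @param eps pseudo-value guarding zeros in the geometric mean
#'   (default 0.01).
#' @param cytolytic_set gene set used by the ssGSEA method.
#' @param alpha ssGSEA exponent for the ssGSEA method.
#' @return named numeric vector of per-cell scores.
#' @export
cytolytic_score <- function(normalized,
                            method = c("geometric_mean", "ssgsea"),
                            eps = 0.01,
                            cytolytic_set = c("GZMA", "PRF1"),
                            alpha = 0.25) {
  method <- match.arg(method)
  stopifnot(is.matrix(normalized))
  eff <- c("GZMA", "PRF1")
  missing <- eff[!(eff %in% toupper(rownames(normalized)))]
  if (length(missing))
    stop("cytolytic effector gene(s) absent: ", paste(missing, collapse = ", "))
  if (method == "geometric_mean") {
    idx <- match(eff, toupper(rownames(normalized)))
    vals <- normalized[idx, , drop = FALSE]
    return(exp(colMeans(log(vals + eps))))
  }
  sc <- ssgsea_matrix(normalized, list(cytolytic = cytolytic_set),
                      alpha = alpha, min_coverage = 0)
  stats::setNames(sc["cytolytic", ], colnames(normalized))
}

#' Test cytolytic scores between conditions, per subset and pooled
#'
#' Two-sided Wilcoxon rank-sum of the per-cell scores between the two
#' conditions, within every subset and for the pooled T-cell community
#' (`subset = "ALL"`); Benjamini-Hochberg adjustment across the subset
#' rows. Subsets represented in only one condition (or with fewer than 3
#' cells in either) are flagged and excluded from testing.
#'
#' @param scores named per-cell score vector (names = barcodes).
#' @param annotation data.frame with `barcode`, `subset`, `condition`.
#' @return data.frame of class `group_comparison`-like: `subset`,
#'   per-condition mean columns, `p_value`, `p_adj`, `stars`, `excluded`.
#' @export
subset_condition_test <- function(scores, annotation) {
  ann <- annotation[match(names(scores), annotation$barcode), ]
  if (anyNA(ann$barcode)) stop("annotation does not cover every scored cell")
  conds <- sort(unique(ann$condition))
  if (length(conds) != 2L) stop("exactly two conditions are required")
  one <- function(sel, label) {
    a <- scores[sel & ann$condition == conds[1L]]
    b <- scores[sel & ann$condition == conds[2L]]
    if (length(a) < 3L || length(b) < 3L)
      return(data.frame(subset = label,
                        mean_1 = mean(a), mean_2 = mean(b),
                        p_value = NA_real_, excluded = TRUE))
    data.frame(subset = label, mean_1 = mean(a), mean_2 = mean(b),
               p_value = wilcox_safe(b, a)$p.value, excluded = FALSE)
  }
  rows <- lapply(sort(unique(ann$subset)), function(s) one(ann$subset == s, s))
  rows <- c(rows, list(one(rep(TRUE, length(scores)), "ALL")))
  out <- do.call(rbind, rows)
  names(out)[2:3] <- paste0("mean_", conds)
  out$p_adj <- NA_real_
  ok <- !out$excluded
  out$p_adj[ok] <- stats::p.adjust(out$p_value[ok], method = "BH")
  out$stars <- significance_stars(out$p_value)
  rownames(out) <- NULL
  out
}
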