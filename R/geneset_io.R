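## Gene-set collections, expression matrices and the FRG catalog:
## construction, validation and plain-text I/O (GMT / TSV).

GENESET_CATEGORIES <- c("lica_cell", "lica_function", "tme",
                        "frg_positive", "frg_negative", "other")

#' Construct a gene-set collection
#'
#' A gene-set collection is a named list of unique gene-symbol vectors
#' carrying per-set `description` and `category` attributes. Categories
#' tag the role a set plays in the analysis: immune cell-type signatures
#' (`lica_cell`), immune-function signatures (`lica_function`), tumor
#' microenvironment metabolic categories (`tme`), ferroptosis regulator
#' direction sets (`frg_positive` / `frg_negative`), or `other`.
#'
#' @param sets named list of character vectors of gene symbols.
#' @param description named or unnamed character vector of set descriptions
#'   (recycled to `""` when missing).
#' @param category character vector of categories, one of
#'   `r paste(GENESET_CATEGORIES, collapse = ", ")`; recycled.
#' @return an object of class `gene_set_collection`.
#' @examples
#' gs <- gene_set_collection(list(A = c("TP53", "CD44"), B = c("GZMA", "PRF1")))
#' geneset_sizes(gs)
#' @export
gene_set_collection <- function(sets, description = NULL, category = "other") {
  if (!is.list(sets)) stop("'sets' must be a list of character vectors")
  nm <- names(sets)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
    stop("gene sets must have unique non-empty names")
  sets <- lapply(sets, function(g) {
    g <- as.character(g)
    g <- g[!is.na(g) & nzchar(g)]
    # case-insensitive dedup, keeping first spelling
    g[!duplicated(toupper(g))]
  })
  if (any(lengths(sets) == 0L)) stop("gene sets must be non-empty")
  description <- rep_len(as.character(description %||% ""), length(sets))
  category <- rep_len(as.character(category), length(sets))
  bad <- setdiff(unique(category), GENESET_CATEGORIES)
  if (length(bad))
    stop("unknown gene-set category: ", paste(bad, collapse = ", "))
  structure(sets,
            description = stats::setNames(description, nm),
            category = stats::setNames(category, nm),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets, sizes %d-%d\n",
              length(x), min(lengths(x)), max(lengths(x))))
  tab <- table(attr(x, "category"))
  cat("  categories:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

#' @export
`[.gene_set_collection` <- function(x, i) {
  sets <- unclass(x)[i]
  gene_set_collection(sets,
                      description = attr(x, "description")[names(sets)],
                      category = attr(x, "category")[names(sets)])
}

#' Sizes of the sets in a collection
#' @param collection a `gene_set_collection`.
#' @return named integer vector of set sizes.
#' @export
geneset_sizes <- function(collection) lengths(unclass(collection))

#' Per-set categories of a collection
#' @inheritParams geneset_sizes
#' @return named character vector of categories.
#' @export
geneset_categories <- function(collection) attr(collection, "category")

#' Read a GMT gene-set file
#'
#' Standard tab-separated GMT dialect: one set per line as
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate genes within a
#' line are dropped with a warning; a line with fewer than three fields or
#' a duplicated set name is an error.
#'
#' @param path path to a GMT file.
#' @param category category tag applied to all sets read (see
#'   [gene_set_collection()]).
#' @return a `gene_set_collection`.
#' @export
read_gmt <- function(path, category = "other") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(gene_set_collection(stats::setNames(list(), character()),
                               character(), character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop(sprintf("GMT line %d has %d field(s); need name, description, genes",
                 which(nf < 3L)[1L], nf[which(nf < 3L)[1L]]))
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm))
    stop("duplicate set name in GMT: ", nm[duplicated(nm)][1L])
  desc <- vapply(fields, `[[`, "", 2L)
  genes <- lapply(fields, function(f) f[-(1:2)])
  ndup <- sum(vapply(genes, function(g) sum(duplicated(toupper(g))), 0L))
  if (ndup > 0L)
    warning(sprintf("%d duplicate gene entries dropped while reading GMT", ndup))
  gene_set_collection(stats::setNames(genes, nm), desc, category)
}

#' Write a gene-set collection as GMT
#'
#' Inverse of [read_gmt()]: `read_gmt(write_gmt(x, p))` reproduces `x`
#' (categories are not stored in GMT and must be re-supplied on read).
#'
#' @param collection a `gene_set_collection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  nm <- names(collection)
  if (any(grepl("\t", nm, fixed = TRUE)))
    stop("set names must not contain tab characters")
  desc <- attr(collection, "description")
  lines <- vapply(seq_along(collection), function(i) {
    paste(c(nm[i], desc[[i]], collection[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

## expression matrices -----------------------------------------------------

#' Construct a validated expression matrix
#'
#' Genes in rows, samples in columns. `scale` records whether values are
#' log2 expression (the substrate every scoring stage assumes) or raw
#' counts. Duplicate gene symbols (case-insensitive) are collapsed by
#' keeping the row with the highest mean expression, the common
#' array probe-collapse convention.
#'
#' @param values numeric matrix with rownames (gene symbols) and colnames
#'   (sample IDs).
#' @param scale `"log2"` or `"counts"`.
#' @return a numeric matrix of class `expression_matrix` with a `scale`
#'   attribute.
#' @export
expression_matrix <- function(values, scale = c("log2", "counts")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (ncol(values) < 1L) stop("expression matrix has zero samples")
  if (anyDuplicated(colnames(values))) stop("duplicate sample IDs")
  if (!all(is.finite(values))) {
    idx <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite expression value at gene '%s', sample '%s'",
                 rownames(values)[idx[1L]], colnames(values)[idx[2L]]))
  }
  values <- collapse_duplicate_genes(values)
  structure(values, scale = scale,
            class = c("expression_matrix", "matrix", "array"))
}

# duplicate symbols (case-insensitive) -> keep the row with highest mean
collapse_duplicate_genes <- function(values) {
  key <- toupper(rownames(values))
  if (!anyDuplicated(key)) return(values)
  means <- rowMeans(values)
  keep <- unlist(lapply(split(seq_len(nrow(values)), key)[unique(key)],
                        function(i) i[which.max(means[i])]),
                 use.names = FALSE)
  values[sort(keep), , drop = FALSE]
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%s scale)\n",
              nrow(x), ncol(x), attr(x, "scale")))
  invisible(x)
}

#' Read an expression matrix from TSV
#'
#' Expects a tab-separated file whose first column holds gene symbols and
#' whose header row holds sample IDs. Non-numeric cells are rejected with
#' their coordinates; duplicate gene rows collapse by maximum mean.
#'
#' @param path path to the TSV file.
#' @param scale scale tag for the values, `"log2"` (default) or `"counts"`.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, scale = "log2") {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("expression TSV has zero sample columns")
  genes <- df[[1L]]
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = list(genes, colnames(vals))))
  if (anyNA(num)) {
    idx <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric expression cell at gene '%s', sample '%s'",
                 genes[idx[1L]], colnames(num)[idx[2L]]))
  }
  expression_matrix(num, scale = scale)
}

#' Write an expression matrix as TSV
#'
#' @param x an [expression_matrix()] or plain named matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  df <- data.frame(gene = rownames(x), as.data.frame(unclass(x)[, , drop = FALSE]),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## FRG catalog -------------------------------------------------------------

FRG_DIRECTIONS <- c("positive", "negative", "unassigned")

# the ten ferroptosis-related genes recovered in the cross-dataset DEG
# intersection; the bundled default catalog must contain all of them
TEN_CORE_FRGS <- c("SLC1A5", "AKR1C1", "AKR1C2", "AKR1C3", "CD44",
                   "TP53", "STEAP3", "NQO1", "HMOX1", "ACSF2")

#' Load a ferroptosis-related gene (FRG) catalog
#'
#' The catalog is a three-column TSV (`symbol`, `direction`, `source`)
#' listing ferroptosis-related genes with their regulator direction:
#' `positive` (pro-ferroptotic driver), `negative` (suppressor) or
#' `unassigned`. Unassigned entries are kept but excluded from the
#' ferroptosis potential index. With no `path` the bundled default is
#' loaded: a 63-gene catalog reconstructed from published ferroptosis
#' regulator reviews, shipped as
#' `inst/extdata/frg_catalog_reconstructed.tsv` and intended to be
#' user-replaceable (see the package vignette).
#'
#' @param path optional path to a catalog TSV; default: bundled catalog.
#' @return a `data.frame` of class `frg_catalog` with columns `symbol`,
#'   `direction`, `source`.
#' @export
load_frg_catalog <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "frg_catalog_reconstructed.tsv",
                        package = "ferrolica", mustWork = TRUE)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  need <- c("symbol", "direction", "source")
  if (!all(need %in% names(df)))
    stop("FRG catalog needs columns: ", paste(need, collapse = ", "))
  df <- df[, need]
  df$symbol <- toupper(trimws(df$symbol))
  if (anyDuplicated(df$symbol))
    stop("duplicate symbol in FRG catalog: ",
         df$symbol[duplicated(df$symbol)][1L])
  bad <- setdiff(unique(df$direction), FRG_DIRECTIONS)
  if (length(bad))
    stop("unknown regulator direction token: ", paste(bad, collapse = ", "),
         " (allowed: ", paste(FRG_DIRECTIONS, collapse = ", "), ")")
  structure(df, class = c("frg_catalog", "data.frame"))
}

#' Split an FRG catalog into direction gene sets
#'
#' @param catalog an `frg_catalog`.
#' @return a `gene_set_collection` with sets `FRG_positive` and
#'   `FRG_negative` (unassigned entries excluded).
#' @export
frg_direction_sets <- function(catalog) {
  stopifnot(inherits(catalog, "frg_catalog"))
  pos <- catalog$symbol[catalog$direction == "positive"]
  neg <- catalog$symbol[catalog$direction == "negative"]
  if (!length(pos) || !length(neg))
    stop("catalog must contain at least one positive and one negative regulator")
  gene_set_collection(
    list(FRG_positive = pos, FRG_negative = neg),
    description = c("pro-ferroptotic drivers", "ferroptosis suppressors"),
    category = c("frg_positive", "frg_negative"))
}

#' Bundled LICA immune gene sets
#'
#' Loads the 29 local-immune-cytolytic-activity signatures (15 immune
#' cell types, 14 immune functions). The bundled GMT is a reconstruction
#' of the published immune signature collections using well-established
#' marker genes; swap in original supplements with [read_gmt()] for exact
#' reproduction.
#'
#' @return a `gene_set_collection` of 29 sets, categories `lica_cell` /
#'   `lica_function`.
#' @export
lica_sets <- function() {
  path <- system.file("extdata", "lica_sets_reconstructed.gmt",
                      package = "ferrolica", mustWork = TRUE)
  gs <- read_gmt(path)
  # category encoded in the description field: "cell:" / "function:"
  desc <- attr(gs, "description")
  cat <- ifelse(startsWith(desc, "cell:"), "lica_cell", "lica_function")
  gene_set_collection(unclass(gs), description = desc, category = cat)
}

#' Bundled TME metabolic gene sets
#'
#' Loads the seven tumor-microenvironment metabolic categories (amino
#' acid, TCA cycle, nucleotide, energy, carbohydrate, lipid, vitamin &
#' cofactor metabolism). As with [lica_sets()], the bundled GMT is a
#' reconstruction from canonical pathway membership and is
#' user-replaceable.
#'
#' @return a `gene_set_collection` of 7 sets, category `tme`.
#' @export
tme_sets <- function() {
  path <- system.file("extdata", "tme_sets_reconstructed.gmt",
                      package = "ferrolica", mustWork = TRUE)
  gs <- read_gmt(path, category = "tme")
  gs
}
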