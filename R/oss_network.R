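## Overall score share (OSS) and the correlation-connected OSS (ccOSS)
## network. For one gene set with per-sample enrichment scores S_i and a
## partition of samples into m groups of sizes n_g,
##
##   OSS_g = (m / n_g) * sum_{i in g} e^{S_i} / sum_{all i} e^{S_i}
##
## i.e. the group's share of the total exponentiated score, rescaled by
## m / n_g so that equal scores give every group OSS = m / N and
## sum_g n_g * OSS_g = m exactly (a conservation identity used as an
## internal check). Scores are max-subtracted per set before
## exponentiation; the ratio of exponentials is invariant under this
## shift, so it is a pure overflow guard. A literal raw-sum reading
## (no exponentiation) is available via `exp_scores = FALSE` and refuses
## sets whose score total is not positive.

#' Per-group overall score share (OSS) of each gene set
#'
#' @param scores enrichment-score matrix (sets x samples).
#' @param groups group label per sample column; every group non-empty.
#' @param exp_scores if `TRUE` (default) shares are computed on
#'   exponentiated scores, which are strictly positive for signed
#'   enrichment scores; `FALSE` uses the raw scores and errors on sets
#'   whose per-group or total sums are not positive.
#' @return numeric matrix sets x groups of class `oss_matrix`, with
#'   attribute `group_sizes`.
#' @export
compute_oss <- function(scores, groups, exp_scores = TRUE) {
  stopifnot(is.matrix(scores))
  groups <- as.character(groups)
  if (length(groups) != ncol(scores))
    stop("'groups' must have one label per score column")
  if (!all(is.finite(scores))) stop("scores must be finite")
  labs <- unique(groups)
  ng <- vapply(labs, function(g) sum(groups == g), 0L)
  if (any(ng == 0L)) stop("every group must be non-empty")
  m <- length(labs)
  if (exp_scores) {
    shifted <- scores - apply(scores, 1L, max)   # overflow guard, share-invariant
    e <- exp(shifted)
  } else {
    e <- scores
    if (any(rowSums(e) <= 0))
      stop("raw-sum OSS undefined: set(s) with non-positive score total: ",
           paste(rownames(scores)[rowSums(e) <= 0], collapse = ", "))
  }
  tot <- rowSums(e)
  oss <- vapply(labs, function(g)
    (m / sum(groups == g)) * rowSums(e[, groups == g, drop = FALSE]) / tot,
    numeric(nrow(scores)))
  oss <- matrix(oss, nrow = nrow(scores),
                dimnames = list(rownames(scores), labs))
  structure(oss, group_sizes = stats::setNames(ng, labs),
            class = c("oss_matrix", "matrix", "array"))
}

#' Build the correlation-connected OSS (ccOSS) network
#'
#' One node per gene set, carrying its category, size (number of member
#' genes) and per-group OSS values; an edge for every pair of sets
#' sharing at least `min_shared` genes, weighted by the Pearson
#' correlation of the two sets' score vectors over all samples (edges
#' with `|r| < min_abs_r` are dropped) and signed positive/negative.
#'
#' @param collection a [gene_set_collection()] covering every scored set.
#' @param scores enrichment-score matrix (sets x samples).
#' @param oss an `oss_matrix` from [compute_oss()] on the same sets.
#' @param min_shared minimum shared-gene count for an edge (default 1).
#' @param min_abs_r minimum absolute correlation for an edge (default 0).
#' @return an object of class `ccoss_network`: list with data.frames
#'   `nodes` (`set`, `category`, `size`, one `oss_<group>` column per
#'   group) and `edges` (`from`, `to`, `shared_genes`, `jaccard`, `r`,
#'   `sign`).
#' @export
build_ccoss <- function(collection, scores, oss, min_shared = 1L,
                        min_abs_r = 0) {
  stopifnot(is.matrix(scores), inherits(oss, "oss_matrix"))
  sets <- rownames(scores)
  missing <- setdiff(sets, names(collection))
  if (length(missing))
    stop("scored set(s) absent from the collection (node size undefined): ",
         paste(missing, collapse = ", "))
  stopifnot(all(sets %in% rownames(oss)))
  categ <- geneset_categories(collection)
  if (is.null(categ)) categ <- stats::setNames(rep("other", length(collection)),
                                               names(collection))
  nodes <- data.frame(set = sets,
                      category = unname(categ[sets]),
                      size = unname(lengths(unclass(collection))[sets]))
  for (g in colnames(oss)) nodes[[paste0("oss_", g)]] <- oss[sets, g]
  edges <- list()
  if (length(sets) >= 2L) {
    upper <- lapply(unclass(collection)[sets], toupper)
    for (a in seq_len(length(sets) - 1L)) for (b in (a + 1L):length(sets)) {
      shared <- length(intersect(upper[[a]], upper[[b]]))
      if (shared < min_shared) next
      r <- stats::cor(scores[sets[a], ], scores[sets[b], ])
      if (is.na(r) || abs(r) < min_abs_r) next
      edges[[length(edges) + 1L]] <- data.frame(
        from = sets[a], to = sets[b], shared_genes = shared,
        jaccard = shared / length(union(upper[[a]], upper[[b]])),
        r = r, sign = if (r >= 0) "positive" else "negative")
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(), to = character(),
               shared_genes = integer(), jaccard = numeric(),
               r = numeric(), sign = character())
  structure(list(nodes = nodes, edges = edges, groups = colnames(oss)),
            class = "ccoss_network")
}

#' @export
print.ccoss_network <- function(x, ...) {
  cat(sprintf("ccoss_network: %d nodes, %d edges, groups: %s\n",
              nrow(x$nodes), nrow(x$edges), paste(x$groups, collapse = ", ")))
  invisible(x)
}

#' Export a ccOSS network to GraphML or JSON
#'
#' GraphML carries node attributes `category`, `size` and one
#' `oss_<group>` per group, and edge attributes `shared_genes`,
#' `jaccard`, `r`, `sign`; the JSON schema is
#' `{groups: [...], nodes: [...], edges: [...]}` with the same fields.
#' [import_network()] round-trips both formats.
#'
#' @param network a `ccoss_network`.
#' @param path output path.
#' @param format `"graphml"` or `"json"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, format = c("graphml", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(network, "ccoss_network"))
  if (format == "json") {
    jsonlite::write_json(
      list(groups = network$groups, nodes = network$nodes,
           edges = network$edges),
      path, dataframe = "rows", digits = NA, auto_unbox = FALSE)
    return(invisible(path))
  }
  g <- igraph::graph_from_data_frame(
    d = if (nrow(network$edges)) network$edges else
      data.frame(from = character(), to = character()),
    directed = FALSE, vertices = network$nodes)
  igraph::graph_attr(g, "groups") <- paste(network$groups, collapse = "|")
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Import a ccOSS network written by [export_network()]
#'
#' @param path file path.
#' @param format `"graphml"` or `"json"`.
#' @return a `ccoss_network`.
#' @export
import_network <- function(path, format = c("graphml", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    nodes <- as.data.frame(obj$nodes)
    edges <- as.data.frame(obj$edges)
    if (!nrow(edges))
      edges <- data.frame(from = character(), to = character(),
                          shared_genes = integer(), jaccard = numeric(),
                          r = numeric(), sign = character())
    return(structure(list(nodes = nodes, edges = edges,
                          groups = as.character(obj$groups)),
                     class = "ccoss_network"))
  }
  g <- igraph::read_graph(path, format = "graphml")
  va <- igraph::vertex_attr(g)
  nodes <- data.frame(set = va$name %||% va$id)
  for (nm in setdiff(names(va), c("name", "id"))) nodes[[nm]] <- va[[nm]]
  ea <- igraph::edge_attr(g)
  el <- igraph::as_edgelist(g)
  edges <- data.frame(from = el[, 1L], to = el[, 2L])
  for (nm in names(ea)) edges[[nm]] <- ea[[nm]]
  if (!nrow(edges))
    edges <- data.frame(from = character(), to = character(),
                        shared_genes = integer(), jaccard = numeric(),
                        r = numeric(), sign = character())
  if ("shared_genes" %in% names(edges))
    edges$shared_genes <- as.integer(round(edges$shared_genes))
  groups <- strsplit(igraph::graph_attr(g, "groups") %||% "", "|",
                     fixed = TRUE)[[1L]]
  structure(list(nodes = nodes, edges = edges, groups = groups),
            class = "ccoss_network")
}
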