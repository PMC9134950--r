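## Simulators producing bulk and single-cell datasets with the
## statistical structure the analysis assumes: two tumor cohorts (and
## optionally normal/adjacent groups) with planted gene-set effects on
## the log2 scale, and a T-cell compartment of 7 subsets with
## condition-dependent cytolytic effector expression. Every generator is
## deterministic for a fixed seed; ground truth is returned alongside
## the data so recovery can be measured.

#' Configuration for the bulk expression simulator
#'
#' @param n_genes number of genes in the simulated universe.
#' @param groups named integer vector: sample count per group label,
#'   e.g. `c(BCC = 15, SCC = 11)`. Labels must be unique.
#' @param gene_sets named list of gene-symbol vectors defining the sets
#'   that planted effects may target. Defaults to an empty list.
#' @param planted_effects data.frame with columns `set`, `group`,
#'   `effect` (log2 units): member genes of `set` get their mean shifted
#'   by `effect` in samples of `group`. Every `set` must name an entry of
#'   `gene_sets`; two effects may not target the same (gene, group) pair.
#' @param baseline_mean baseline log2 expression mean (default 6, a
#'   mid-range microarray/log-CPM intensity).
#' @param noise_sd Gaussian noise standard deviation on the log2 scale
#'   (default 1); must be >= 0 (0 gives the noise-free limit).
#' @param count_mode if `TRUE`, values are drawn as negative-binomial
#'   counts with the log2 structure on the mean and returned as
#'   `log2(x + 1)`; default `FALSE` (direct Gaussian log2 values).
#' @param seed integer seed.
#' @return a `bulk_sim_config` list.
#' @export
bulk_sim_config <- function(n_genes = 1000L,
                            groups = c(BCC = 15L, SCC = 11L),
                            gene_sets = list(),
                            planted_effects = NULL,
                            baseline_mean = 6,
                            noise_sd = 1,
                            count_mode = FALSE,
                            seed = 1L) {
  n_genes <- assert_count(n_genes, "n_genes", min = 2L)
  if (is.null(names(groups)) || anyDuplicated(names(groups)) ||
      any(names(groups) == ""))
    stop("'groups' must be a named vector with unique non-empty labels")
  groups <- vapply(groups, assert_count, 0L, name = "groups")
  assert_scalar_number(baseline_mean, "baseline_mean")
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0)
    stop("'noise_sd' must be a single number >= 0")
  seed <- assert_count(seed, "seed", min = 0L)
  if (is.null(planted_effects))
    planted_effects <- data.frame(set = character(), group = character(),
                                  effect = numeric())
  stopifnot(is.data.frame(planted_effects),
            all(c("set", "group", "effect") %in% names(planted_effects)))
  unresolved <- setdiff(planted_effects$set, names(gene_sets))
  if (length(unresolved))
    stop("planted effect targets unknown gene set(s): ",
         paste(unique(unresolved), collapse = ", "))
  badgrp <- setdiff(planted_effects$group, names(groups))
  if (length(badgrp))
    stop("planted effect targets unknown group(s): ",
         paste(unique(badgrp), collapse = ", "))
  # reject contradictory effects: same (gene, group) hit twice
  if (nrow(planted_effects)) {
    pairs <- unlist(lapply(seq_len(nrow(planted_effects)), function(i)
      paste(gene_sets[[planted_effects$set[i]]],
            planted_effects$group[i], sep = "\r")))
    if (anyDuplicated(pairs)) {
      d <- strsplit(pairs[duplicated(pairs)][1L], "\r", fixed = TRUE)[[1L]]
      stop(sprintf(
        "conflicting planted effects on gene '%s' in group '%s'", d[1L], d[2L]))
    }
  }
  structure(list(n_genes = n_genes, groups = groups, gene_sets = gene_sets,
                 planted_effects = planted_effects,
                 baseline_mean = baseline_mean, noise_sd = noise_sd,
                 count_mode = isTRUE(count_mode), seed = seed),
            class = "bulk_sim_config")
}

#' Simulate a bulk expression dataset with planted gene-set effects
#'
#' Gene `g` belonging to a planted set for group `G` has mean
#' `baseline_mean + effect` in `G` and `baseline_mean` elsewhere; values
#' are Gaussian on the log2 scale (or negative-binomial counts under
#' `count_mode`). Genes named in `gene_sets` are placed first in the
#' universe under their own symbols; remaining rows are filled with
#' `bg_...` background genes.
#'
#' @param config a [bulk_sim_config()].
#' @return a list with elements `expr` (an [expression_matrix()]),
#'   `groups` (data.frame `sample`, `group`) and `truth` (data.frame of
#'   per-gene planted shifts: `gene`, `group`, `effect`).
#' @export
generate_bulk <- function(config) {
  stopifnot(inherits(config, "bulk_sim_config"))
  set.seed(config$seed)
  set_genes <- unique(unlist(config$gene_sets, use.names = FALSE))
  if (length(set_genes) > config$n_genes)
    stop("n_genes smaller than the number of distinct gene-set members")
  n_bg <- config$n_genes - length(set_genes)
  bg <- setdiff(sprintf("bg_%05d", seq_len(n_bg + length(set_genes))),
                set_genes)[seq_len(n_bg)]
  genes <- c(set_genes, if (n_bg) bg)
  labels <- rep(names(config$groups), config$groups)
  samples <- sprintf("%s_s%02d", labels,
                     unlist(lapply(config$groups, seq_len), use.names = FALSE))
  mu <- matrix(config$baseline_mean, nrow = length(genes), ncol = length(samples),
               dimnames = list(genes, samples))
  pe <- config$planted_effects
  truth <- list()
  for (i in seq_len(nrow(pe))) {
    members <- config$gene_sets[[pe$set[i]]]
    mu[members, labels == pe$group[i]] <-
      mu[members, labels == pe$group[i]] + pe$effect[i]
    truth[[i]] <- data.frame(gene = members, group = pe$group[i],
                             effect = pe$effect[i])
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(gene = character(), group = character(), effect = numeric())
  if (config$count_mode) {
    counts <- matrix(stats::rnbinom(length(mu), mu = 2^mu, size = 10),
                     nrow = nrow(mu), dimnames = dimnames(mu))
    vals <- log2(counts + 1)
  } else {
    vals <- mu + matrix(stats::rnorm(length(mu), sd = config$noise_sd),
                        nrow = nrow(mu), dimnames = dimnames(mu))
  }
  list(expr = expression_matrix(vals, scale = "log2"),
       groups = data.frame(sample = samples, group = labels),
       truth = truth)
}

#' Configuration for the single-cell T-cell simulator
#'
#' Emulates a tumor-infiltrating T-cell compartment measured under two
#' conditions: seven T-cell subsets, each with its own elevated marker
#' genes, and the cytolytic effector genes GZMA/PRF1 (always present in
#' the universe) shifted by `effector_shift` log2 units in the second
#' condition.
#'
#' @param n_cells_per_subset cells simulated per subset and condition.
#' @param subsets subset labels; default the seven T-cell subsets
#'   CD8_activation, CD8_exhaustion, CD8_memory, Naive, Tfh, Th17, Treg.
#' @param conditions exactly two condition labels (default BCC, SCC).
#' @param nb_dispersion negative-binomial size parameter (> 0; variance
#'   `mu + mu^2 / size`, so large values approach Poisson).
#' @param effector_shift log2 shift (>= 0) applied to GZMA and PRF1
#'   means in the second condition, in every subset.
#' @param n_marker_genes_per_subset marker genes planted per subset
#'   (log2 shift `marker_shift` within the subset).
#' @param marker_shift log2 elevation of a subset's markers (default 2).
#' @param n_background_genes unstructured background genes (default 100).
#' @param base_mean baseline negative-binomial mean count (default 2).
#' @param seed integer seed.
#' @return an `sc_sim_config` list.
#' @export
sc_sim_config <- function(n_cells_per_subset = 200L,
                          subsets = c("CD8_activation", "CD8_exhaustion",
                                      "CD8_memory", "Naive", "Tfh",
                                      "Th17", "Treg"),
                          conditions = c("BCC", "SCC"),
                          nb_dispersion = 2,
                          effector_shift = 1,
                          n_marker_genes_per_subset = 10L,
                          marker_shift = 2,
                          n_background_genes = 100L,
                          base_mean = 2,
                          seed = 1L) {
  n_cells_per_subset <- assert_count(n_cells_per_subset, "n_cells_per_subset")
  if (length(conditions) != 2L || anyDuplicated(conditions))
    stop("exactly two distinct condition labels are required")
  if (anyDuplicated(subsets) || !length(subsets))
    stop("'subsets' must be non-empty and unique")
  assert_scalar_number(nb_dispersion, "nb_dispersion", positive = TRUE)
  if (!is.numeric(effector_shift) || effector_shift < 0)
    stop("'effector_shift' must be >= 0")
  n_marker_genes_per_subset <- assert_count(n_marker_genes_per_subset,
                                            "n_marker_genes_per_subset", min = 0L)
  n_background_genes <- assert_count(n_background_genes,
                                     "n_background_genes", min = 1L)
  assert_scalar_number(marker_shift, "marker_shift")
  assert_scalar_number(base_mean, "base_mean", positive = TRUE)
  seed <- assert_count(seed, "seed", min = 0L)
  if (n_cells_per_subset < 2L)
    stop("need at least 2 cells per subset x condition cell")
  structure(list(n_cells_per_subset = n_cells_per_subset, subsets = subsets,
                 conditions = conditions, nb_dispersion = nb_dispersion,
                 effector_shift = effector_shift,
                 n_marker_genes_per_subset = n_marker_genes_per_subset,
                 marker_shift = marker_shift,
                 n_background_genes = n_background_genes,
                 base_mean = base_mean, seed = seed),
            class = "sc_sim_config")
}

#' Simulate a single-cell T-cell count table
#'
#' Counts are negative binomial with a per-cell log-normal library-size
#' factor (sdlog 0.3) acting as exposure, so the normalisation path is
#' exercised. Marker genes are named `MK_<subset>_<i>`; GZMA and PRF1
#' are always included.
#'
#' @param config an [sc_sim_config()].
#' @return a `cell_table`: list with `counts` (genes x cells sparse
#'   matrix), `annotation` (data.frame `barcode`, `subset`, `condition`)
#'   and `truth` (data.frame of planted subset markers).
#' @export
generate_sc <- function(config) {
  stopifnot(inherits(config, "sc_sim_config"))
  set.seed(config$seed)
  subsets <- config$subsets
  conds <- config$conditions
  nps <- config$n_cells_per_subset
  marker_genes <- if (config$n_marker_genes_per_subset > 0)
    unlist(lapply(subsets, function(s)
      sprintf("MK_%s_%02d", s, seq_len(config$n_marker_genes_per_subset))),
      use.names = FALSE) else character()
  genes <- c("GZMA", "PRF1", marker_genes,
             sprintf("BG_%04d", seq_len(config$n_background_genes)))
  ann <- expand.grid(idx = seq_len(nps), subset = subsets,
                     condition = conds, stringsAsFactors = FALSE)
  ann$barcode <- sprintf("%s_%s_c%04d", ann$condition, ann$subset, ann$idx)
  n_cells <- nrow(ann)
  # per-cell exposure: log-normal library-size factor, sdlog 0.3
  sf <- stats::rlnorm(n_cells, meanlog = 0, sdlog = 0.3)
  mu <- matrix(config$base_mean, nrow = length(genes), ncol = n_cells,
               dimnames = list(genes, ann$barcode))
  # effector genes elevated above background so they are reliably detected
  mu[c("GZMA", "PRF1"), ] <- 4 * config$base_mean
  mu[c("GZMA", "PRF1"), ann$condition == conds[2L]] <-
    mu[c("GZMA", "PRF1"), ann$condition == conds[2L]] * 2^config$effector_shift
  for (s in subsets) {
    mk <- grep(sprintf("^MK_%s_", s), genes, value = TRUE)
    if (length(mk))
      mu[mk, ann$subset == s] <- mu[mk, ann$subset == s] * 2^config$marker_shift
  }
  mu <- sweep(mu, 2L, sf, "*")
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = config$nb_dispersion),
                   nrow = nrow(mu), dimnames = dimnames(mu))
  truth <- if (length(marker_genes))
    data.frame(gene = marker_genes,
               subset = rep(subsets, each = config$n_marker_genes_per_subset))
    else data.frame(gene = character(), subset = character())
  cell_table(Matrix::Matrix(counts, sparse = TRUE),
             ann[, c("barcode", "subset", "condition")], truth = truth)
}

#' Generate random gene sets with controlled pairwise overlap
#'
#' All sets share a common core of `round(overlap_fraction * min(sizes))`
#' genes; the remainder of each set is unique, so every pairwise
#' intersection equals the core. `overlap_fraction = 0` yields disjoint
#' sets; `overlap_fraction = 1` with equal sizes yields identical sets.
#'
#' @param n_sets number of sets.
#' @param size_range integer vector of length 2 (min, max set size);
#'   sizes are drawn uniformly.
#' @param overlap_fraction fraction in \[0, 1\] of the smallest set shared
#'   by all sets.
#' @param universe character vector of gene symbols to draw from.
#' @param seed integer seed.
#' @return a `gene_set_collection` of `n_sets` sets named `set_01`, ...
#' @export
generate_genesets <- function(n_sets, size_range, overlap_fraction,
                              universe, seed = 1L) {
  n_sets <- assert_count(n_sets, "n_sets")
  stopifnot(length(size_range) == 2L, size_range[1L] >= 1,
            size_range[1L] <= size_range[2L])
  if (overlap_fraction < 0 || overlap_fraction > 1)
    stop("'overlap_fraction' must be in [0, 1]")
  seed <- assert_count(seed, "seed", min = 0L)
  set.seed(seed)
  span <- seq.int(size_range[1L], size_range[2L])
  sizes <- span[sample.int(length(span), n_sets, replace = TRUE)]
  core_size <- round(overlap_fraction * min(sizes))
  need <- core_size + sum(sizes - core_size)
  if (need > length(universe))
    stop(sprintf("universe too small: need %d distinct genes, have %d",
                 need, length(universe)))
  pool <- sample(universe, need)
  core <- pool[seq_len(core_size)]
  rest <- if (core_size > 0) pool[-seq_len(core_size)] else pool
  off <- 0L
  sets <- lapply(seq_len(n_sets), function(i) {
    k <- sizes[i] - core_size
    own <- if (k > 0) rest[off + seq_len(k)] else character()
    off <<- off + k
    c(core, own)
  })
  names(sets) <- sprintf("set_%02d", seq_len(n_sets))
  gene_set_collection(sets, description = "simulated", category = "other")
}
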