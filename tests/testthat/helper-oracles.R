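# Independent oracles used across the suite. These are deliberately
# naive, loop-based implementations sharing no code with the package.

# brute-force ssGSEA running sum: rank genes by decreasing expression
# (ties by symbol), walk the list accumulating normalised rank weights
# for hits and a uniform penalty for misses, and sum the walk.
oracle_ssgsea <- function(expr, gene_set, alpha) {
  nms <- names(expr)
  ord <- order(-expr, nms, method = "radix")
  ranked <- nms[ord]
  N <- length(ranked)
  inset <- toupper(ranked) %in% toupper(gene_set)
  nh <- sum(inset)
  wsum <- 0
  for (i in seq_len(N)) if (inset[i]) wsum <- wsum + (N - i + 1)^alpha
  rs <- 0
  total <- 0
  for (i in seq_len(N)) {
    rs <- if (inset[i]) rs + (N - i + 1)^alpha / wsum else rs - 1 / (N - nh)
    total <- total + rs
  }
  total
}

# direct Benjamini-Hochberg step-up: q_(i) = min over j >= i of n*p_(j)/j
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, n * p[o[i]] / i)
    q[o[i]] <- val
    prev <- val
  }
  q
}

# textbook Pearson correlation
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# random expression matrix with unique gene symbols
random_expr <- function(n_genes, n_samples, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples, mean = 6, sd = 2),
              nrow = n_genes,
              dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                              sprintf("S%02d", seq_len(n_samples))))
  m
}

# random gene-set list over the rownames of a matrix
random_sets <- function(genes, n_sets, min_size = 3, max_size = NULL) {
  max_size <- max_size %||% max(min_size, floor(length(genes) / 2))
  sets <- lapply(seq_len(n_sets), function(i)
    sample(genes, sample(min_size:max_size, 1)))
  names(sets) <- sprintf("set%02d", seq_len(n_sets))
  sets
}

`%||%` <- function(x, y) if (is.null(x)) y else x
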