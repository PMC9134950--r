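test_that("cell normalisation follows the log-library-size formula", {
  counts <- matrix(c(5, 0, 0, 2, 3, 5), nrow = 3,
                   dimnames = list(c("GZMA", "PRF1", "G3"), c("c1", "c2")))
  ann <- data.frame(barcode = c("c1", "c2"), subset = "s", condition = "x")
  tab <- cell_table(counts, ann)
  norm <- normalize_cells(tab, scale_factor = 1e4)
  # single expressed gene: value = log2(1 + scale_factor)
  expect_equal(norm["GZMA", "c1"], log2(1 + 1e4))
  # direct formula on the other cell
  expect_equal(norm[, "c2"], log2(1 + counts[, "c2"] / 10 * 1e4))
  # doubling a cell's counts leaves its normalised vector unchanged
  tab2 <- cell_table(counts * 2L, ann)
  expect_equal(normalize_cells(tab2), norm)
  # zero-total cells are rejected by barcode
  counts0 <- counts; counts0[, 2] <- 0
  expect_error(normalize_cells(cell_table(counts0, ann)), "c2")
})

test_that("cell_table validates annotation and count integrality", {
  counts <- matrix(1:4, nrow = 2,
                   dimnames = list(c("A", "B"), c("c1", "c2")))
  ann <- data.frame(barcode = c("c1", "c2"), subset = "s", condition = "x")
  expect_s3_class(cell_table(counts, ann), "cell_table")
  expect_error(cell_table(counts, ann[1, ]), "match")
  bad <- counts; bad[1, 1] <- 1.5
  expect_error(cell_table(bad, ann), "integer")
})

test_that("cell tables round-trip through the MTX triplet format", {
  sc <- generate_sc(sc_sim_config(n_cells_per_subset = 5,
                                  n_background_genes = 20, seed = 2))
  dir <- withr::local_tempdir()
  write_cell_table(sc, dir)
  expect_true(all(file.exists(file.path(dir,
    c("matrix.mtx", "genes.tsv", "barcodes.tsv", "annotation.tsv")))))
  back <- read_cell_table(dir)
  expect_equal(as.matrix(back$counts), as.matrix(sc$counts))
  expect_identical(back$annotation$subset, sc$annotation$subset)
})

test_that("planted subset markers are recovered with high sensitivity", {
  sc <- generate_sc(sc_sim_config(n_cells_per_subset = 60,
                                  n_background_genes = 60, seed = 11))
  norm <- normalize_cells(sc)
  mk <- cluster_markers(norm, sc$annotation)
  truth_key <- paste(sc$truth$gene, sc$truth$subset)
  found_key <- paste(mk$gene, mk$subset)
  sensitivity <- mean(truth_key %in% found_key)
  expect_gte(sensitivity, 0.9)
  # markers never satisfy the thresholds in the wrong subset direction
  expect_true(all(mk$log2FC > 0.5 & mk$p_value < 0.05))
})

test_that("cluster_markers excludes flat genes and validates inputs", {
  set.seed(9)
  norm <- matrix(rnorm(200, 4), nrow = 10,
                 dimnames = list(sprintf("G%d", 1:10), sprintf("c%d", 1:20)))
  norm[1, ] <- 2   # identical everywhere -> never a marker
  ann <- data.frame(barcode = colnames(norm),
                    subset = rep(c("a", "b"), each = 10), condition = "x")
  mk <- cluster_markers(norm, ann)
  expect_false("G1" %in% mk$gene)
  expect_error(cluster_markers(norm, transform(ann, subset = "a")),
               ">= 2 subsets")
})

test_that("the geometric-mean cytolytic score satisfies its identities", {
  mk_norm <- function(gzma, prf1) {
    matrix(c(gzma, prf1), nrow = 2, byrow = TRUE,
           dimnames = list(c("GZMA", "PRF1"),
                           sprintf("c%d", seq_along(gzma))))
  }
  # (x, x) -> x and (4, 1) -> 2 at eps = 0
  expect_equal(unname(cytolytic_score(mk_norm(3, 3), eps = 0)), 3)
  expect_equal(unname(cytolytic_score(mk_norm(4, 1), eps = 0)), 2)
  # log identity on random positive pairs + scale equivariance
  set.seed(71)
  a <- runif(20, 0.1, 8); b <- runif(20, 0.1, 8)
  s <- cytolytic_score(mk_norm(a, b), eps = 0)
  expect_equal(unname(s), exp((log(a) + log(b)) / 2), tolerance = 1e-12)
  s3 <- cytolytic_score(mk_norm(3 * a, 3 * b), eps = 0)
  expect_equal(unname(s3), 3 * unname(s), tolerance = 1e-12)
  # effectors must be present
  m <- matrix(1, dimnames = list("OTHER", "c1"))
  expect_error(cytolytic_score(rbind(m, m * 2)), "GZMA")
})

test_that("the ssGSEA cytolytic score reuses the enrichment engine verbatim", {
  set.seed(13)
  norm <- matrix(runif(120, 0, 6), nrow = 12,
                 dimnames = list(c("GZMA", "PRF1", sprintf("G%d", 1:10)),
                                 sprintf("c%d", 1:10)))
  s <- cytolytic_score(norm, method = "ssgsea")
  ref <- ssgsea_matrix(norm, list(cytolytic = c("GZMA", "PRF1")),
                       alpha = 0.25, min_coverage = 0)
  expect_equal(unname(s), unname(ref["cytolytic", ]))
})

test_that("subset condition tests handle shifts, ties and missing subsets", {
  sc <- generate_sc(sc_sim_config(n_cells_per_subset = 60,
                                  effector_shift = 1, seed = 21))
  norm <- normalize_cells(sc)
  cyt <- cytolytic_score(norm)
  res <- subset_condition_test(cyt, sc$annotation)
  expect_true("ALL" %in% res$subset)
  pooled <- res[res$subset == "ALL", ]
  expect_lt(pooled$p_value, 0.01)
  expect_gt(pooled$mean_SCC, pooled$mean_BCC)

  # all-tied scores give p = 1
  ann <- data.frame(barcode = sprintf("c%d", 1:12),
                    subset = "s", condition = rep(c("A", "B"), 6))
  tied <- setNames(rep(1, 12), ann$barcode)
  res2 <- subset_condition_test(tied, ann)
  expect_equal(res2$p_value[res2$subset == "s"], 1)

  # a subset present in only one condition is excluded, not dropped
  ann3 <- rbind(ann,
                data.frame(barcode = sprintf("d%d", 1:6), subset = "only_a",
                           condition = "A"))
  sc3 <- setNames(c(rep(1, 12), rnorm(6)), ann3$barcode)
  res3 <- subset_condition_test(sc3, ann3)
  expect_true(res3$excluded[res3$subset == "only_a"])
  expect_true(is.na(res3$p_value[res3$subset == "only_a"]))
})

test_that("shuffled condition labels give a null p distribution", {
  sc <- generate_sc(sc_sim_config(n_cells_per_subset = 30,
                                  effector_shift = 0, seed = 31))
  cyt <- cytolytic_score(normalize_cells(sc))
  set.seed(42)
  ps <- vapply(1:60, function(i) {
    ann <- sc$annotation
    ann$condition <- sample(ann$condition)
    subset_condition_test(cyt, ann)$p_value[8]   # pooled row
  }, 0)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})
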