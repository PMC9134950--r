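test_that("bulk simulator is deterministic and honours the noise-free limit", {
  sets <- list(up = sprintf("TGT%02d", 1:10))
  cfg <- bulk_sim_config(n_genes = 50, groups = c(A = 5, B = 5),
                         gene_sets = sets,
                         planted_effects = data.frame(
                           set = "up", group = "B", effect = 2),
                         noise_sd = 0, seed = 3)
  sim <- generate_bulk(cfg)
  expect_equal(dim(sim$expr), c(50L, 10L))
  # noise-free limit: every member gene's group difference is exactly 2
  a <- rowMeans(sim$expr[sets$up, sim$groups$group == "A"])
  b <- rowMeans(sim$expr[sets$up, sim$groups$group == "B"])
  expect_equal(unname(b - a), rep(2, 10))
  # non-members untouched
  bg <- setdiff(rownames(sim$expr), sets$up)
  expect_true(all(sim$expr[bg, ] == cfg$baseline_mean))
  # fixed seed -> bit-identical repeat
  sim2 <- generate_bulk(cfg)
  expect_identical(unclass(sim$expr), unclass(sim2$expr))
})

test_that("null bulk simulation yields uniform t-test p-values", {
  ps <- vapply(1:100, function(s) {
    cfg <- bulk_sim_config(n_genes = 2, groups = c(A = 6, B = 6),
                           noise_sd = 1, seed = s)
    sim <- generate_bulk(cfg)
    g <- sim$groups$group
    t.test(sim$expr[1, g == "A"], sim$expr[1, g == "B"])$p.value
  }, 0)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("planted bulk effects are recovered without bias", {
  # 1000 genes, 50-gene set, effect +2, n = 10/10, across 100 seeds:
  # the mean fold-change estimate must sit within 0.1 of the truth
  sets <- list(up = sprintf("TGT%02d", 1:50))
  est <- vapply(1:100, function(s) {
    cfg <- bulk_sim_config(n_genes = 1000, groups = c(A = 10, B = 10),
                           gene_sets = sets,
                           planted_effects = data.frame(
                             set = "up", group = "B", effect = 2),
                           noise_sd = 1, seed = s)
    sim <- generate_bulk(cfg)
    g <- sim$groups$group
    mean(rowMeans(sim$expr[sets$up, g == "B"]) -
         rowMeans(sim$expr[sets$up, g == "A"]))
  }, 0)
  expect_lt(abs(mean(est) - 2), 0.1)
  # bias under 5% of the effect size
  expect_lt(abs(mean(est) - 2) / 2, 0.05)
})

test_that("conflicting planted effects are rejected with a diagnostic", {
  sets <- list(a = c("G1", "G2"), b = c("G2", "G3"))
  expect_error(
    bulk_sim_config(gene_sets = sets,
                    planted_effects = data.frame(
                      set = c("a", "b"), group = c("BCC", "BCC"),
                      effect = c(1, 2))),
    "conflicting planted effects on gene 'G2'")
  expect_error(
    bulk_sim_config(gene_sets = sets,
                    planted_effects = data.frame(
                      set = "missing", group = "BCC", effect = 1)),
    "unknown gene set")
})

test_that("single-cell simulator produces annotated NB counts deterministically", {
  cfg <- sc_sim_config(n_cells_per_subset = 20, seed = 5)
  sc <- generate_sc(cfg)
  expect_s3_class(sc, "cell_table")
  expect_equal(ncol(sc$counts), 20L * 7L * 2L)
  expect_true(all(c("GZMA", "PRF1") %in% rownames(sc$counts)))
  expect_setequal(unique(sc$annotation$subset),
                  c("CD8_activation", "CD8_exhaustion", "CD8_memory",
                    "Naive", "Tfh", "Th17", "Treg"))
  sc2 <- generate_sc(cfg)
  expect_identical(as.matrix(sc$counts), as.matrix(sc2$counts))
  expect_error(sc_sim_config(n_cells_per_subset = 1), "at least 2 cells")
  expect_error(sc_sim_config(conditions = c("A", "A", "B")), "two distinct")
})

test_that("zero effector shift leaves GZMA balanced between conditions", {
  d <- vapply(1:20, function(s) {
    sc <- generate_sc(sc_sim_config(n_cells_per_subset = 50,
                                    effector_shift = 0, seed = s))
    cond <- sc$annotation$condition
    mean(sc$counts["GZMA", cond == "SCC"]) -
      mean(sc$counts["GZMA", cond == "BCC"])
  }, 0)
  expect_lt(abs(mean(d)), 0.5)   # mean count ~8; no systematic shift
})

test_that("large NB dispersion approaches the Poisson variance-mean limit", {
  sc <- generate_sc(sc_sim_config(n_cells_per_subset = 300,
                                  nb_dispersion = 1e6,
                                  n_marker_genes_per_subset = 0, seed = 9))
  bg <- grep("^BG_", rownames(sc$counts), value = TRUE)[1:30]
  # remove the library-size exposure before checking var ~ mean
  m <- rowMeans(as.matrix(sc$counts[bg, ]))
  v <- apply(as.matrix(sc$counts[bg, ]), 1, var)
  # exposure sdlog 0.3 inflates variance ~ mu^2*(e^{0.09}-1); allow for it
  expect_lt(median(v / m), 1.5)
  expect_gt(median(v / m), 0.8)
})

test_that("generate_genesets controls pairwise overlap exactly", {
  universe <- sprintf("U%04d", 1:2000)
  # disjoint
  gs0 <- generate_genesets(5, c(10, 20), 0, universe, seed = 1)
  for (a in 1:4) for (b in (a + 1):5)
    expect_length(intersect(gs0[[a]], gs0[[b]]), 0L)
  # identical at full overlap with equal sizes
  gs1 <- generate_genesets(4, c(15, 15), 1, universe, seed = 2)
  for (k in 2:4) expect_setequal(gs1[[k]], gs1[[1]])
  # half overlap at sizes 20/20 -> intersection exactly 10
  gs5 <- generate_genesets(2, c(20, 20), 0.5, universe, seed = 3)
  expect_length(intersect(gs5[[1]], gs5[[2]]), 10L)
  # infeasible request rejected
  expect_error(generate_genesets(50, c(30, 30), 0, universe[1:100], seed = 1),
               "universe too small")
})
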