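test_that("OSS reproduces the worked two-group example exactly", {
  # group a: two samples with exp-scores summing to 3; group b: summing to 1
  # OSS_a = (2/2) * 3/4 = 0.75, OSS_b = 0.25
  s <- log(c(1.5, 1.5, 0.5, 0.5))
  scores <- matrix(s, nrow = 1,
                   dimnames = list("set1", sprintf("s%d", 1:4)))
  oss <- compute_oss(scores, c("a", "a", "b", "b"))
  expect_equal(unname(oss["set1", "a"]), 0.75, tolerance = 1e-12)
  expect_equal(unname(oss["set1", "b"]), 0.25, tolerance = 1e-12)
})

test_that("equal scores force OSS_g = m/N for any group sizes", {
  scores <- matrix(0.42, nrow = 3, ncol = 10,
                   dimnames = list(sprintf("set%d", 1:3), sprintf("s%d", 1:10)))
  groups <- rep(c("x", "y", "z"), c(5, 3, 2))
  oss <- compute_oss(scores, groups)
  expect_equal(unname(oss), matrix(3 / 10, nrow = 3, ncol = 3),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("OSS satisfies conservation, monotonicity and shift stability", {
  set.seed(17)
  for (i in 1:30) {
    n_sets <- sample(2:6, 1)
    sizes <- sample(2:6, sample(2:4, 1), replace = TRUE)
    groups <- rep(sprintf("g%d", seq_along(sizes)), sizes)
    scores <- matrix(rnorm(n_sets * length(groups)), nrow = n_sets,
                     dimnames = list(sprintf("set%d", 1:n_sets),
                                     sprintf("s%d", seq_along(groups))))
    oss <- compute_oss(scores, groups)
    m <- length(sizes)
    # conservation: sum_g n_g * OSS_g = m for every set
    cons <- oss %*% attr(oss, "group_sizes")[colnames(oss)]
    expect_true(all(abs(cons - m) < 1e-9))
    # monotonicity: raising one group's scores raises its OSS, lowers others
    g1 <- groups == "g1"
    up <- scores; up[, g1] <- up[, g1] + 0.5
    oss_up <- compute_oss(up, groups)
    expect_true(all(oss_up[, "g1"] > oss[, "g1"]))
    expect_true(all(oss_up[, colnames(oss) != "g1"] <=
                    oss[, colnames(oss) != "g1"] + 1e-12))
    # shift stability: constant shift of a set's scores changes nothing
    sh <- scores + 3
    expect_equal(unclass(compute_oss(sh, groups))[, ], unclass(oss)[, ],
                 tolerance = 1e-12)
  }
})

test_that("the literal raw-sum OSS mode works and refuses invalid sets", {
  scores <- matrix(c(3, 1, 2, 2), nrow = 1,
                   dimnames = list("s", sprintf("c%d", 1:4)))
  oss <- compute_oss(scores, c("a", "a", "b", "b"), exp_scores = FALSE)
  expect_equal(unname(oss[1, "a"]), (2 / 2) * 4 / 8)
  neg <- matrix(c(-1, -2, 1, 1), nrow = 1,
                dimnames = list("s", sprintf("c%d", 1:4)))
  expect_error(compute_oss(neg, c("a", "a", "b", "b"), exp_scores = FALSE),
               "non-positive")
})

test_that("extreme scores do not overflow the exponentiation", {
  scores <- matrix(c(800, 0, -800, 795), nrow = 1,
                   dimnames = list("s", sprintf("c%d", 1:4)))
  oss <- compute_oss(scores, c("a", "a", "b", "b"))
  expect_true(all(is.finite(oss)))
  cons <- sum(oss[1, ] * attr(oss, "group_sizes")[colnames(oss)])
  expect_equal(cons, 2, tolerance = 1e-9)
})

test_that("ccOSS edges equal brute-force pairwise intersections", {
  set.seed(29)
  universe <- sprintf("U%03d", 1:200)
  coll <- generate_genesets(6, c(8, 20), 0.4, universe, seed = 7)
  m <- random_expr(160, 8)
  rownames(m)[seq_along(universe[1:160])] <- universe[1:160]
  # score only sets fully covered by the matrix genes
  coll_cov <- gene_set_collection(
    lapply(unclass(coll), function(g) intersect(g, rownames(m))))
  scores <- ssgsea_matrix(m, coll_cov, min_coverage = 0)
  oss <- compute_oss(scores, rep(c("A", "B"), each = 4))
  net <- build_ccoss(coll_cov, scores, oss)
  # brute-force edge layer
  nm <- names(coll_cov)
  for (a in seq_len(length(nm) - 1)) for (b in (a + 1):length(nm)) {
    shared <- length(intersect(coll_cov[[a]], coll_cov[[b]]))
    row <- net$edges[net$edges$from == nm[a] & net$edges$to == nm[b], ]
    if (shared >= 1) {
      expect_equal(row$shared_genes, shared)
      expect_equal(row$r, oracle_pearson(scores[nm[a], ], scores[nm[b], ]),
                   tolerance = 1e-12)
    } else {
      expect_equal(nrow(row), 0L)
    }
  }
})

test_that("disjoint collections give zero edges; identical sets give r = 1", {
  universe <- sprintf("U%03d", 1:100)
  coll <- generate_genesets(4, c(10, 10), 0, universe, seed = 3)
  m <- random_expr(80, 6)
  rownames(m)[1:80] <- universe[1:80]
  coll_cov <- gene_set_collection(
    lapply(unclass(coll), function(g) intersect(g, rownames(m))))
  scores <- ssgsea_matrix(m, coll_cov, min_coverage = 0)
  oss <- compute_oss(scores, rep(c("A", "B"), each = 3))
  net <- build_ccoss(coll_cov, scores, oss)
  expect_equal(nrow(net$edges), 0L)

  # two identical sets: jaccard 1 and r = 1
  twin <- gene_set_collection(list(t1 = rownames(m)[1:8],
                                   t2 = rownames(m)[1:8]))
  sc2 <- ssgsea_matrix(m, twin, min_coverage = 0)
  oss2 <- compute_oss(sc2, rep(c("A", "B"), each = 3))
  net2 <- build_ccoss(twin, sc2, oss2)
  expect_equal(net2$edges$jaccard, 1)
  expect_equal(net2$edges$r, 1, tolerance = 1e-12)
  expect_identical(net2$edges$sign, "positive")
})

test_that("network export round-trips through GraphML and JSON", {
  m <- random_expr(60, 6, seed = 53)
  coll <- gene_set_collection(list(a = rownames(m)[1:10],
                                   b = rownames(m)[5:20],
                                   c = rownames(m)[30:40]))
  scores <- ssgsea_matrix(m, coll, min_coverage = 0)
  oss <- compute_oss(scores, rep(c("X", "Y"), each = 3))
  net <- build_ccoss(coll, scores, oss)
  # node attribute count: set + category + size + one OSS column per group
  expect_equal(ncol(net$nodes), 3L + 2L)

  for (fmt in c("graphml", "json")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    export_network(net, f, fmt)
    back <- import_network(f, fmt)
    expect_identical(back$groups, net$groups)
    expect_equal(back$nodes[order(back$nodes$set), ],
                 net$nodes[order(net$nodes$set), ],
                 tolerance = 1e-9, ignore_attr = TRUE)
    key <- function(e) paste(pmin(e$from, e$to), pmax(e$from, e$to))
    expect_setequal(key(back$edges), key(net$edges))
    ord_b <- order(key(back$edges)); ord_n <- order(key(net$edges))
    expect_equal(back$edges$shared_genes[ord_b], net$edges$shared_genes[ord_n])
    expect_equal(back$edges$r[ord_b], net$edges$r[ord_n], tolerance = 1e-9)
    expect_identical(back$edges$sign[ord_b], net$edges$sign[ord_n])
  }
  expect_error(export_network(net, tempfile(), "dot"), "arg")
})

test_that("a scored set missing from the collection is rejected", {
  m <- random_expr(30, 4, seed = 57)
  coll <- gene_set_collection(list(a = rownames(m)[1:5]))
  scores <- ssgsea_matrix(m, list(a = rownames(m)[1:5],
                                  ghost = rownames(m)[6:10]),
                          min_coverage = 0)
  oss <- compute_oss(scores, c("A", "A", "B", "B"))
  expect_error(build_ccoss(coll, scores, oss), "ghost")
})
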