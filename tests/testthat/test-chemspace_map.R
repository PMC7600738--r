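test_that("LSH forest returns an inserted signature as its own nearest neighbor", {
  sig <- cluster_signatures(2, 3, corrupt = 0.2, seed = 4)
  f <- build_lsh_forest(sig, n_trees = 8, depth = 4, seed = 1)
  q <- lsh_query(f, sig[1, , drop = FALSE], k = 1)
  # query rows are unnamed, so the hit must be the inserted copy at sim 1
  expect_equal(q$id[1], rownames(sig)[1])
  expect_equal(q$similarity[1], 1)

  # duplicate signatures are mutual nearest neighbors at distance 0
  dup <- sig[c(1, 1), , drop = FALSE]
  rownames(dup) <- c("d1", "d2")
  fd <- build_lsh_forest(dup, n_trees = 4, depth = 4, seed = 1)
  g <- knn_graph(fd, k = 1)
  expect_equal(nrow(g), 1)
  expect_equal(g$weight, 0)

  expect_error(build_lsh_forest(matrix(numeric(0), 0, 1024)), "at least one")
})

test_that("brute-force kNN matches the frozen ten-molecule golden edge list", {
  sig <- map4_fingerprint(stats::setNames(
    canonicalize_strip_stereo(unname(TEN_SMILES)), names(TEN_SMILES)))
  g <- brute_force_knn(sig, k = 2)
  # golden list frozen after a manual check of the pairwise similarity
  # matrix (sugar pair, dipeptide pair and aromatic pair are the closest)
  golden <- tibble::tribble(
    ~from, ~to, ~weight,
    "m07", "m08", 0.4736328125,
    "m09", "m10", 0.4951171875,
    "m05", "m06", 0.6494140625,
    "m04", "m05", 0.8183593750,
    "m02", "m03", 0.8222656250,
    "m04", "m06", 0.8710937500,
    "m01", "m02", 0.9365234375,
    "m01", "m03", 0.9531250000,
    "m03", "m08", 0.9824218750,
    "m02", "m07", 0.9912109375,
    "m01", "m09", 0.9921875000,
    "m01", "m10", 0.9921875000
  )
  expect_equal(as.data.frame(g)[, c("from", "to", "weight")],
               as.data.frame(golden))
})

test_that("brute-force kNN handles equidistant points and k >= n", {
  sig <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 5, 6), c = c(1, 2, 7, 8))
  g <- brute_force_knn(sig, k = 2)
  # all pairs share exactly positions 1-2: an equilateral triangle
  expect_equal(nrow(g), 3)
  expect_true(all(g$weight == 0.5))

  expect_warning(gk <- brute_force_knn(sig, k = 5), "truncating")
  expect_equal(nrow(gk), 3)  # complete graph on 3 nodes

  expect_error(brute_force_knn(sig[1, , drop = FALSE], k = 1), "at least two")
})

test_that("LSH kNN recall against brute force is high on clustered signatures", {
  sig <- cluster_signatures(8, 15, corrupt = 0.25, seed = 7)
  f <- build_lsh_forest(sig, n_trees = 16, depth = 8, seed = 2)
  hits <- lsh_query(f, sig, k = 6, exclude_self = TRUE)
  K <- kernel_matrix(sig)
  exact <- exact_topk(K, 6)
  expect_gte(mean_recall(hits, exact, 6), 0.8)
})

test_that("Kruskal MST matches closed-form cases and stays within the graph", {
  tri <- tibble::tibble(from = c("a", "a", "b"), to = c("b", "c", "c"),
                        weight = c(0.1, 0.9, 0.2))
  t1 <- mst_kruskal(tri)
  expect_equal(sort(t1$weight), c(0.1, 0.2))
  expect_equal(attr(t1, "total_weight"), 0.3)

  # a tree input is returned unchanged (it is already its own MST)
  path <- tibble::tibble(from = c("a", "b"), to = c("b", "c"),
                         weight = c(0.4, 0.6))
  t2 <- mst_kruskal(path)
  expect_equal(nrow(t2), 2)
  expect_equal(attr(t2, "total_weight"), 1.0)

  # edges of the tree are a subset of the input edges
  g <- withr::with_seed(31, random_graph(20, p = 0.2))
  t3 <- mst_kruskal(g)
  key <- function(d) paste(d$from, d$to, signif(d$weight, 12))
  expect_true(all(key(t3) %in% key(g)))
  # acyclic and spanning: |E| = |V| - components
  expect_equal(nrow(t3), length(attr(t3, "nodes")) - max(attr(t3, "components")))
})

test_that("Kruskal total weight equals the independent Prim oracle on random graphs", {
  withr::with_seed(17, {
    for (i in 1:20) {
      g <- random_graph(30, p = 0.1)
      t <- mst_kruskal(g)
      expect_equal(attr(t, "total_weight"), prim_total_weight(g), tolerance = 1e-12)
    }
  })
})

test_that("MST is invariant to input row order", {
  g <- withr::with_seed(8, random_graph(25, p = 0.15))
  t1 <- mst_kruskal(g)
  gs <- g[withr::with_seed(9, sample.int(nrow(g))), ]
  attr(gs, "nodes") <- attr(g, "nodes")
  t2 <- mst_kruskal(gs)
  expect_equal(as.data.frame(t1), as.data.frame(t2))
})

test_that("exact and LSH pipelines agree on MST total weight at k = n - 1", {
  sig <- cluster_signatures(4, 8, corrupt = 0.3, seed = 12)
  n <- nrow(sig)
  gb <- brute_force_knn(sig, k = n - 1)
  f <- build_lsh_forest(sig, n_trees = 16, depth = 6, seed = 3)
  gl <- knn_graph(f, k = n - 1)
  expect_equal(attr(mst_kruskal(gl), "total_weight"),
               attr(mst_kruskal(gb), "total_weight"), tolerance = 1e-12)
})

test_that("component linking recovers a single display tree", {
  sig <- cluster_signatures(3, 4, corrupt = 0.02, seed = 5)
  g <- brute_force_knn(sig, k = 2)
  # drop inter-cluster edges to force a disconnected graph
  g2 <- g[g$weight < 0.5, ]
  attr(g2, "nodes") <- attr(g, "nodes")
  t0 <- mst_kruskal(g2)
  expect_gt(max(attr(t0, "components")), 1)
  t1 <- mst_kruskal(g2, link_components = TRUE, signatures = sig)
  expect_equal(max(attr(t1, "components")), 1)
  expect_equal(nrow(t1), nrow(sig) - 1)
  expect_true(any(t1$linked))
  expect_error(mst_kruskal(g2, link_components = TRUE), "signature")
})

test_that("graph export writes a round-trippable edge list and valid GraphML", {
  sig <- cluster_signatures(2, 3, corrupt = 0.1, seed = 20)
  tree <- mst_kruskal(brute_force_knn(sig, k = 2))
  ann <- tibble::tibble(compound_id = rownames(sig),
                        mw = seq(100, 600, 100), origin = rep(c("b", "f"), 3))
  prefix <- file.path(withr::local_tempdir(), "map")
  paths <- export_graph(tree, ann, prefix)
  edges <- readr::read_tsv(paths[["edges"]], show_col_types = FALSE)
  expect_equal(nrow(edges), nrow(tree))
  expect_equal(sort(edges$weight), sort(tree$weight))
  g2 <- igraph::read_graph(paths[["graphml"]], format = "graphml")
  expect_equal(igraph::vcount(g2), nrow(sig))
  expect_equal(igraph::ecount(g2), nrow(tree))
  expect_true(all(c("mw", "origin") %in% igraph::vertex_attr_names(g2)))

  # 2-node tree -> single edge row
  two <- mst_kruskal(tibble::tibble(from = "a", to = "b", weight = 0.5))
  p2 <- export_graph(two, NULL, file.path(withr::local_tempdir(), "two"))
  expect_equal(nrow(readr::read_tsv(p2[["edges"]], show_col_types = FALSE)), 1)

  # missing annotation ids are reported
  expect_error(export_graph(tree, ann[-1, ], prefix), ann$compound_id[1])
})

test_that("tree layout is deterministic and separates nodes", {
  path <- mst_kruskal(tibble::tibble(from = c("a", "b"), to = c("b", "c"),
                                     weight = c(0.4, 0.6)))
  lay <- tree_layout(path)
  expect_equal(nrow(lay), 3)
  expect_equal(nrow(dplyr::distinct(lay[, c("x", "y")])), 3)
  expect_identical(tree_layout(path), tree_layout(path))

  # star: leaves distinct from the center
  star <- mst_kruskal(tibble::tibble(from = "hub", to = c("l1", "l2", "l3"),
                                     weight = c(0.1, 0.2, 0.3)))
  ls <- tree_layout(star)
  hub <- ls[ls$id == "hub", ]
  leaves <- ls[ls$id != "hub", ]
  expect_true(all(leaves$x != hub$x | leaves$y != hub$y))
})
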