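make_tacs <- function(mat, voi = rep("A", nrow(mat))) {
  sched <- frame_schedule(rep(60, ncol(mat)))
  kinclust:::new_tac_matrix(
    mat, sched$midpoint_min,
    tibble::tibble(voi = voi, voxel_id = seq_len(nrow(mat)),
                   x = seq_len(nrow(mat)), y = 1L, z = 1L),
    sched
  )
}

test_that("Pearson correlations match hand-computed values", {
  x <- c(1, 2, 3, 4)
  y <- c(1, 2, 3, 5)
  vc <- pearson_matrix(make_tacs(rbind(x, y, -x + 10)))
  expect_equal(vc$r[1, 1], 1)
  expect_equal(vc$r[1, 2], 0.9827, tolerance = 1e-4)
  expect_equal(vc$r[1, 2], cor(x, y), tolerance = 1e-12)
  expect_equal(vc$r[1, 3], -1)
  expect_lt(max(abs(vc$r - t(vc$r))), 1e-12)
})

test_that("zero-variance voxels are excluded, not NaN-propagated", {
  mat <- rbind(c(1, 2, 3), c(2, 2, 2), c(3, 1, 2))
  expect_message(vc <- pearson_matrix(make_tacs(mat)), "zero-variance")
  expect_equal(nrow(vc$nodes), 2)
  expect_equal(nrow(vc$dropped), 1)
  expect_equal(vc$dropped$voxel_id, 2)
  expect_false(anyNA(vc$r))
  expect_error(pearson_matrix(make_tacs(matrix(1:3, ncol = 1))), "two frames")
})

test_that("thresholding keeps exactly the edges at or above r_min", {
  mat <- rbind(c(0, 1, 2.2, 3), c(0, 1.2, 2, 3.4), c(1, 0.4, 2.8, 2.4),
               c(3, 2, 1, 0))
  vc <- pearson_matrix(make_tacs(mat))
  g_all <- threshold_graph(vc, -1)
  expect_equal(nrow(g_all$edges), 6)  # complete graph on 4 nodes
  g <- threshold_graph(vc, 0.7)
  manual <- sum(vc$r[upper.tri(vc$r)] >= 0.7)
  expect_equal(nrow(g$edges), manual)
  expect_true(all(g$edges$weight >= 0.7))
  expect_true(all(g$edges$from < g$edges$to))
  g_none <- threshold_graph(vc, 1)
  expect_equal(nrow(g_none$edges), 0)
  expect_error(threshold_graph(vc, 1.5), "\\[-1, 1\\]")
})

test_that("kNN reduction follows union semantics", {
  # star K(1,5): hub keeps its single best edge, but all edges survive
  # through each leaf's own top-1
  star <- make_test_graph(tibble::tibble(
    from = 1, to = 2:6, weight = c(0.9, 0.8, 0.7, 0.6, 0.5)
  ))
  red <- knn_reduce(star, 1)
  expect_equal(nrow(red$edges), 5)
  # a node with degree <= k keeps all its edges
  g <- random_test_graph(8, p = 0.5, seed = 2)
  deg <- table(c(g$edges$from, g$edges$to))
  red8 <- knn_reduce(g, 8)
  expect_identical(red8$edges, g$edges)
  # retained edges are always a subset of the input
  red2 <- knn_reduce(g, 2)
  key <- function(e) paste(e$from, e$to)
  expect_true(all(key(red2$edges) %in% key(g$edges)))
})

test_that("kNN reduction matches a brute-force oracle on random graphs", {
  brute_knn <- function(graph, k) {
    e <- graph$edges
    keep <- logical(nrow(e))
    for (v in unique(c(e$from, e$to))) {
      inc <- which(e$from == v | e$to == v)
      nbr <- ifelse(e$from[inc] == v, e$to[inc], e$from[inc])
      ord <- inc[order(-e$weight[inc], nbr)]
      keep[utils::head(ord, k)] <- TRUE
    }
    e[keep, ]
  }
  for (seed in 1:8) {
    g <- random_test_graph(10, p = 0.6, seed = seed)
    for (k in c(1, 3, 5)) {
      expect_identical(knn_reduce(g, k)$edges, brute_knn(g, k),
                       label = sprintf("seed %d k %d", seed, k))
    }
  }
})

test_that("small components are filtered with dropped-node reporting", {
  # components of size 3 and 12
  cl3 <- utils::combn(1:3, 2)
  cl12 <- utils::combn(4:15, 2)
  g <- make_test_graph(tibble::tibble(
    from = c(cl3[1, ], cl12[1, ]), to = c(cl3[2, ], cl12[2, ]),
    weight = 0.9
  ))
  f <- filter_components(g, 10)
  expect_equal(sort(f$nodes$node), 4:15)
  expect_equal(sort(f$dropped$voxel_id), 1:3)
  expect_true(all(f$dropped$reason == "small component"))
  # min_size 1 is the identity
  expect_equal(filter_components(g, 1)$nodes, g$nodes)
  # all retained nodes have degree >= 1 after filtering
  expect_true(all(f$nodes$node %in% c(f$edges$from, f$edges$to)))
})

test_that("graph exports round trip and carry attributes", {
  g <- two_clique_graph()
  dir <- withr::local_tempdir()
  el <- file.path(dir, "edges.tsv")
  write_edge_list(g, el)
  back <- read_edge_list(el)
  expect_equal(back$edges, g$edges)
  gml <- file.path(dir, "graph.graphml")
  write_graphml(g, gml)
  gg <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(gg), nrow(g$edges))
  expect_setequal(igraph::V(gg)$voi, g$nodes$voi)
})
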