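test_that("a single clique collapses to one cluster", {
  cmb <- utils::combn(1:6, 2)
  g <- make_test_graph(tibble::tibble(from = cmb[1, ], to = cmb[2, ],
                                      weight = 0.9))
  cl <- mcl(g, granularity = 1.2)
  expect_equal(dplyr::n_distinct(cl$assignment$cluster), 1)
  expect_true(cl$converged)
})

test_that("bridged cliques separate when inflation resolves them", {
  # two 10-cliques with one 0.71 bridge split at granularity 1.2
  g10 <- two_clique_graph(k = 10, bridge_weight = 0.71)
  cl <- mcl(g10, granularity = 1.2)
  parts <- partition_sets(cl$assignment$node, cl$assignment$cluster)
  expect_equal(parts, list(1:10, 11:20))
  expect_equal(partition_sets(g10$nodes$node,
                              reference_mcl(g10, inflation = 1.2)), parts)
  # two 5-cliques need granularity 1.3; at 1.2 the flow stays joint,
  # and the implementation agrees with the dense oracle either way
  g5 <- two_clique_graph(k = 5, bridge_weight = 0.71)
  cl12 <- mcl(g5, granularity = 1.2)
  expect_equal(
    partition_sets(cl12$assignment$node, cl12$assignment$cluster),
    partition_sets(g5$nodes$node, reference_mcl(g5, inflation = 1.2))
  )
  cl13 <- mcl(g5, granularity = 1.3)
  parts13 <- partition_sets(cl13$assignment$node, cl13$assignment$cluster)
  expect_equal(parts13, list(1:5, 6:10))
  expect_equal(partition_sets(g5$nodes$node,
                              reference_mcl(g5, inflation = 1.3)), parts13)
})

test_that("the production MCL matches the dense reference on small graphs", {
  fixtures <- c(
    list(two_clique_graph(3, 0.75), two_clique_graph(5, 0.71)),
    lapply(1:10, function(s) random_test_graph(12, p = 0.4, seed = s)),
    lapply(11:15, function(s) random_test_graph(7, p = 0.6, seed = s))
  )
  for (i in seq_along(fixtures)) {
    g <- fixtures[[i]]
    cl <- quiet(mcl(g, granularity = 1.4))
    oracle <- reference_mcl(g, inflation = 1.4)
    expect_equal(
      partition_sets(cl$assignment$node, cl$assignment$cluster),
      partition_sets(g$nodes$node, oracle),
      label = sprintf("fixture %d", i)
    )
  }
})

test_that("MCL output is a partition of the retained nodes", {
  for (s in 1:5) {
    g <- random_test_graph(15, p = 0.3, seed = s)
    g <- filter_components(g, 2)
    cl <- quiet(mcl(g, granularity = 1.5))
    expect_equal(sort(cl$assignment$node), sort(g$nodes$node))
    expect_equal(sum(table(cl$assignment$cluster)), nrow(g$nodes))
    expect_true(all(table(cl$assignment$cluster) >= 1))
  }
})

test_that("higher granularity never decreases the cluster count", {
  fixtures <- list(
    two_clique_graph(5, 0.71),
    random_test_graph(20, p = 0.3, seed = 3),
    random_test_graph(16, p = 0.5, seed = 7)
  )
  for (g in fixtures) {
    counts <- vapply(c(1.2, 1.5, 2, 4), function(infl) {
      cl <- quiet(mcl(g, granularity = infl))
      dplyr::n_distinct(cl$assignment$cluster)
    }, numeric(1))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("pipeline partitions are equivariant under voxel permutation", {
  ph <- generate_phantom(default_phantom_spec(seed = 4))
  img <- to_suv(ph$image)
  tacs <- extract_tacs(img, place_biopsies(img, ph$centers[1:3, ]))
  perm <- withr::with_seed(2, sample(nrow(tacs$values)))
  tacs_perm <- kinclust:::new_tac_matrix(
    tacs$values[perm, ], tacs$midpoints_min, tacs$voxels[perm, ],
    tacs$schedule
  )
  cl <- quiet(cluster_voxels(tacs))
  clp <- quiet(cluster_voxels(tacs_perm))
  key <- function(a) {
    ids <- paste(a$voi, a$voxel_id)
    partition_sets(ids, a$cluster)
  }
  expect_equal(key(cl$assignment), key(clp$assignment))
})

test_that("a noise-free two-class phantom is recovered with purity 1", {
  ph <- generate_phantom(default_phantom_spec(seed = 1, noise_scale = 0))
  img <- to_suv(ph$image)
  tacs <- extract_tacs(
    img, place_biopsies(img, ph$centers[ph$centers$label %in%
                                          c("malignant", "inflammatory"), ])
  )
  cl <- quiet(cluster_voxels(tacs))
  pur <- cluster_purity(cl)
  expect_true(all(pur$purity == 1))
  expect_equal(nrow(cl$assignment), 600)
})

test_that("degenerate graphs are handled", {
  g1 <- make_test_graph(tibble::tibble(from = integer(0), to = integer(0),
                                       weight = numeric(0)), n_nodes = 3)
  cl <- mcl(g1, granularity = 1.2)
  expect_equal(dplyr::n_distinct(cl$assignment$cluster), 3)  # singletons
  expect_error(mcl(two_clique_graph(), granularity = 1), "exceed")
})
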