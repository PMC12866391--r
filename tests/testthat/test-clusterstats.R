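asg <- function(voi, cluster) {
  tibble::tibble(node = seq_along(voi), voi = voi,
                 voxel_id = seq_along(voi), cluster = cluster)
}

test_that("purity and composition follow their definitions", {
  a <- asg(rep("A", 10), rep(1, 10))
  expect_equal(cluster_purity(a)$purity, 1)
  b <- asg(c(rep("A", 96), rep("B", 4)), rep(1, 100))
  expect_equal(cluster_purity(b)$purity, 0.96)
  expect_equal(cluster_purity(b)$majority_voi, "A")
  c2 <- asg(c(rep("A", 5), rep("B", 5)), rep(1, 10))
  expect_equal(cluster_purity(c2)$purity, 0.5)
  comp <- cluster_composition(b)
  sums <- tapply(comp$fraction, comp$cluster, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("clusters-per-VOI applies the membership fraction rule", {
  a <- asg(rep("V", 100), c(rep(1, 60), rep(2, 30), rep(3, 10)))
  expect_equal(clusters_per_voi(a, 0.10)$n_clusters, 3)
  expect_equal(clusters_per_voi(a, 0.15)$n_clusters, 2)
  one <- asg(rep("V", 50), rep(1, 50))
  expect_equal(clusters_per_voi(one)$n_clusters, 1)
  # cohort averaging over per-VOI counts
  counts <- c(1, 2, 1, 2, 2)
  expect_equal(mean(counts), 1.6)
  expect_error(clusters_per_voi(a, 0), "\\(0, 1\\]")
})

test_that("averaged cluster TACs use frame-wise mean and population SD", {
  tacs <- kinclust:::new_tac_matrix(
    rbind(c(1, 2), c(3, 4)),
    frame_schedule(c(60, 60))$midpoint_min,
    tibble::tibble(voi = "V", voxel_id = 1:2, x = 1:2, y = 1L, z = 1L),
    frame_schedule(c(60, 60))
  )
  a <- asg(rep("V", 2), c(1, 1))
  avg <- averaged_cluster_tac(a, tacs)
  expect_equal(avg$mean_suv, c(2, 3))
  expect_equal(avg$sd_suv, c(1, 1))  # population convention
  single <- averaged_cluster_tac(asg("V", 1)[1, ], tacs)
  expect_equal(single$sd_suv, c(0, 0))
  two_same <- kinclust:::new_tac_matrix(
    rbind(c(1, 2), c(1, 2)), tacs$midpoints_min,
    tacs$voxels, tacs$schedule
  )
  avg2 <- averaged_cluster_tac(a, two_same)
  expect_equal(avg2$sd_suv, c(0, 0))
})

test_that("coclustering fractions hit their boundary cases", {
  both <- asg(c(rep("L", 5), rep("R", 5)), rep(1, 10))
  expect_equal(cocluster_fraction(both, "L", "R"), 1)
  apart <- asg(c(rep("L", 5), rep("R", 5)), c(rep(1, 5), rep(2, 5)))
  expect_equal(cocluster_fraction(apart, "L", "R"), 0)
  expect_error(cocluster_fraction(apart, "L", "missing"), "retained")
})

test_that("cluster reports assemble consistent summaries", {
  ph <- generate_phantom(default_phantom_spec(seed = 3))
  img <- to_suv(ph$image)
  tacs <- extract_tacs(img, place_biopsies(img, ph$centers))
  cl <- quiet(cluster_voxels(tacs))
  rep <- cluster_report(cl, tacs,
                        pathologic = c("malignant", "inflammatory"))
  sums <- tapply(rep$composition$fraction, rep$composition$cluster, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_true(all(rep$vois$retained_frac >= 0 & rep$vois$retained_frac <= 1))
  gl <- glance(rep)
  expect_true(gl$mean_purity >= gl$min_purity)
  td <- tidy(rep)
  expect_identical(td, rep$clusters)
  # purity is invariant to cluster relabeling
  shuffled <- cl$assignment
  relabel <- withr::with_seed(1, sample(max(shuffled$cluster)))
  shuffled$cluster <- relabel[shuffled$cluster]
  expect_equal(sort(cluster_purity(shuffled)$purity),
               sort(rep$clusters$purity))
})

test_that("combined networks are affine invariant and degenerate correctly", {
  ph <- generate_phantom(default_phantom_spec(seed = 5))
  img <- to_suv(ph$image)
  lesions <- ph$centers[ph$centers$label %in%
                          c("malignant", "inflammatory"), ]
  tacs <- extract_tacs(img, place_biopsies(img, lesions))
  params <- network_params(0.9, 9, 1.3, 10)
  one <- build_combined_network(list(tacs), params = params)
  direct <- quiet(cluster_voxels(tacs, params))
  expect_equal(
    partition_sets(paste(sub("^scan1:", "", one$clustering$assignment$voi),
                         one$clustering$assignment$voxel_id),
                   one$clustering$assignment$cluster),
    partition_sets(paste(direct$assignment$voi, direct$assignment$voxel_id),
                   direct$assignment$cluster)
  )
  # multiplying one scan's TACs by a positive constant changes nothing
  tacs_scaled <- tacs
  tacs_scaled$values <- tacs$values * 3.7
  two_a <- build_combined_network(list(tacs, tacs), params = params)
  two_b <- build_combined_network(list(tacs, tacs_scaled), params = params)
  expect_equal(
    partition_sets(paste(two_a$clustering$assignment$voi,
                         two_a$clustering$assignment$voxel_id),
                   two_a$clustering$assignment$cluster),
    partition_sets(paste(two_b$clustering$assignment$voi,
                         two_b$clustering$assignment$voxel_id),
                   two_b$clustering$assignment$cluster)
  )
  # duplicating a scan duplicates every cluster's composition
  comp <- two_a$report$composition
  comp$scan <- sub(":.*$", "", comp$voi)
  comp$tissue <- sub("^scan[0-9]+:", "", comp$voi)
  by_cluster <- split(comp, comp$cluster)
  for (cc in by_cluster) {
    per_scan <- tapply(cc$n, cc$scan, sum)
    if (length(per_scan) == 2) expect_equal(per_scan[[1]], per_scan[[2]])
  }
  # mismatched frame axes are a schedule error
  short <- kinclust:::new_tac_matrix(
    tacs$values[, 1:27], tacs$midpoints_min[1:27], tacs$voxels,
    frame_schedule(tacs$schedule$duration_s[1:27])
  )
  expect_error(build_combined_network(list(tacs, short)), "schedule")
})

test_that("a combined malignant/benign cohort separates by washout", {
  mk_scan <- function(seed, class) {
    k <- dplyr::filter(tissue_kinetics(), .data$class_name == !!class)
    organs <- kinclust:::.organ_row(class, NULL, 3L, 3L, k)
    spec <- phantom_spec(organs, grid_dim = c(14L, 14L, 7L), seed = seed)
    ph <- generate_phantom(spec)
    img <- to_suv(ph$image)
    extract_tacs(img, place_biopsies(img, ph$centers))
  }
  scans <- c(lapply(1:3, mk_scan, class = "malignant"),
             lapply(4:6, mk_scan, class = "inflammatory"))
  res <- quiet(build_combined_network(scans, params = combined_defaults()))
  rep <- res$report
  tails <- dplyr::filter(rep$avg_tacs, .data$frame == 28) |>
    dplyr::left_join(rep$clusters[, c("cluster", "majority_voi")],
                     by = "cluster") |>
    dplyr::mutate(class = sub("^scan[0-9]+:", "", .data$majority_voi))
  mal <- tails$mean_suv[tails$class == "malignant"]
  ben <- tails$mean_suv[tails$class == "inflammatory"]
  expect_gt(length(mal), 0)
  expect_gt(length(ben), 0)
  expect_gt(min(mal), max(ben))  # sustained late signal in malignant clusters
})

test_that("parameter tuning tabulates the separation/coverage trade-off", {
  ph <- generate_phantom(default_phantom_spec(seed = 2))
  img <- to_suv(ph$image)
  tacs <- extract_tacs(
    img, place_biopsies(img, ph$centers[ph$centers$label %in%
                                          c("malignant", "inflammatory",
                                            "kidney"), ])
  )
  grid1 <- data.frame(r_min = 0.7, k = 9, granularity = 1.2,
                      min_component_size = 10)
  t1 <- quiet(tune_params(tacs, grid1))
  expect_equal(nrow(t1), 1)
  grid <- data.frame(r_min = c(0.5, 0.7, 0.9), k = 9, granularity = 1.2,
                     min_component_size = 10)
  tab <- quiet(tune_params(tacs, grid))
  expect_true(all(diff(tab$retained_frac) <= 0))
  expect_true(any(tab$mean_purity >= 0.95 & tab$retained_frac >= 0.8))
})
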