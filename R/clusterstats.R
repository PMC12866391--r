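as_assignment <- function(x) {
  if (inherits(x, "mcl_clustering")) return(x$assignment)
  if (is.data.frame(x) && all(c("voi", "cluster") %in% names(x))) {
    return(x)
  }
  abort("Expected an `mcl_clustering` or a tibble with `voi` and `cluster`.")
}

#' Cluster purity
#'
#' Purity of a cluster is the largest fraction of its members originating
#' from a single source VOI; a cluster drawn wholly from one VOI has
#' purity 1.
#'
#' @param x An `mcl_clustering` or an assignment tibble with `voi` and
#'   `cluster` columns.
#' @return Tibble `cluster`, `size`, `majority_voi`, `purity`.
#' @export
cluster_purity <- function(x) {
  a <- as_assignment(x)
  count(a, .data$cluster, .data$voi) |>
    group_by(.data$cluster) |>
    summarise(
      size = sum(.data$n),
      majority_voi = .data$voi[which.max(.data$n)],
      purity = max(.data$n) / sum(.data$n),
      .groups = "drop"
    )
}

#' Cluster composition
#'
#' @param x As in [cluster_purity()].
#' @return Long tibble `cluster`, `voi`, `n`, `fraction`; fractions sum
#'   to 1 within each cluster.
#' @export
cluster_composition <- function(x) {
  a <- as_assignment(x)
  count(a, .data$cluster, .data$voi) |>
    group_by(.data$cluster) |>
    mutate(fraction = .data$n / sum(.data$n)) |>
    ungroup()
}

#' Clusters per VOI
#'
#' Counts, for every VOI, the clusters that substantially contain it: a
#' cluster counts towards a VOI when it holds at least `min_frac` of that
#' VOI's retained voxels.  The fraction rule (default 10%) suppresses
#' stray-voxel counts; it is the package's explicit operationalisation of
#' "number of clusters per VOI".
#'
#' @param x As in [cluster_purity()].
#' @param min_frac Membership fraction threshold in `(0, 1]`.
#' @return Tibble `voi`, `n_retained`, `n_clusters`.
#' @export
clusters_per_voi <- function(x, min_frac = 0.10) {
  if (min_frac <= 0 || min_frac > 1) abort("`min_frac` must lie in (0, 1].")
  a <- as_assignment(x)
  count(a, .data$voi, .data$cluster) |>
    group_by(.data$voi) |>
    summarise(
      n_retained = sum(.data$n),
      n_clusters = sum(.data$n >= min_frac * sum(.data$n)),
      .groups = "drop"
    )
}

#' Averaged cluster time-activity curves
#'
#' Frame-wise mean and dispersion of the member-voxel TACs of every
#' cluster.  Dispersion uses the population SD (divisor n), so singleton
#' clusters report zero.
#'
#' @param x As in [cluster_purity()].
#' @param tacs The `tac_matrix` the clustering was computed from.
#' @return Tibble `cluster`, `frame`, `midpoint_min`, `mean_suv`,
#'   `sd_suv`, `n_voxels`.
#' @export
averaged_cluster_tac <- function(x, tacs) {
  a <- as_assignment(x)
  stopifnot(inherits(tacs, "tac_matrix"))
  key <- paste(tacs$voxels$voi, tacs$voxels$voxel_id)
  rows <- match(paste(a$voi, a$voxel_id), key)
  if (anyNA(rows)) abort("Assignment refers to voxels missing from `tacs`.")
  purrr::map_dfr(split(seq_len(nrow(a)), a$cluster), function(sel) {
    vals <- tacs$values[rows[sel], , drop = FALSE]
    tibble(
      cluster = a$cluster[sel[1]],
      frame = seq_len(ncol(vals)),
      midpoint_min = tacs$midpoints_min,
      mean_suv = colMeans(vals),
      sd_suv = apply(vals, 2, sd_pop),
      n_voxels = nrow(vals)
    )
  })
}

#' Coclustering fraction of two VOIs
#'
#' Fraction of the voxels of two VOIs (jointly) that lie in clusters
#' containing voxels of both; 1 when the VOIs share all their clusters,
#' 0 when fully separated.
#'
#' @param x As in [cluster_purity()].
#' @param voi_a,voi_b VOI labels.
#' @return A single fraction.
#' @export
cocluster_fraction <- function(x, voi_a, voi_b) {
  a <- as_assignment(x)
  in_ab <- a$voi %in% c(voi_a, voi_b)
  if (!any(a$voi == voi_a) || !any(a$voi == voi_b)) {
    abort("Both VOIs must have retained voxels.")
  }
  shared <- intersect(a$cluster[a$voi == voi_a], a$cluster[a$voi == voi_b])
  sum(in_ab & a$cluster %in% shared) / sum(in_ab)
}

#' Full cluster report
#'
#' Bundles the cluster-level readouts of a clustering run: per-cluster
#' size, composition and purity, averaged cluster TACs, per-VOI cluster
#' counts and retained fractions, and pairwise VOI coclustering.
#'
#' @param clustering An `mcl_clustering`.
#' @param tacs The `tac_matrix` it was computed from.
#' @param min_frac Cluster-membership fraction for [clusters_per_voi()].
#' @param pathologic Character vector naming the pathologic (lesion) VOIs;
#'   used for the cohort summary in [glance.cluster_report()].  Default:
#'   all VOIs.
#' @return A `cluster_report` list: `clusters`, `composition`,
#'   `avg_tacs`, `vois`, `cocluster`, `params`.
#' @export
cluster_report <- function(clustering, tacs, min_frac = 0.10,
                           pathologic = NULL) {
  stopifnot(inherits(clustering, "mcl_clustering"))
  a <- clustering$assignment
  total <- count(tacs$voxels, .data$voi, name = "n_total")
  vois <- clusters_per_voi(a, min_frac) |>
    left_join(total, by = "voi") |>
    mutate(retained_frac = .data$n_retained / .data$n_total)
  voi_names <- unique(a$voi)
  pairs <- if (length(voi_names) >= 2) {
    cmb <- combn(sort(voi_names), 2)
    tibble(voi_a = cmb[1, ], voi_b = cmb[2, ]) |>
      mutate(fraction = purrr::map2_dbl(
        .data$voi_a, .data$voi_b, function(u, v) cocluster_fraction(a, u, v)
      ))
  } else {
    tibble(voi_a = character(0), voi_b = character(0), fraction = numeric(0))
  }
  structure(
    list(
      clusters = cluster_purity(a),
      composition = cluster_composition(a),
      avg_tacs = averaged_cluster_tac(a, tacs),
      vois = vois,
      cocluster = pairs,
      params = clustering$params,
      pathologic = pathologic %||% unique(a$voi)
    ),
    class = "cluster_report"
  )
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf(
    "<cluster_report> %d clusters over %d VOI(s)\n",
    nrow(x$clusters), nrow(x$vois)
  ))
  print(x$clusters)
  invisible(x)
}

#' @describeIn cluster_report Per-cluster tibble (size, majority VOI,
#'   purity).
#' @param x A `cluster_report`.
#' @param ... Unused.
#' @export
tidy.cluster_report <- function(x, ...) x$clusters

#' @describeIn cluster_report One-row summary: cluster count, mean/min
#'   purity, mean clusters per pathologic VOI, retained fraction.
#' @export
glance.cluster_report <- function(x, ...) {
  path <- dplyr::filter(x$vois, .data$voi %in% x$pathologic)
  tibble(
    n_clusters = nrow(x$clusters),
    mean_purity = mean(x$clusters$purity),
    min_purity = min(x$clusters$purity),
    mean_clusters_per_pathologic_voi = mean(path$n_clusters),
    mean_retained_frac = mean(x$vois$retained_frac)
  )
}

#' Build a combined multi-scan lesion network
#'
#' Concatenates lesion TACs from several scans (no inter-scan intensity
#' normalization: Pearson correlation is invariant to positive affine
#' rescaling of any single curve, which is what makes cross-scan networks
#' valid) and runs the pipeline at the combined-network defaults
#' (minimum Pearson 0.95, k = 25, granularity 1.3, minimum component size
#' 100).
#'
#' @param tac_list List of `tac_matrix` objects, one per scan, already
#'   restricted to the VOIs to combine; all must share the frame schedule.
#' @param params A [network_params()]; default [combined_defaults()].
#' @param scan_ids Optional scan identifiers for prefixing VOI labels;
#'   defaults to `scan1`, `scan2`, ...
#' @param min_frac Passed to [cluster_report()].
#' @return List with `tacs`, `clustering` and `report`.
#' @export
build_combined_network <- function(tac_list, params = combined_defaults(),
                                   scan_ids = NULL, min_frac = 0.10) {
  stopifnot(length(tac_list) >= 1)
  scan_ids <- scan_ids %||% sprintf("scan%d", seq_along(tac_list))
  tacs <- bind_tacs(tac_list, scan_ids = scan_ids)
  clustering <- cluster_voxels(tacs, params)
  list(
    tacs = tacs, clustering = clustering,
    report = cluster_report(clustering, tacs, min_frac = min_frac)
  )
}

#' Subset a TAC matrix by VOI
#'
#' @param tacs A `tac_matrix`.
#' @param vois VOI labels to keep.
#' @return A `tac_matrix`.
#' @export
filter_tacs <- function(tacs, vois) {
  keep <- tacs$voxels$voi %in% vois
  if (!any(keep)) abort("No voxels left after filtering.")
  new_tac_matrix(tacs$values[keep, , drop = FALSE], tacs$midpoints_min,
                 tacs$voxels[keep, , drop = FALSE], tacs$schedule)
}

#' Evaluate a grid of network parameters
#'
#' Exhaustively runs the pipeline over a parameter grid and tabulates, for
#' each setting, the fraction of voxels retained in the network, the
#' number of clusters and the mean cluster purity.  No automatic selection
#' is performed: the table supports the operator's manual trade-off
#' between separation and node coverage.
#'
#' @param tacs A `tac_matrix`.
#' @param grid Data frame with columns `r_min`, `k`, `granularity`,
#'   `min_component_size` (e.g. from [expand.grid()]).
#' @return The grid with `retained_frac`, `n_clusters` and `mean_purity`
#'   columns appended.
#' @export
tune_params <- function(tacs, grid) {
  stopifnot(all(c("r_min", "k", "granularity", "min_component_size")
                %in% names(grid)))
  res <- purrr::pmap_dfr(grid, function(r_min, k, granularity,
                                        min_component_size, ...) {
    cl <- cluster_voxels(tacs, network_params(r_min, k, granularity,
                                              min_component_size))
    pur <- cluster_purity(cl)
    tibble(
      retained_frac = nrow(cl$assignment) / nrow(tacs$voxels),
      n_clusters = nrow(pur),
      mean_purity = mean(pur$purity)
    )
  })
  dplyr::bind_cols(as_tibble(grid), res)
}
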