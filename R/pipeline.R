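#' Run the individual-scan pipeline end to end
#'
#' Orchestrates one scan: obtain the image (generate a phantom or read a
#' NIfTI + sidecar pair), convert to SUV, place the digital biopsies,
#' optionally gate pathologic VOIs on tumor-to-background positivity,
#' mask the labels, build and cluster the voxel network at the
#' individual-scan defaults, unmask, and assemble a [cluster_report()].
#' When `out_dir` is given, the graph (edge list + GraphML), the cluster
#' assignment, the report and a provenance log (parameters, seeds,
#' package version) are written there; the run is deterministic given the
#' config.
#'
#' @param config A list with elements:
#'   * `phantom`: a [phantom_spec()], or `nifti`/`sidecar` paths instead;
#'   * `biopsies`: manifest tibble (`label`, `cx`, `cy`, `cz`); defaults
#'     to the phantom's organ centres;
#'   * `params`: a [network_params()]; default [individual_defaults()];
#'   * `pathologic`: labels of lesion VOIs (for reporting and TBR gating);
#'   * `tbr_gate`: gate pathologic VOIs at TBR >= 1.5 (needs a `blood`
#'     VOI); default `FALSE`;
#'   * `blood_label`: name of the blood-pool VOI (default `"blood"`);
#'   * `mask`: mask labels before clustering (default `TRUE`);
#'   * `mask_seed`: seed for alias assignment (default 1);
#'   * `min_frac`: cluster-membership fraction for per-VOI counts.
#' @param out_dir Optional output directory for artifacts.
#' @return List with `tacs`, `clustering`, `report`, `tbr` (when gated)
#'   and `provenance`.
#' @export
run_individual <- function(config, out_dir = NULL) {
  config <- validate_run_config(config)
  img <- load_scan(config)
  biopsies <- place_biopsies(img, config$biopsies)
  tbr <- NULL
  if (isTRUE(config$tbr_gate)) {
    blood <- biopsies[[config$blood_label]]
    tbr <- purrr::map_dfr(biopsies[config$pathologic], function(b) {
      tbr_positive(b, blood, img)
    })
    drop <- tbr$label[!tbr$positive]
    if (length(drop) > 0) {
      inform(paste("TBR-negative VOI(s) excluded:", paste(drop, collapse = ", ")))
      biopsies <- biopsies[setdiff(names(biopsies), drop)]
      config$pathologic <- setdiff(config$pathologic, drop)
    }
  }
  mask <- NULL
  if (isTRUE(config$mask)) {
    m <- mask_labels(biopsies, seed = config$mask_seed)
    biopsies <- m$biopsies
    mask <- m$table
  }
  tacs <- extract_tacs(img, biopsies)
  clustering <- cluster_voxels(tacs, config$params)
  if (!is.null(mask)) {
    clustering <- unmask(clustering, mask)
    tacs$voxels <- unmask(tacs$voxels, mask)
  }
  report <- cluster_report(clustering, tacs, min_frac = config$min_frac,
                           pathologic = config$pathologic)
  prov <- list(
    package_version = as.character(utils::packageVersion("kinclust")),
    params = unclass(config$params),
    mask = isTRUE(config$mask), mask_seed = config$mask_seed,
    tbr_gate = isTRUE(config$tbr_gate),
    phantom_seed = if (!is.null(config$phantom)) config$phantom$seed else NULL,
    n_nodes = nrow(clustering$assignment),
    n_edges_params = clustering$params,
    n_clusters = nrow(report$clusters)
  )
  out <- list(tacs = tacs, clustering = clustering, report = report,
              tbr = tbr, provenance = prov)
  if (!is.null(out_dir)) write_run_artifacts(out, tacs, config, out_dir)
  out
}

#' Run the combined multi-scan pipeline
#'
#' Loads each scan config, extracts only the pathologic VOIs' TACs and
#' builds the cross-scan lesion network at the combined-network defaults
#' (see [build_combined_network()]).
#'
#' @param configs List of configs as in [run_individual()].
#' @param params A [network_params()]; default [combined_defaults()].
#' @param out_dir Optional output directory.
#' @return As [build_combined_network()], plus `provenance`.
#' @export
run_combined <- function(configs, params = combined_defaults(),
                         out_dir = NULL) {
  configs <- purrr::map(configs, validate_run_config)
  tac_list <- purrr::map(configs, function(cfg) {
    img <- load_scan(cfg)
    biopsies <- place_biopsies(img, cfg$biopsies)
    filter_tacs(extract_tacs(img, biopsies), cfg$pathologic)
  })
  res <- build_combined_network(tac_list, params = params)
  res$provenance <- list(
    package_version = as.character(utils::packageVersion("kinclust")),
    params = unclass(params),
    n_scans = length(configs),
    phantom_seeds = purrr::map(configs, function(cfg) {
      if (!is.null(cfg$phantom)) cfg$phantom$seed else NULL
    }),
    n_nodes = nrow(res$clustering$assignment),
    n_clusters = nrow(res$report$clusters)
  )
  if (!is.null(out_dir)) {
    write_run_artifacts(res, res$tacs, list(params = params), out_dir)
  }
  res
}

validate_run_config <- function(config) {
  stopifnot(is.list(config))
  if (is.null(config$phantom) &&
      (is.null(config$nifti) || is.null(config$sidecar))) {
    abort("Config needs either `phantom` or `nifti` + `sidecar` paths.")
  }
  if (!is.null(config$nifti) && !file.exists(config$nifti)) {
    abort(sprintf("No such file: %s", config$nifti))
  }
  defaults <- list(
    params = individual_defaults(), mask = TRUE, mask_seed = 1L,
    tbr_gate = FALSE, blood_label = "blood", min_frac = 0.10
  )
  config <- modifyList(defaults, config)
  if (is.null(config$biopsies)) {
    if (is.null(config$phantom)) {
      abort("A biopsy manifest is required when reading scans from files.")
    }
    config$biopsies <- generate_phantom(config$phantom)$centers
  }
  if (is.null(config$pathologic)) {
    config$pathologic <- setdiff(
      config$biopsies$label,
      c("kidney", "kidney_left", "kidney_right", "liver", "blood",
        "muscle", "fat")
    )
  }
  if (isTRUE(config$tbr_gate) &&
      !config$blood_label %in% config$biopsies$label) {
    abort("TBR gating needs a blood-pool VOI in the biopsy manifest.")
  }
  config
}

load_scan <- function(config) {
  img <- if (!is.null(config$phantom)) {
    generate_phantom(config$phantom)$image
  } else {
    read_dynamic(config$nifti, config$sidecar)
  }
  if (img$units != "SUV") img <- to_suv(img)
  img
}

write_run_artifacts <- function(res, tacs, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  vc <- pearson_matrix(tacs)
  g <- threshold_graph(vc, res$clustering$params$r_min %||% 0.7)
  g <- knn_reduce(g, res$clustering$params$k %||% 9)
  g <- filter_components(g, res$clustering$params$min_component_size %||% 10)
  write_edge_list(g, file.path(out_dir, "edges.tsv"))
  write_graphml(g, file.path(out_dir, "graph.graphml"))
  utils::write.csv(res$clustering$assignment,
                   file.path(out_dir, "assignment.csv"), row.names = FALSE)
  utils::write.csv(res$report$clusters,
                   file.path(out_dir, "clusters.csv"), row.names = FALSE)
  utils::write.csv(res$report$avg_tacs,
                   file.path(out_dir, "cluster_tacs.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(
      vois = res$report$vois, cocluster = res$report$cocluster,
      clusters = res$report$clusters
    ),
    file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  jsonlite::write_json(res$provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' Export a TAC matrix as CSV
#'
#' One row per voxel: `voi`, `voxel_id`, then one column per frame
#' midpoint (minutes, three decimals).
#'
#' @param tacs A `tac_matrix`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_tacs_csv <- function(tacs, path) {
  stopifnot(inherits(tacs, "tac_matrix"))
  m <- as.data.frame(tacs$values)
  names(m) <- sprintf("%.3f", tacs$midpoints_min)
  out <- cbind(tacs$voxels[, c("voi", "voxel_id")], m)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
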