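# Shared fixtures: tiny images and graphs built in code at test time.

# A small dynamic image with the given per-frame fill values.
make_test_image <- function(frame_values, dim3 = c(12, 12, 5),
                            spacing = c(1, 1, 4),
                            dose = 140, weight = 70, units = "SUV") {
  n_frames <- length(frame_values)
  sched <- frame_schedule(rep(60, n_frames))
  vals <- array(rep(frame_values, each = prod(dim3)),
                dim = c(dim3, n_frames))
  dynamic_image(vals, spacing, sched,
                injected_dose_MBq = dose, body_weight_kg = weight,
                units = units)
}

# A correlation_graph built directly from an edge list (1-based node ids).
make_test_graph <- function(edges, n_nodes = max(edges$from, edges$to),
                            voi = rep("A", n_nodes)) {
  nodes <- tibble::tibble(
    node = seq_len(n_nodes), voi = voi,
    voxel_id = seq_len(n_nodes),
    x = seq_len(n_nodes), y = 1L, z = 1L
  )
  kinclust:::new_correlation_graph(
    nodes, tibble::tibble(from = as.integer(edges$from),
                          to = as.integer(edges$to),
                          weight = edges$weight),
    tibble::tibble(), list()
  )
}

# Two k-cliques joined by a single bridge edge.
two_clique_graph <- function(k = 5, bridge_weight = 0.71,
                             clique_weight = 0.9) {
  cl <- function(ids) {
    cmb <- utils::combn(ids, 2)
    tibble::tibble(from = cmb[1, ], to = cmb[2, ], weight = clique_weight)
  }
  edges <- dplyr::bind_rows(
    cl(1:k), cl((k + 1):(2 * k)),
    tibble::tibble(from = k, to = k + 1L, weight = bridge_weight)
  )
  make_test_graph(edges, n_nodes = 2 * k,
                  voi = rep(c("A", "B"), each = k))
}

# Random weighted graph on n nodes (edge prob p, weights in [w_lo, w_hi]).
random_test_graph <- function(n, p = 0.4, seed = 1, w_lo = 0.5, w_hi = 1) {
  withr::with_seed(seed, {
    cmb <- utils::combn(n, 2)
    keep <- stats::runif(ncol(cmb)) < p
    edges <- tibble::tibble(
      from = cmb[1, keep], to = cmb[2, keep],
      weight = stats::runif(sum(keep), w_lo, w_hi)
    )
  })
  make_test_graph(edges, n_nodes = n)
}

# Canonical form of a partition: list of sorted member sets, sorted.
partition_sets <- function(ids, cluster) {
  s <- split(ids, cluster)
  s <- lapply(s, sort)
  firsts <- vapply(s, function(x) as.character(x[1]), character(1))
  unname(s[order(firsts)])
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))
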