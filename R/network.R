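#' Voxelwise Pearson correlation matrix
#'
#' Correlates every pair of voxel time-activity curves over frames.
#' Voxels with zero variance across frames (flat curves) cannot be
#' correlated; they are flagged, excluded from the matrix and reported as
#' dropped rather than propagating `NaN`s.
#'
#' @param tacs A `tac_matrix` with at least two frames.
#' @return A `voxel_cor` object: `r` (symmetric correlation matrix over
#'   retained voxels), `nodes` (tibble `node`, `voi`, `voxel_id`, `x`,
#'   `y`, `z`) and `dropped` (tibble of excluded voxels with a reason).
#' @export
pearson_matrix <- function(tacs) {
  stopifnot(inherits(tacs, "tac_matrix"))
  if (ncol(tacs$values) < 2) abort("Need at least two frames to correlate.")
  sds <- apply(tacs$values, 1, sd)
  keep <- sds > 0
  if (!all(keep)) {
    inform(sprintf("Dropping %d zero-variance voxel(s).", sum(!keep)))
  }
  nodes <- tacs$voxels[keep, , drop = FALSE]
  nodes$node <- seq_len(nrow(nodes))
  nodes <- dplyr::relocate(nodes, "node")
  dropped <- tacs$voxels[!keep, , drop = FALSE]
  if (nrow(dropped) > 0) dropped$reason <- "zero variance" else
    dropped$reason <- character(0)
  # Pearson over frames via a BLAS crossproduct of row-standardized curves
  x <- tacs$values[keep, , drop = FALSE]
  x <- x - rowMeans(x)
  x <- x / sqrt(rowSums(x^2))
  r <- tcrossprod(x)
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 1
  structure(list(r = r, nodes = nodes, dropped = dropped),
            class = "voxel_cor")
}

new_correlation_graph <- function(nodes, edges, dropped, params) {
  structure(
    list(nodes = nodes, edges = edges, dropped = dropped, params = params),
    class = "correlation_graph"
  )
}

#' @export
print.correlation_graph <- function(x, ...) {
  cat(sprintf(
    "<correlation_graph> %d nodes, %d edges (%d dropped)\n",
    nrow(x$nodes), nrow(x$edges), nrow(x$dropped)
  ))
  p <- x$params
  cat("  params:", paste(names(p), unlist(p), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Threshold a correlation matrix into a graph
#'
#' Creates an undirected simple graph with an edge between voxels i and j
#' whenever their Pearson correlation is at least `r_min`, weighted by the
#' correlation.
#'
#' @param vc A [pearson_matrix()] result.
#' @param r_min Minimum Pearson correlation in `[-1, 1]`; default 0.7.
#' @return A `correlation_graph`: `nodes`, `edges` (tibble `from`, `to`,
#'   `weight` with `from < to`), `dropped`, `params`.
#' @export
threshold_graph <- function(vc, r_min = 0.7) {
  stopifnot(inherits(vc, "voxel_cor"))
  if (r_min < -1 || r_min > 1) abort("`r_min` must lie in [-1, 1].")
  n <- nrow(vc$r)
  idx <- which(vc$r >= r_min)
  i <- (idx - 1L) %% n + 1L
  j <- (idx - 1L) %/% n + 1L
  up <- i < j
  edges <- tibble(
    from = i[up], to = j[up], weight = vc$r[idx[up]]
  )
  new_correlation_graph(vc$nodes, edges, vc$dropped, list(r_min = r_min))
}

#' k-nearest-neighbour edge reduction
#'
#' For every node, its incident edges are ranked by weight in descending
#' order (ties break towards the smaller neighbour index) and an edge is
#' retained when it ranks within the top k of either endpoint (union
#' semantics).  The retained edge set is always a subset of the input.
#'
#' @param graph A `correlation_graph`.
#' @param k Number of neighbours to keep per node; default 9.
#' @return A `correlation_graph`.
#' @export
knn_reduce <- function(graph, k = 9) {
  stopifnot(inherits(graph, "correlation_graph"))
  if (k < 1) abort("`k` must be at least 1.")
  e <- graph$edges
  if (nrow(e) > 0) {
    both <- dplyr::bind_rows(
      tibble(node = e$from, nbr = e$to, eid = seq_len(nrow(e)), w = e$weight),
      tibble(node = e$to, nbr = e$from, eid = seq_len(nrow(e)), w = e$weight)
    )
    both <- arrange(both, .data$node, dplyr::desc(.data$w), .data$nbr)
    both <- mutate(group_by(both, .data$node), rank = row_number())
    keep_ids <- sort(unique(both$eid[both$rank <= k]))
    e <- e[keep_ids, , drop = FALSE]
  }
  new_correlation_graph(graph$nodes, e, graph$dropped,
                        modifyList(graph$params, list(k = k)))
}

#' Remove small connected components
#'
#' Components with fewer than `min_size` nodes (including isolated nodes)
#' are removed before clustering; the removed nodes are appended to the
#' graph's dropped list.
#'
#' @param graph A `correlation_graph`.
#' @param min_size Minimum component size; 1 is the identity.
#' @return A `correlation_graph`.
#' @export
filter_components <- function(graph, min_size = 10) {
  stopifnot(inherits(graph, "correlation_graph"))
  if (min_size < 1) abort("`min_size` must be at least 1.")
  if (min_size == 1) {
    return(new_correlation_graph(
      graph$nodes, graph$edges, graph$dropped,
      modifyList(graph$params, list(min_component_size = min_size))
    ))
  }
  g <- igraph_from_graph(graph)
  comp <- igraph::components(g)
  node_ids <- as.integer(igraph::V(g)$name)
  big <- comp$csize[comp$membership] >= min_size
  keep_ids <- node_ids[big]
  nodes <- graph$nodes[graph$nodes$node %in% keep_ids, , drop = FALSE]
  edges <- graph$edges[graph$edges$from %in% keep_ids &
                         graph$edges$to %in% keep_ids, , drop = FALSE]
  removed <- graph$nodes[!graph$nodes$node %in% keep_ids, , drop = FALSE]
  if (nrow(removed) > 0) removed$reason <- "small component"
  dropped <- dplyr::bind_rows(graph$dropped, removed)
  new_correlation_graph(
    nodes, edges, dropped,
    modifyList(graph$params, list(min_component_size = min_size))
  )
}

igraph_from_graph <- function(graph) {
  igraph::graph_from_data_frame(
    graph$edges[, c("from", "to", "weight")],
    directed = FALSE,
    vertices = data.frame(name = graph$nodes$node)
  )
}

#' Export a correlation graph
#'
#' `write_edge_list()` writes a tab-separated `node_a`, `node_b`,
#' `weight` file; `write_graphml()` writes GraphML (with `voi` and
#' `voxel_id` node attributes) for external viewers.
#'
#' @param graph A `correlation_graph`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  stopifnot(inherits(graph, "correlation_graph"))
  utils::write.table(
    graph$edges, path,
    sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = c("node_a", "node_b", "weight")
  )
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_graphml <- function(graph, path) {
  stopifnot(inherits(graph, "correlation_graph"))
  g <- igraph_from_graph(graph)
  ord <- match(as.integer(igraph::V(g)$name), graph$nodes$node)
  igraph::V(g)$voi <- graph$nodes$voi[ord]
  igraph::V(g)$voxel_id <- graph$nodes$voxel_id[ord]
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read an edge-list graph
#'
#' @param path A tab-separated `node_a`, `node_b`, `weight` file written
#'   by [write_edge_list()].
#' @param nodes Optional node tibble (`node`, `voi`, ...); reconstructed
#'   from the edge list when absent.
#' @return A `correlation_graph`.
#' @export
read_edge_list <- function(path, nodes = NULL) {
  e <- utils::read.table(path, header = TRUE, sep = "\t")
  edges <- tibble(from = as.integer(e$node_a), to = as.integer(e$node_b),
                  weight = e$weight)
  if (is.null(nodes)) {
    ids <- sort(unique(c(edges$from, edges$to)))
    nodes <- tibble(node = ids, voi = NA_character_, voxel_id = NA_integer_)
  }
  new_correlation_graph(nodes, edges,
                        tibble(voi = character(0), reason = character(0)),
                        list())
}
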