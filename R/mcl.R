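#' Markov clustering of a voxel correlation graph
#'
#' Runs the Markov cluster algorithm (MCL) on the weighted adjacency
#' matrix with unit self-loops.  The column-stochastic transition matrix
#' is alternately expanded (matrix squared) and inflated (entrywise power
#' `granularity`, then column renormalized), with entries below
#' `prune_eps` zeroed to keep the matrix sparse, until the maximum
#' absolute change drops below `tol` or `max_iter` is reached.  Clusters
#' are read off the limit matrix via its attractors: attractor rows
#' sharing support form one cluster, and every node is assigned to the
#' attractor cluster holding the largest share of its column mass (ties to
#' the lowest cluster id).  The `granularity` exponent controls cluster
#' granularity: larger values fragment the graph into more, smaller
#' clusters.
#'
#' @param graph A `correlation_graph` with at least one node.
#' @param granularity Inflation exponent, > 1; 1.2 is the default for
#'   single-scan networks and 1.3 for combined networks.
#' @param max_iter Iteration cap; a convergence warning flag is set if it
#'   is reached.
#' @param prune_eps Entries below this value are zeroed each iteration
#'   (1e-4, the canonical MCL pruning cutoff).
#' @param tol Convergence tolerance on the maximum entry change.  Exact
#'   period-two limit cycles (a known MCL artifact on symmetric flows) are
#'   also treated as converged, interpreting the current matrix.
#' @param use_weights Use Pearson weights (default) or binarized edges.
#' @return An `mcl_clustering`: `assignment` (the graph's node tibble plus
#'   a `cluster` column), `dropped`, `converged`, `iterations`, `params`.
#' @export
mcl <- function(graph, granularity = 1.2, max_iter = 200,
                prune_eps = 1e-4, tol = 1e-6, use_weights = TRUE) {
  stopifnot(inherits(graph, "correlation_graph"))
  if (granularity <= 1) abort("`granularity` must exceed 1.")
  n <- nrow(graph$nodes)
  if (n < 1) abort("The graph has no nodes.")
  idx <- match(c(graph$edges$from, graph$edges$to), graph$nodes$node)
  i <- idx[seq_len(nrow(graph$edges))]
  j <- idx[nrow(graph$edges) + seq_len(nrow(graph$edges))]
  w <- if (use_weights) graph$edges$weight else rep(1, nrow(graph$edges))
  A <- Matrix::sparseMatrix(
    i = c(i, j, seq_len(n)), j = c(j, i, seq_len(n)),
    x = c(w, w, rep(1, n)), dims = c(n, n)
  )
  # MCL flow never crosses connected components (the transition matrix is
  # block diagonal), so iterate per component; small blocks use dense BLAS.
  membership <- igraph::components(igraph::graph_from_adjacency_matrix(
    A, mode = "undirected", weighted = TRUE, diag = FALSE
  ))$membership
  cluster <- integer(n)
  converged <- TRUE
  iter <- 0
  offset <- 0
  for (cm in unique(membership)) {
    sel <- which(membership == cm)
    res <- mcl_iterate(A[sel, sel, drop = FALSE], granularity, max_iter,
                       prune_eps, tol)
    converged <- converged && res$converged
    iter <- max(iter, res$iterations)
    cluster[sel] <- res$cluster + offset
    offset <- offset + max(res$cluster)
  }
  if (!converged) {
    warn(sprintf("MCL did not converge within %d iterations.", max_iter))
  }
  # canonical labels: clusters numbered by their smallest member
  first_member <- tapply(seq_len(n), cluster, min)
  cluster <- match(cluster, as.integer(names(sort(first_member))))
  assignment <- graph$nodes
  assignment$cluster <- cluster
  structure(
    list(
      assignment = assignment, dropped = graph$dropped,
      converged = converged, iterations = iter,
      params = modifyList(graph$params, list(
        granularity = granularity, prune_eps = prune_eps,
        max_iter = max_iter, use_weights = use_weights
      ))
    ),
    class = "mcl_clustering"
  )
}

# Expansion/inflation iteration on one connected component.  Blocks of up
# to 2000 nodes run as dense base matrices (BLAS-backed squaring); larger
# ones stay sparse; pruning and normalization semantics are identical.
# Pruning severs weak inter-cluster bridges early, after which the
# transition matrix is exactly block diagonal, so every few iterations the
# support graph is re-checked and disconnected sub-blocks continue
# independently — a pure speed device with unchanged results.
mcl_iterate <- function(A, granularity, max_iter, prune_eps, tol,
                        resplit_every = 3) {
  n0 <- ncol(A)
  cluster <- integer(n0)
  offset <- 0
  iterations <- 0
  converged <- TRUE
  # worklist of (index set, current matrix, iteration count)
  work <- list(list(idx = seq_len(n0), M = mcl_normalize(A), iter = 0))
  while (length(work) > 0) {
    blk <- work[[1]]
    work <- work[-1]
    M <- blk$M
    dense <- is.matrix(M)
    if (!dense && ncol(M) <= 2000) {
      M <- as.matrix(M)
      dense <- TRUE
    }
    iter <- blk$iter
    blk_done <- FALSE
    M_prev2 <- NULL
    while (iter < max_iter) {
      if (dense) {
        # compiled kernel iterates and reports the first support split
        res <- .mcl_dense_steps(M, granularity, max_iter - iter,
                                prune_eps, tol)
        iter <- iter + res$done
        M <- res$M
        if (res$converged) {
          blk_done <- TRUE
          break
        }
        if (res$split) {
          parts <- res$membership
          for (p in seq_len(max(parts))) {
            sel <- which(parts == p)
            work[[length(work) + 1]] <- list(
              idx = blk$idx[sel],
              M = M[sel, sel, drop = FALSE],
              iter = iter
            )
          }
          blk_done <- NA
          break
        }
        next  # max_iter reached
      } else {
        iter <- iter + 1
        M2 <- M %*% M                               # expansion
        M2 <- as(M2, "CsparseMatrix")
        M2@x <- M2@x^granularity                    # inflation
        M2@x[M2@x < prune_eps] <- 0
        M2 <- Matrix::drop0(M2)
        M2 <- mcl_normalize(M2)
        delta <- max(abs(M2 - M))
        # period-two limit cycles (flip-flopping columns on symmetric
        # flow) count as converged; the current matrix is interpreted
        delta2 <- if (!is.null(M_prev2)) max(abs(M2 - M_prev2)) else Inf
        M_prev2 <- M
        M <- M2
        if (delta < tol || delta2 < tol) {
          blk_done <- TRUE
          break
        }
      }
      if (!dense && iter %% resplit_every == 0 && ncol(M) > 50) {
        parts <- mcl_support_components(M)
        if (max(parts) > 1) {
          for (p in seq_len(max(parts))) {
            sel <- which(parts == p)
            work[[length(work) + 1]] <- list(
              idx = blk$idx[sel],
              M = M[sel, sel, drop = FALSE],
              iter = iter
            )
          }
          blk_done <- NA
          break
        }
      }
    }
    if (is.na(blk_done)) next
    iterations <- max(iterations, iter)
    converged <- converged && blk_done
    Msp <- if (dense) Matrix::Matrix(M, sparse = TRUE) else M
    cl <- interpret_mcl(Msp)
    cluster[blk$idx] <- cl + offset
    offset <- offset + max(cl)
  }
  list(cluster = cluster, converged = converged, iterations = iterations)
}

mcl_normalize <- function(m) {
  if (is.matrix(m)) m / rep(colSums(m), each = nrow(m))
  else m %*% Matrix::Diagonal(x = 1 / Matrix::colSums(m))
}

# weakly connected components of the support of M (every node has at
# least its own column mass, so every index appears in the edge list)
mcl_support_components <- function(M) {
  n <- ncol(M)
  if (is.matrix(M)) {
    idx <- which(M != 0)
    i <- (idx - 1L) %% n + 1L
    j <- (idx - 1L) %/% n + 1L
  } else {
    S <- as(M, "TsparseMatrix")
    i <- S@i + 1L
    j <- S@j + 1L
  }
  g <- igraph::graph_from_edgelist(cbind(i, j), directed = TRUE)
  g <- igraph::add_vertices(g, n - igraph::vcount(g))
  igraph::components(g, mode = "weak")$membership
}

# Attractor-based interpretation of the (near-)idempotent limit matrix.
interpret_mcl <- function(M) {
  n <- ncol(M)
  att <- which(Matrix::diag(M) > 0)
  if (length(att) == 0) att <- seq_len(n)  # pathological; treat all as attractors
  S <- M[att, , drop = FALSE]
  # attractors sharing any column belong to one attractor system
  P <- S != 0
  overlap <- Matrix::tcrossprod(P * 1)
  comp <- igraph::components(igraph::graph_from_adjacency_matrix(
    overlap > 0, mode = "undirected", diag = FALSE
  ))
  att_cluster <- comp$membership
  k <- comp$no
  # mass of every node's column within each attractor cluster
  agg <- Matrix::sparseMatrix(
    i = att_cluster, j = seq_along(att), x = 1,
    dims = c(k, length(att))
  )
  mass <- as.matrix(agg %*% S)               # k x n
  cluster <- max.col(t(mass), ties.method = "first")
  unassigned <- Matrix::colSums(S)[seq_len(n)] == 0
  if (any(unassigned)) {
    # non-converged columns without attractor mass: follow the strongest
    # entry to an assigned node
    target <- apply(as.matrix(M[, unassigned, drop = FALSE]), 2, which.max)
    cluster[unassigned] <- cluster[target]
  }
  # canonical labels: clusters numbered by their smallest member
  first_member <- tapply(seq_len(n), cluster, min)
  match(cluster, as.integer(names(sort(first_member))))
}

#' @export
print.mcl_clustering <- function(x, ...) {
  cat(sprintf(
    "<mcl_clustering> %d nodes in %d clusters (%s, %d iterations)\n",
    nrow(x$assignment), dplyr::n_distinct(x$assignment$cluster),
    if (x$converged) "converged" else "NOT converged", x$iterations
  ))
  invisible(x)
}

#' @describeIn mcl Tidy the node-level assignment (one row per voxel).
#' @param x An `mcl_clustering`.
#' @param ... Unused.
#' @export
tidy.mcl_clustering <- function(x, ...) x$assignment

#' @describeIn mcl One-row model summary (node, cluster and dropped
#'   counts, convergence).
#' @export
glance.mcl_clustering <- function(x, ...) {
  pur <- cluster_purity(x)
  tibble(
    n_nodes = nrow(x$assignment),
    n_clusters = dplyr::n_distinct(x$assignment$cluster),
    n_dropped = nrow(x$dropped),
    mean_purity = mean(pur$purity),
    min_purity = min(pur$purity),
    converged = x$converged,
    iterations = x$iterations
  )
}

#' Run the full network-clustering pipeline on a TAC matrix
#'
#' Convenience wrapper chaining [pearson_matrix()], [threshold_graph()],
#' [knn_reduce()], [filter_components()] and [mcl()] with one parameter
#' set.
#'
#' @param tacs A `tac_matrix`.
#' @param params A [network_params()] list; default
#'   [individual_defaults()].
#' @return An `mcl_clustering`.
#' @export
cluster_voxels <- function(tacs, params = individual_defaults()) {
  vc <- pearson_matrix(tacs)
  g <- threshold_graph(vc, params$r_min)
  g <- knn_reduce(g, params$k)
  g <- filter_components(g, params$min_component_size)
  mcl(g, granularity = params$granularity)
}

#' Network construction parameter sets
#'
#' `individual_defaults()` are the single-scan settings (minimum Pearson
#' 0.7, k = 9 nearest neighbours, granularity 1.2, minimum component size
#' 10); `combined_defaults()` the multi-scan settings (0.95, 25, 1.3,
#' 100).
#'
#' @param r_min Minimum Pearson correlation.
#' @param k Nearest-neighbour count for edge reduction.
#' @param granularity MCL inflation exponent.
#' @param min_component_size Minimum connected-component size.
#' @return A named list of class `network_params`.
#' @export
network_params <- function(r_min, k, granularity, min_component_size) {
  if (r_min < -1 || r_min > 1) abort("`r_min` must lie in [-1, 1].")
  if (k < 1) abort("`k` must be at least 1.")
  if (granularity <= 1) abort("`granularity` must exceed 1.")
  if (min_component_size < 1) abort("`min_component_size` must be >= 1.")
  structure(
    list(r_min = r_min, k = as.integer(k), granularity = granularity,
         min_component_size = as.integer(min_component_size)),
    class = "network_params"
  )
}

#' @rdname network_params
#' @export
individual_defaults <- function() network_params(0.7, 9, 1.2, 10)

#' @rdname network_params
#' @export
combined_defaults <- function() network_params(0.95, 25, 1.3, 100)
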