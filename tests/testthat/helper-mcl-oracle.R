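# Independent dense reference MCL: straightforward matrix iteration with
# no pruning and no block decomposition, interpreted via a hand-rolled
# breadth-first search on the limit support.  Used as the oracle for the
# production implementation on small graphs.

reference_mcl <- function(graph, inflation, max_iter = 2000, tol = 1e-9) {
  n <- nrow(graph$nodes)
  A <- matrix(0, n, n)
  idx_from <- match(graph$edges$from, graph$nodes$node)
  idx_to <- match(graph$edges$to, graph$nodes$node)
  for (e in seq_along(idx_from)) {
    A[idx_from[e], idx_to[e]] <- graph$edges$weight[e]
    A[idx_to[e], idx_from[e]] <- graph$edges$weight[e]
  }
  diag(A) <- 1
  M <- A %*% diag(1 / colSums(A), n)
  M_prev2 <- NULL
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M
    M2 <- M2^inflation
    M2 <- M2 %*% diag(1 / colSums(M2), n)
    d1 <- max(abs(M2 - M))
    d2 <- if (is.null(M_prev2)) Inf else max(abs(M2 - M_prev2))
    M_prev2 <- M
    M <- M2
    if (d1 < tol || d2 < tol) break
  }
  # clusters = connected components of the (symmetrized) limit support
  S <- (M > 1e-7) | t(M > 1e-7)
  cluster <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(cluster[s])) next
    cid <- cid + 1L
    queue <- s
    cluster[s] <- cid
    while (length(queue) > 0) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- which(S[v, ] & is.na(cluster))
      cluster[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  cluster
}
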