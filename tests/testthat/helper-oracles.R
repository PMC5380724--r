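# Independent brute-force oracles for the graph metrics, used to
# cross-check the package implementations.

oracle_graph_from_matrix <- function(A) {
  structure(list(adjacency = A, threshold_fraction = NA_real_,
                 threshold_value = NA_real_), class = "meg_graph")
}

oracle_random_graph <- function(n, p, seed) {
  set.seed(seed)
  A <- matrix(runif(n * n) < p, n, n)
  A[lower.tri(A, diag = TRUE)] <- FALSE
  A <- A | t(A)
  oracle_graph_from_matrix(A)
}

# per-node edge count by explicit enumeration
oracle_degree <- function(g) {
  vapply(seq_len(nrow(g$adjacency)),
         function(i) sum(g$adjacency[i, ]), integer(1))
}

# dense eigendecomposition on the largest component (BFS), scaled to max 1
oracle_evc <- function(g) {
  A <- g$adjacency * 1
  n <- nrow(A)
  comp <- rep(NA_integer_, n); cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L; queue <- s; comp[s] <- cid
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      nb <- which(A[cur, ] > 0 & is.na(comp))
      comp[nb] <- cid; queue <- c(queue, nb)
    }
  }
  sizes <- tabulate(comp)
  big <- which(sizes == max(sizes))
  if (length(big) > 1)
    big <- big[which.min(vapply(big, function(cc) min(which(comp == cc)),
                                integer(1)))]
  nodes <- which(comp == big)
  out <- numeric(n)
  if (length(nodes) == 1) { out[nodes] <- 1; return(out) }
  e <- eigen(A[nodes, nodes], symmetric = TRUE)
  v <- abs(e$vectors[, 1])
  out[nodes] <- v / max(v)
  out
}

# exhaustive enumeration of every shortest path between every pair
oracle_betweenness <- function(g) {
  A <- g$adjacency
  n <- nrow(A)
  D <- matrix(Inf, n, n); diag(D) <- 0
  D[A] <- 1
  for (k in 1:n) for (i in 1:n) for (j in 1:n)
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  all_paths <- function(s, t) {
    if (s == t) return(list(s))
    res <- list()
    for (m in which(A[, t] & D[s, ] == D[s, t] - 1))
      for (p in all_paths(s, m)) res <- c(res, list(c(p, t)))
    res
  }
  bt <- numeric(n)
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(D[s, t])) next
    paths <- all_paths(s, t)
    inner <- unlist(lapply(paths, function(p) p[-c(1, length(p))]))
    if (length(inner)) {
      tab <- table(inner)
      idx <- as.integer(names(tab))
      bt[idx] <- bt[idx] + tab / length(paths)
    }
  }
  bt
}
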