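# Independent brute-force oracles used across the suite.

# max ECDF gap between two samples (two-sample K-S statistic)
ks_D_brute <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  F1 <- vapply(pts, function(p) mean(x <= p), numeric(1))
  F2 <- vapply(pts, function(p) mean(y <= p), numeric(1))
  max(abs(F1 - F2))
}

# all-pairs shortest paths by repeated BFS on an edge list (character ids)
bfs_distances_brute <- function(nodes, edges, source) {
  adj <- lapply(stats::setNames(nm = nodes), function(v)
    c(edges$to[edges$from == v], edges$from[edges$to == v]))
  d <- stats::setNames(rep(Inf, length(nodes)), nodes)
  d[source] <- 0
  frontier <- source
  while (length(frontier)) {
    nxt <- character(0)
    for (v in frontier) for (w in adj[[v]]) if (!is.finite(d[w])) {
      d[w] <- d[v] + 1
      nxt <- c(nxt, w)
    }
    frontier <- unique(nxt)
  }
  d
}

# ASPL over connected pairs of the largest component, from an adjacency matrix
aspl_brute <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj > 0] <- 1
  diag(d) <- 0
  for (k in 1:n) for (i in 1:n) for (j in 1:n)
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  # largest component = rows with the most finite entries
  comp_sizes <- rowSums(is.finite(d))
  keep <- which(comp_sizes == max(comp_sizes))
  dd <- d[keep, keep]
  vals <- dd[upper.tri(dd)]
  mean(vals[is.finite(vals)])
}

# average local clustering with degree-<2 nodes contributing 0
clustering_brute <- function(adj) {
  n <- nrow(adj)
  local <- numeric(n)
  for (v in 1:n) {
    nb <- which(adj[v, ] > 0)
    k <- length(nb)
    if (k < 2) next
    links <- sum(adj[nb, nb]) / 2
    local[v] <- links / choose(k, 2)
  }
  mean(local)
}

# spec toy: source miRNA A; A targets t1,t2; B targets t2,t3; C targets t3,t4
toy_topology <- function() {
  bipartite_topology(
    c("A", "B", "C"), c("t1", "t2", "t3", "t4"),
    data.frame(mirna = c("A", "A", "B", "B", "C", "C"),
               mrna = c("t1", "t2", "t2", "t3", "t3", "t4")))
}

ref_params <- function(...) kinetic_params(...)

unpack_state_for_test <- function(sys, x) ceRNAflow:::unpack_state(sys, x)

# random valid parameter set for property tests (qp guard not applied here)
random_params <- function() {
  kinetic_params(
    g_R = stats::runif(1, 0.2, 2), g_T = stats::runif(1, 0.2, 2),
    b = stats::runif(1, 0.1, 2), u_C = stats::runif(1, 0, 1),
    d_C = stats::runif(1, 0.2, 2), d_R = stats::runif(1, 0.1, 1),
    d_T = stats::runif(1, 0.1, 1), alpha = stats::runif(1, 0.05, 1))
}
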