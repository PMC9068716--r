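# Independent brute-force oracles for the graph measures, written directly
# from the defining sums with no shared code with the package internals.

# Floyd-Warshall all-pairs shortest paths
oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj > 0] <- 1
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

oracle_global_efficiency <- function(adj) {
  n <- nrow(adj)
  d <- oracle_distances(adj)
  acc <- 0
  for (i in seq_len(n))
    for (j in seq_len(n))
      if (i != j && is.finite(d[i, j])) acc <- acc + 1 / d[i, j]
  acc / (n * (n - 1))
}

oracle_nodal_efficiency <- function(adj) {
  n <- nrow(adj)
  d <- oracle_distances(adj)
  sapply(seq_len(n), function(i) {
    v <- 0
    for (j in seq_len(n))
      if (j != i && is.finite(d[i, j])) v <- v + 1 / d[i, j]
    v / (n - 1)
  })
}

oracle_local_efficiency <- function(adj) {
  n <- nrow(adj)
  vals <- sapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] > 0)
    if (length(nb) < 2) return(0)
    oracle_global_efficiency(adj[nb, nb, drop = FALSE])
  })
  mean(vals)
}

# weighted (directed) modularity of a fixed partition, straight from the sum
oracle_modularity <- function(w, membership) {
  W <- sum(w)
  s_out <- rowSums(w)
  s_in <- colSums(w)
  q <- 0
  n <- nrow(w)
  for (i in seq_len(n))
    for (j in seq_len(n))
      if (membership[i] == membership[j])
        q <- q + w[i, j] - s_out[i] * s_in[j] / W
  q / W
}

# discrete-type assortativity with node degree as the type
oracle_assortativity <- function(adj) {
  deg <- rowSums(adj)
  ends <- NULL
  n <- nrow(adj)
  for (i in seq_len(n))
    for (j in seq_len(n))
      if (adj[i, j] > 0) ends <- rbind(ends, c(deg[i], deg[j]))
  types <- sort(unique(as.vector(ends)))
  nt <- length(types)
  e <- matrix(0, nt, nt)
  for (r in seq_len(nrow(ends))) {
    x <- match(ends[r, 1], types)
    y <- match(ends[r, 2], types)
    e[x, y] <- e[x, y] + 1
  }
  e <- e / sum(e)
  a <- rowSums(e)
  b <- colSums(e)
  (sum(diag(e)) - sum(a * b)) / (1 - sum(a * b))
}

oracle_rich_club_phi <- function(adj, k) {
  deg <- rowSums(adj)
  rich <- which(deg > k)
  if (length(rich) < 2) return(NA_real_)
  e <- 0
  for (i in rich)
    for (j in rich)
      if (i < j && adj[i, j] > 0) e <- e + 1
  2 * e / (length(rich) * (length(rich) - 1))
}

# random symmetric binary graph
random_graph <- function(n, p) {
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- rbinom(n * (n - 1) / 2, 1L, p)
  a + t(a)
}

# paired t statistic from the textbook formula
oracle_paired_t <- function(x, y) {
  d <- x - y
  mean(d) / (sd(d) / sqrt(length(d)))
}
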