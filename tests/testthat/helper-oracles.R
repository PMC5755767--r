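`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force graph oracles, deliberately independent of igraph's algorithms:
# Floyd-Warshall distances plus matrix-power geodesic counting (a minimal-length
# walk cannot revisit a vertex, so the d-th power of the adjacency matrix counts
# geodesics exactly).

oracle_geodesics <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  d[a == 1] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

oracle_path_counts <- function(a, d) {
  n <- nrow(a)
  maxd <- max(0, d[is.finite(d)])
  pows <- vector("list", maxd + 1L)
  pows[[1L]] <- diag(n)
  if (maxd >= 1) for (l in seq_len(maxd)) pows[[l + 1L]] <- pows[[l]] %*% a
  np <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (is.finite(d[i, j])) np[i, j] <- pows[[d[i, j] + 1L]][i, j]
  np
}

oracle_betweenness <- function(a) {
  d <- oracle_geodesics(a)
  np <- oracle_path_counts(a, d)
  n <- nrow(a)
  b <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n - 1L)) for (k in (j + 1L):n) {
      if (j == i || k == i || !is.finite(d[j, k])) next
      if (is.finite(d[j, i]) && is.finite(d[i, k]) &&
          d[j, i] + d[i, k] == d[j, k])
        b[i] <- b[i] + np[j, i] * np[i, k] / np[j, k]
    }
  }
  b
}

oracle_diameter <- function(a) {
  d <- oracle_geodesics(a)
  off <- d[row(d) != col(d)]
  fin <- off[is.finite(off)]
  if (!length(fin)) 0 else max(fin)
}

oracle_eccentricity <- function(a) {
  d <- oracle_geodesics(a)
  apply(d, 1L, function(r) {
    fin <- r[is.finite(r)]
    max(fin)  # includes the 0 self-distance: isolated node -> 0
  })
}

oracle_modularity <- function(a, labels) {
  m <- sum(a) / 2
  stopifnot(m > 0)
  k <- rowSums(a)
  q <- 0
  for (c in unique(labels)) {
    idx <- which(labels == c)
    e_c <- sum(a[idx, idx]) / 2
    d_c <- sum(k[idx])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}

oracle_entropy_per_node <- function(a) {
  b <- oracle_betweenness(a)
  tot <- sum(b)
  if (tot == 0) return(0)
  p <- b / tot
  p <- p[p > 0]
  -sum(p * log2(p)) / nrow(a)
}

# graph construction helpers -------------------------------------------------

graph_from_adj <- function(a, names = NULL) {
  dimnames(a) <- list(names %||% paste0("v", seq_len(nrow(a))),
                      names %||% paste0("v", seq_len(nrow(a))))
  igraph::graph_from_adjacency_matrix(a, mode = "undirected", diag = FALSE)
}

adj_path <- function(n) {
  a <- matrix(0L, n, n)
  for (i in seq_len(n - 1L)) a[i, i + 1L] <- a[i + 1L, i] <- 1L
  a
}

adj_cycle <- function(n) {
  a <- adj_path(n)
  a[1L, n] <- a[n, 1L] <- 1L
  a
}

adj_star <- function(n) {           # node 1 is the hub
  a <- matrix(0L, n, n)
  a[1L, -1L] <- a[-1L, 1L] <- 1L
  a
}

adj_complete <- function(n) {
  a <- matrix(1L, n, n)
  diag(a) <- 0L
  a
}

adj_random <- function(n, p) {
  a <- matrix(0L, n, n)
  up <- upper.tri(a)
  a[up] <- as.integer(stats::runif(sum(up)) < p)
  a + t(a)
}

# all labelled simple graphs on n nodes, as adjacency matrices
all_graphs <- function(n) {
  npairs <- n * (n - 1L) / 2L
  lapply(seq_len(2L^npairs) - 1L, function(code) {
    bits <- as.integer(intToBits(code))[seq_len(npairs)]
    a <- matrix(0L, n, n)
    a[upper.tri(a)] <- bits
    a + t(a)
  })
}

# all set partitions of seq_len(n), as label vectors
all_partitions <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_partitions(n - 1L)) {
    for (c in seq_len(max(p) + 1L)) out[[length(out) + 1L]] <- c(p, c)
  }
  out
}

# a small named correlation-network matrix from an upper-triangle spec
make_net <- function(n, fill = 0, pairs = list(), names = paste0("g", seq_len(n))) {
  s <- matrix(fill, n, n, dimnames = list(names, names))
  for (p in pairs) s[p[[1L]], p[[2L]]] <- s[p[[2L]], p[[1L]]] <- p[[3L]]
  diag(s) <- 0
  class(s) <- c("correlation_network", class(s))
  s
}
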