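# Brute-force reference implementations, deliberately naive and
# independent of the package's kernels: Floyd-Warshall distances,
# exhaustive triangle counts, recursive shortest-path counting for
# betweenness. Usable up to N ~ 12.

oracle_distances <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[adj == 1] <- 1
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

oracle_clustering <- function(adj) {
  n <- nrow(adj)
  sapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    t <- 0
    for (a in seq_len(k - 1))
      for (b in seq(a + 1, k))
        if (adj[nb[a], nb[b]] == 1) t <- t + 1
    2 * t / (k * (k - 1))
  })
}

oracle_global_efficiency <- function(adj) {
  D <- oracle_distances(adj)
  n <- nrow(adj)
  inv <- ifelse(is.finite(D) & D > 0, 1 / D, 0)
  list(Eglob = sum(inv) / (n * (n - 1)),
       per_node = rowSums(inv) / (n - 1))
}

oracle_local_efficiency <- function(adj) {
  n <- nrow(adj)
  sapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] == 1)
    if (length(nb) < 2) return(0)
    oracle_global_efficiency(adj[nb, nb, drop = FALSE])$Eglob
  })
}

# number of shortest s-t paths, recursively over BFS layers
oracle_path_counts <- function(adj, D, s) {
  n <- nrow(adj)
  sigma <- numeric(n)
  sigma[s] <- 1
  for (d in seq_len(max(D[s, is.finite(D[s, ])]))) {
    for (t in which(D[s, ] == d)) {
      preds <- which(adj[, t] == 1 & D[s, ] == d - 1)
      sigma[t] <- sum(sigma[preds])
    }
  }
  sigma
}

oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  D <- oracle_distances(adj)
  sig <- lapply(seq_len(n), function(s) oracle_path_counts(adj, D, s))
  # sigma_st(i) = sigma_si * sigma_it when i lies on a geodesic
  bc <- numeric(n)
  for (i in seq_len(n)) {
    for (s in seq_len(n - 1)) {
      for (t in seq(s + 1, n)) {
        if (s == i || t == i || !is.finite(D[s, t])) next
        if (is.finite(D[s, i]) && is.finite(D[i, t]) &&
            D[s, i] + D[i, t] == D[s, t])
          bc[i] <- bc[i] + sig[[s]][i] * sig[[i]][t] / sig[[s]][t]
      }
    }
  }
  bc
}

# --- small graph builders -------------------------------------------------

graph_from_edges <- function(n, edges) {
  adj <- matrix(0L, n, n)
  for (e in edges) {
    adj[e[1], e[2]] <- 1L
    adj[e[2], e[1]] <- 1L
  }
  binary_graph(adj)
}

complete_graph <- function(n) binary_graph(matrix(1L, n, n) - diag(n))

star_graph <- function(n_leaves) {
  adj <- matrix(0L, n_leaves + 1, n_leaves + 1)
  adj[1, -1] <- 1L
  adj[-1, 1] <- 1L
  binary_graph(adj)
}

path_graph <- function(n) {
  adj <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) { adj[i, i + 1] <- 1L; adj[i + 1, i] <- 1L }
  binary_graph(adj)
}

ring_lattice <- function(n, k) {
  stopifnot(k %% 2 == 0)
  adj <- matrix(0L, n, n)
  for (i in seq_len(n))
    for (d in seq_len(k / 2)) {
      j <- ((i - 1 + d) %% n) + 1
      adj[i, j] <- 1L
      adj[j, i] <- 1L
    }
  binary_graph(adj)
}

random_graph <- function(n, p = 0.3, seed = NULL, ensure_edge = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  adj <- matrix(0L, n, n)
  ut <- upper.tri(adj)
  adj[ut] <- as.integer(runif(sum(ut)) < p)
  if (ensure_edge && sum(adj) == 0) adj[1, 2] <- 1L
  adj <- adj + t(adj)
  binary_graph(adj)
}
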