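# Independent oracles for centrality checks: all-pairs BFS on the adjacency
# matrix, with shortest-path counts accumulated level by level.  Shares no
# code with the implementation under test (which delegates to igraph).

oracle_dist_sigma <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  S <- matrix(0, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); sig <- rep(0, n)
    dist[s] <- 0; sig[s] <- 1
    frontier <- s
    while (length(frontier)) {
      nxt <- integer()
      for (u in frontier) {
        for (v in which(adj[u, ] > 0)) {
          if (is.infinite(dist[v])) {
            dist[v] <- dist[u] + 1
            nxt <- c(nxt, v)
          }
          if (dist[v] == dist[u] + 1) sig[v] <- sig[v] + sig[u]
        }
      }
      frontier <- unique(nxt)
    }
    D[s, ] <- dist
    S[s, ] <- sig
  }
  list(D = D, S = S)
}

oracle_adjacency <- function(net) {
  nodes <- sort(igraph::V(net)$name)
  n <- length(nodes)
  adj <- matrix(0L, n, n, dimnames = list(nodes, nodes))
  el <- igraph::as_edgelist(net)
  if (nrow(el)) {
    adj[cbind(el[, 1], el[, 2])] <- 1L
    adj[cbind(el[, 2], el[, 1])] <- 1L
  }
  adj
}

oracle_betweenness <- function(net) {
  adj <- oracle_adjacency(net)
  n <- nrow(adj)
  if (n < 3) return(setNames(numeric(n), rownames(adj)))
  ds <- oracle_dist_sigma(adj)
  D <- ds$D; S <- ds$S
  bc <- numeric(n)
  for (v in seq_len(n)) {
    on_path <- outer(D[, v], D[v, ], "+") == D
    val <- (outer(S[, v], S[v, ]) * on_path) / S
    val[S == 0] <- 0
    val[!is.finite(D)] <- 0
    val[v, ] <- 0; val[, v] <- 0
    diag(val) <- 0
    bc[v] <- sum(val[upper.tri(val)])
  }
  setNames(bc / ((n - 1) * (n - 2) / 2), rownames(adj))
}

oracle_closeness <- function(net) {
  adj <- oracle_adjacency(net)
  n <- nrow(adj)
  D <- oracle_dist_sigma(adj)$D
  cc <- vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    d <- d[is.finite(d)]
    if (length(d) == 0) 0 else 1 / mean(d)
  }, numeric(1))
  setNames(cc, rownames(adj))
}

# Erdos-Renyi test network with shuffled string labels
random_test_network <- function(n, p, seed) {
  set.seed(seed)
  labels <- sample(sprintf("N%03d", seq_len(n)))
  pairs <- t(combn(labels, 2))
  keep <- runif(nrow(pairs)) < p
  pin_network(labels, pairs[keep, , drop = FALSE])
}
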