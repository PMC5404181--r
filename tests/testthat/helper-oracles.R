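# independent oracles: brute-force subset enumeration, hand-rolled BFS,
# hypergeometric tail sums

# motif census by exhaustive enumeration of ALL 3- and 4-node subsets,
# classified from the subset's edge count and degree multiset
bruteForceCensus <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  n <- nrow(A)
  counts <- stats::setNames(numeric(8), motifClasses())
  if (n >= 3) for (s in utils::combn(n, 3, simplify = FALSE)) {
    e <- A[s[1], s[2]] + A[s[1], s[3]] + A[s[2], s[3]]
    if (e == 3) counts["triangle"] <- counts["triangle"] + 1
    else if (e == 2) counts["path3"] <- counts["path3"] + 1
  }
  if (n >= 4) for (s in utils::combn(n, 4, simplify = FALSE)) {
    B <- A[s, s]
    deg <- rowSums(B)
    e <- sum(B) / 2
    if (any(deg == 0)) next                       # disconnected
    if (e == 6) counts["clique4"] <- counts["clique4"] + 1
    else if (e == 5) counts["diamond4"] <- counts["diamond4"] + 1
    else if (e == 4) {
      cls <- if (max(deg) == 3) "tadpole4" else "cycle4"
      counts[cls] <- counts[cls] + 1
    } else if (e == 3) {
      # e = 3 with no isolated node: star or path (triangle+isolate has
      # a zero-degree node and was skipped above)
      cls <- if (max(deg) == 3) "star4" else "path4"
      counts[cls] <- counts[cls] + 1
    }
  }
  counts
}

# all shortest path lengths from node i by hand-rolled BFS
bfsFrom <- function(adj, i) {
  n <- length(adj)
  dist <- rep(NA_integer_, n)
  dist[i] <- 0L
  frontier <- i
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[is.na(dist[nxt])]
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

# topology metrics from scratch: BFS over every node
bruteForceTopology <- function(g) {
  n <- igraph::gorder(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (r in seq_len(nrow(el))) {
    adj[[el[r, 1]]] <- c(adj[[el[r, 1]]], el[r, 2])
    adj[[el[r, 2]]] <- c(adj[[el[r, 2]]], el[r, 1])
  }
  dists <- numeric(0)
  for (i in seq_len(n)) {
    d <- bfsFrom(adj, i)
    d <- d[seq_len(n) > i & !is.na(d)]  # unordered connected pairs
    dists <- c(dists, d)
  }
  list(n_nodes = n, n_edges = nrow(el), avg_degree = 2 * nrow(el) / n,
       avg_shortest_path = mean(dists), diameter = max(dists),
       dist_table = table(dists))
}

# one-sided hypergeometric tail by direct summation of choose() products
hyperTailSum <- function(k, nA, nB, U) {
  if (nA == 0 || nB == 0) return(1)
  kk <- k:min(nA, nB)
  sum(choose(nA, kk) * choose(U - nA, nB - kk)) / choose(U, nB)
}

# one-way ANOVA F statistic from the textbook between/within mean squares
anovaFByHand <- function(groups) {
  all <- unlist(groups)
  gm <- mean(all)
  ssb <- sum(lengths(groups) * (vapply(groups, mean, 0) - gm)^2)
  ssw <- sum(vapply(groups, function(x) sum((x - mean(x))^2), 0))
  dfb <- length(groups) - 1
  dfw <- length(all) - length(groups)
  (ssb / dfb) / (ssw / dfw)
}
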