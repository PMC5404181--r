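# graph fixtures built in code

namedGraph <- function(edges, n = NULL, prefix = "T") {
  # edges: 2-column matrix of integer node indices
  if (is.null(n)) n <- max(edges)
  ids <- sprintf("%s|g%03d", prefix, seq_len(n))
  g <- igraph::make_empty_graph(n, directed = FALSE)
  igraph::V(g)$name <- ids
  if (length(edges))
    g <- igraph::add_edges(g, t(matrix(ids[edges], ncol = 2)))
  igraph::simplify(g)
}

randomGnp <- function(n, p, seed, prefix = "T") {
  withr::with_seed(seed, {
    g <- igraph::sample_gnp(n, p, directed = FALSE)
    igraph::V(g)$name <- sprintf("%s|g%03d", prefix, seq_len(n))
    g
  })
}

ringLattice <- function(n, k = 2, prefix = "T") {
  # circulant graph: node i linked to i+-1..k
  edges <- do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, ((i - 1 + seq_len(k)) %% n) + 1)))
  namedGraph(edges, n, prefix)
}

# identity orthology between same-numbered genes of two prefixed networks
identityOrthology <- function(genesA, genesB = genesA) {
  stripA <- sub("^[^|]*\\|", "", genesA)
  stripB <- sub("^[^|]*\\|", "", genesB)
  common <- intersect(stripA, stripB)
  groups <- lapply(common, function(s)
    c(genesA[match(s, stripA)], genesB[match(s, stripB)]))
  names(groups) <- paste0("G", seq_along(groups))
  OrthologyMap(groups, warn = FALSE)
}

relabelGraph <- function(g, prefix) {
  igraph::V(g)$name <- sub("^[^|]*", prefix, igraph::V(g)$name)
  g
}
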