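#' Putative DELLA interactors (PIDs) of a species
#'
#' Maps curated seed interactors from the reference species into a target
#' species through the ortholog group map: every target-species gene
#' sharing a group with any seed qualifies. For the reference species
#' itself the seeds are included alongside their paralogs. The result is
#' intersected with the network's node set; seeds without an expressed
#' counterpart are dropped (count reported via message).
#'
#' @param seeds character vector of seed gene ids in the reference species
#' @param map an [OrthologyMap-class]
#' @param net the target species' [CoexpressionNetwork-class]
#' @param reference reference species label (species of the seeds)
#' @return character vector of PID gene ids present in \code{net}
#' @export
pidSet <- function(seeds, map, net, reference = geneSpecies(seeds[1])) {
  target <- netSpecies(net)
  cand <- unique(unlist(lapply(seeds, orthologsOf, map = map,
                               target_species = target),
                        use.names = FALSE))
  if (target == reference) cand <- unique(c(seeds, cand))
  pids <- intersect(cand, netNodes(net))
  if (length(cand) > length(pids))
    message(length(cand) - length(pids),
            " candidate PID(s) absent from the ", target, " network")
  pids
}

.induced <- function(net, nodes, kind) {
  keep <- intersect(nodes, netNodes(net))
  g <- igraph::induced_subgraph(netGraph(net), keep)
  out <- CoexpressionNetwork(g, species = netSpecies(net))
  attr(out, "kind") <- kind
  out
}

#' "Neighbors" subnetwork: PIDs plus their first neighbors
#'
#' The induced subgraph of the parent network on the PIDs present in the
#' network together with all their first neighbors. All parent edges among
#' the selected nodes are retained (induced-subgraph semantics). PIDs
#' absent from the network are dropped with a warning; an empty effective
#' PID set yields an empty subnetwork with a warning.
#'
#' @param net a [CoexpressionNetwork-class]
#' @param pids gene ids of the DELLA interactors / PIDs
#' @return induced [CoexpressionNetwork-class]
#' @export
neighborsSubnetwork <- function(net, pids) {
  present <- intersect(pids, netNodes(net))
  if (length(present) < length(pids))
    warning(length(pids) - length(present),
            " PID(s) not in the network were dropped")
  if (!length(present)) {
    warning("empty effective PID set: returning empty subnetwork")
    return(.induced(net, character(0), "neighbors"))
  }
  g <- netGraph(net)
  nbr <- unique(unlist(lapply(igraph::adjacent_vertices(g, present),
                              function(v) v$name), use.names = FALSE))
  .induced(net, union(present, nbr), "neighbors")
}

#' "Orthologs" subnetwork: orthologs of all species' PID neighborhoods
#'
#' For a target species, takes its own Neighbors node set plus every
#' target-network gene that is an ortholog of any node of any other
#' species' Neighbors subnetwork, and induces the subgraph on the target's
#' parent network. This represents the full landscape of potential DELLA
#' transcriptional targets.
#'
#' @param nets named list of per-species parent [CoexpressionNetwork-class]s
#' @param neighbor_nodesets named list (same names) of the species'
#'   Neighbors subnetwork node sets
#' @param map an [OrthologyMap-class]
#' @param target_species which species to build the subnetwork for
#' @return induced [CoexpressionNetwork-class]
#' @export
orthologsSubnetwork <- function(nets, neighbor_nodesets, map, target_species) {
  if (!target_species %in% names(nets))
    stop("target species not among networks: ", target_species)
  own <- neighbor_nodesets[[target_species]]
  target_nodes <- netNodes(nets[[target_species]])
  extra <- character(0)
  for (sp in setdiff(names(neighbor_nodesets), target_species)) {
    nodes <- neighbor_nodesets[[sp]]
    if (!length(nodes)) {
      message("species ", sp, " has an empty Neighbors set; contributes nothing")
      next
    }
    orth <- unique(unlist(lapply(nodes, orthologsOf, map = map,
                                 target_species = target_species),
                          use.names = FALSE))
    extra <- union(extra, orth)
  }
  nodes <- union(intersect(own, target_nodes), intersect(extra, target_nodes))
  .induced(nets[[target_species]], nodes, "orthologs")
}

#' Build Neighbors and Orthologs subnetworks for every species
#'
#' Convenience wrapper: derives PID sets from the seed list, builds each
#' species' Neighbors subnetwork, then each species' Orthologs subnetwork.
#'
#' @param nets named list of parent networks
#' @param seeds seed gene ids in the reference species
#' @param map an [OrthologyMap-class]
#' @param reference reference species label
#' @return list with elements \code{pids}, \code{neighbors},
#'   \code{orthologs}, each a named list per species
#' @export
buildSubnetworks <- function(nets, seeds, map,
                             reference = geneSpecies(seeds[1])) {
  pids <- lapply(nets, function(n) pidSet(seeds, map, n, reference))
  neigh <- lapply(names(nets), function(sp)
    suppressWarnings(neighborsSubnetwork(nets[[sp]], pids[[sp]])))
  names(neigh) <- names(nets)
  nodesets <- lapply(neigh, netNodes)
  ortho <- lapply(names(nets), function(sp)
    orthologsSubnetwork(nets, nodesets, map, sp))
  names(ortho) <- names(nets)
  list(pids = pids, neighbors = neigh, orthologs = ortho)
}
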