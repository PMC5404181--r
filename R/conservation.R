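#' @importFrom stats phyper
NULL

# group ids containing at least one of `genes`
.groupsOfGenes <- function(map, genes) {
  unique(unlist(map@index[genes], use.names = FALSE))
}

# one-sided (enrichment) Fisher exact p for a 2x2 overlap table:
# P(X >= k) with X ~ Hypergeometric(|U|, |NA|, |NB|)
.fisherEnrichP <- function(k, nA, nB, U) {
  if (nA == 0 || nB == 0) return(1)
  phyper(k - 1, nA, U - nA, nB, lower.tail = FALSE)
}

#' Cross-species neighborhood conservation (Fisher exact tests)
#'
#' For each gene of network A having at least one ortholog among network
#' B's nodes, both genes' first-neighbor sets are projected into ortholog
#' group space and their overlap is tested for enrichment with a one-sided
#' Fisher exact test. The universe is the set of ortholog groups with at
#' least one member among A's nodes and at least one among B's nodes. A
#' gene counts as having a conserved neighborhood when any of its orthologs
#' yields p < alpha. Genes with an empty projected neighborhood get p = 1
#' by convention.
#'
#' No multiple-testing correction is applied by default; set
#' \code{correct = "BH"} for Benjamini-Hochberg within each direction.
#'
#' @param netA,netB [CoexpressionNetwork-class]s of the two species
#' @param map an [OrthologyMap-class] covering both species
#' @param alpha significance threshold (default 0.05)
#' @param correct \code{"none"} (default) or \code{"BH"}
#' @return list with \code{pct_A} and \code{pct_B} (percent of testable
#'   genes with conserved neighborhood, per direction), \code{pct_mean},
#'   \code{n_testable_A}, \code{n_testable_B}, \code{universe_size}, and
#'   \code{tests} (per-gene data.frame for the A-side direction)
#' @export
neighborhoodConservation <- function(netA, netB, map, alpha = 0.05,
                                     correct = c("none", "BH")) {
  correct <- match.arg(correct)
  U <- .conservationUniverse(netA, netB, map)
  if (!length(U)) stop("empty universe: no ortholog group spans both networks")
  dirA <- .neighDirection(netA, netB, map, U, alpha, correct)
  dirB <- .neighDirection(netB, netA, map, U, alpha, correct)
  list(pct_A = dirA$pct, pct_B = dirB$pct,
       pct_mean = mean(c(dirA$pct, dirB$pct)),
       n_testable_A = dirA$n, n_testable_B = dirB$n,
       universe_size = length(U), tests = dirA$tests)
}

.conservationUniverse <- function(netA, netB, map) {
  intersect(.groupsOfGenes(map, netNodes(netA)),
            .groupsOfGenes(map, netNodes(netB)))
}

.neighDirection <- function(netA, netB, map, U, alpha, correct) {
  spB <- netSpecies(netB)
  nodesB <- netNodes(netB)
  gA <- netGraph(netA); gB <- netGraph(netB)
  adjA <- igraph::adjacent_vertices(gA, netNodes(netA))
  adjB <- igraph::adjacent_vertices(gB, nodesB)
  rows <- list()
  conserved <- logical(0)
  for (a in netNodes(netA)) {
    orth <- intersect(orthologsOf(map, a, spB), nodesB)
    if (!length(orth)) next
    NA_ <- intersect(.groupsOfGenes(map, adjA[[a]]$name), U)
    best_p <- 1; best_b <- orth[1]; best_k <- 0L; best_nB <- 0L
    for (b in orth) {
      NB_ <- intersect(.groupsOfGenes(map, adjB[[b]]$name), U)
      k <- length(intersect(NA_, NB_))
      p <- .fisherEnrichP(k, length(NA_), length(NB_), length(U))
      if (p < best_p || identical(b, orth[1])) {
        best_p <- p; best_b <- b; best_k <- k; best_nB <- length(NB_)
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      gene_a = a, gene_b = best_b, nA = length(NA_), nB = best_nB,
      k = best_k, p_value = best_p)
  }
  tests <- do.call(rbind, rows)
  if (is.null(tests)) return(list(pct = NA_real_, n = 0L, tests = NULL))
  p <- tests$p_value
  if (correct == "BH") p <- stats::p.adjust(p, method = "BH")
  tests$significant <- p < alpha
  list(pct = 100 * mean(tests$significant), n = nrow(tests), tests = tests)
}

#' Cross-species link (edge) conservation
#'
#' An edge of network A is mappable when both endpoints have at least one
#' ortholog among network B's nodes, and conserved when some ortholog pair
#' of its endpoints is itself an edge of B (any-match semantics for
#' many-to-many orthology). The percentage conserved / mappable is
#' reported for both directions plus their mean.
#'
#' @inheritParams neighborhoodConservation
#' @return list with \code{pct_A_to_B}, \code{pct_B_to_A}, \code{pct_mean},
#'   \code{n_mappable_A}, \code{n_mappable_B}
#' @export
linkConservation <- function(netA, netB, map) {
  dAB <- .linkDirection(netA, netB, map)
  dBA <- .linkDirection(netB, netA, map)
  if (dAB$n == 0 && dBA$n == 0) stop("no mappable edges in either direction")
  list(pct_A_to_B = dAB$pct, pct_B_to_A = dBA$pct,
       pct_mean = mean(c(dAB$pct, dBA$pct), na.rm = TRUE),
       n_mappable_A = dAB$n, n_mappable_B = dBA$n)
}

.linkDirection <- function(netA, netB, map) {
  spB <- netSpecies(netB)
  nodesB <- netNodes(netB)
  gB <- netGraph(netB)
  edgesB <- igraph::as_edgelist(gB, names = TRUE)
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  edgeSetB <- if (nrow(edgesB)) ekey(edgesB[, 1], edgesB[, 2]) else character(0)
  edgeSetB <- stats::setNames(rep(TRUE, length(edgeSetB)), edgeSetB)
  orthCache <- new.env(parent = emptyenv())
  getOrth <- function(g) {
    v <- orthCache[[g]]
    if (is.null(v)) {
      v <- intersect(orthologsOf(map, g, spB), nodesB)
      assign(g, v, envir = orthCache)
    }
    v
  }
  edgesA <- igraph::as_edgelist(netGraph(netA), names = TRUE)
  n_mappable <- 0L; n_conserved <- 0L
  if (nrow(edgesA)) for (i in seq_len(nrow(edgesA))) {
    o1 <- getOrth(edgesA[i, 1]); o2 <- getOrth(edgesA[i, 2])
    if (!length(o1) || !length(o2)) next
    n_mappable <- n_mappable + 1L
    keys <- ekey(rep(o1, each = length(o2)), rep(o2, length(o1)))
    if (any(!is.na(edgeSetB[keys]))) n_conserved <- n_conserved + 1L
  }
  pct <- if (n_mappable > 0) 100 * n_conserved / n_mappable else NA_real_
  list(pct = pct, n = n_mappable)
}

#' Pairwise conservation table for full networks and Orthologs subnetworks
#'
#' @param nets named list of per-species full networks
#' @param subnets result of [buildSubnetworks()]
#' @param map an [OrthologyMap-class]
#' @param alpha neighborhood-test significance threshold
#' @return data.frame: species pair, network kind, neighborhood and link
#'   conservation percentages (both directions and mean)
#' @export
conservationTable <- function(nets, subnets, map, alpha = 0.05) {
  sps <- names(nets)
  rows <- list()
  for (i in seq_along(sps)) for (j in seq_along(sps)) {
    if (j <= i) next
    for (kind in c("Full", "Ortho")) {
      a <- if (kind == "Full") nets[[sps[i]]] else subnets$orthologs[[sps[i]]]
      b <- if (kind == "Full") nets[[sps[j]]] else subnets$orthologs[[sps[j]]]
      if (igraph::gsize(netGraph(a)) == 0 || igraph::gsize(netGraph(b)) == 0)
        next
      nc <- tryCatch(neighborhoodConservation(a, b, map, alpha = alpha),
                     error = function(e) NULL)
      lc <- tryCatch(linkConservation(a, b, map), error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        species_a = sps[i], species_b = sps[j], network = kind,
        pct_neighborhood_A = if (is.null(nc)) NA else nc$pct_A,
        pct_neighborhood_B = if (is.null(nc)) NA else nc$pct_B,
        pct_neighborhood_mean = if (is.null(nc)) NA else nc$pct_mean,
        pct_links_A_to_B = if (is.null(lc)) NA else lc$pct_A_to_B,
        pct_links_B_to_A = if (is.null(lc)) NA else lc$pct_B_to_A,
        pct_links_mean = if (is.null(lc)) NA else lc$pct_mean)
    }
  }
  do.call(rbind, rows)
}
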