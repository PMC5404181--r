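#' @import methods
#' @importFrom igraph is_igraph is_directed is_simple gorder gsize V
NULL

#' Co-expression network for one species
#'
#' Thin S4 wrapper around an undirected simple \pkg{igraph} graph whose
#' vertices are gene identifiers of a single species (conventionally
#' prefixed, e.g. \code{"At|g0001"}). Edges connect genes whose expression
#' profiles correlate above the inference threshold.
#'
#' @slot graph an undirected, simple, named \pkg{igraph} graph
#' @slot species single species label
#'
#' @seealso [buildNetwork()], [pruneNetwork()], [summarizeTopology()]
#' @export
setClass("CoexpressionNetwork",
  representation(graph = "ANY", species = "character"))

setValidity("CoexpressionNetwork", function(object) {
  g <- object@graph
  if (!is_igraph(g)) return("'graph' must be an igraph object")
  if (is_directed(g)) return("network must be undirected")
  if (!is_simple(g)) return("network must be simple (no self-edges or multi-edges)")
  if (gorder(g) > 0 && is.null(V(g)$name)) return("vertices must be named")
  if (length(object@species) != 1L) return("'species' must be a single label")
  TRUE
})

#' Construct a CoexpressionNetwork
#'
#' @param graph an undirected simple named igraph graph
#' @param species species label; by default inferred from the gene-id prefix
#'   of the first vertex (text before \code{"|"}), or \code{"unknown"}.
#' @return a [CoexpressionNetwork-class] object
#' @examples
#' g <- igraph::make_ring(5)
#' igraph::V(g)$name <- paste0("Sp|g", 1:5)
#' CoexpressionNetwork(g, "Sp")
#' @export
CoexpressionNetwork <- function(graph, species = NULL) {
  if (is.null(species)) {
    nm <- igraph::V(graph)$name
    species <- if (length(nm)) geneSpecies(nm[1]) else "unknown"
  }
  new("CoexpressionNetwork", graph = graph, species = species)
}

#' @describeIn CoexpressionNetwork underlying igraph graph
#' @param x,object a \code{CoexpressionNetwork}
#' @export
netGraph <- function(x) x@graph

#' @describeIn CoexpressionNetwork species label
#' @export
netSpecies <- function(x) x@species

#' @describeIn CoexpressionNetwork vertex (gene) names
#' @export
netNodes <- function(x) {
  g <- x@graph
  if (gorder(g) == 0) character(0) else igraph::V(g)$name
}

setMethod("show", "CoexpressionNetwork", function(object) {
  g <- object@graph
  cat("CoexpressionNetwork [", object@species, "]: ",
      gorder(g), " nodes, ", gsize(g), " edges\n", sep = "")
})

#' Species tag of prefixed gene identifiers
#'
#' Gene identifiers carry their species as a prefix before \code{"|"}
#' (OrthoMCL convention, e.g. \code{"At|AT1G01030"}).
#'
#' @param genes character vector of prefixed gene ids
#' @return character vector of species labels
#' @examples geneSpecies(c("At|g1", "Sl|g9"))
#' @export
geneSpecies <- function(genes) sub("\\|.*$", "", genes)

#' Ortholog group map (OrthoMCL-style)
#'
#' Named groups of species-prefixed gene identifiers, with a reverse index
#' from gene to group names. Genes in the same group are orthologs when they
#' belong to different species and paralogs when they belong to the same
#' species. A gene may belong to several groups only if the input file says
#' so; such genes are tracked in \code{duplicated}.
#'
#' @slot groups named list; each element a character vector of "Sp|gene" ids
#' @slot index named list mapping gene id to the group names containing it
#' @slot duplicated gene ids appearing in more than one group
#' @seealso [readOrthoGroups()], [orthologsOf()], [membershipVenn()]
#' @export
setClass("OrthologyMap",
  representation(groups = "list", index = "list", duplicated = "character"))

setValidity("OrthologyMap", function(object) {
  if (length(object@groups) && is.null(names(object@groups)))
    return("groups must be named")
  ok <- vapply(object@groups, is.character, logical(1))
  if (!all(ok)) return("each group must be a character vector of gene ids")
  TRUE
})

#' Construct an OrthologyMap from a named list of groups
#'
#' @param groups named list of character vectors of "Sp|gene" identifiers
#' @param warn warn when a gene belongs to more than one group
#' @return an [OrthologyMap-class]
#' @examples
#' OrthologyMap(list(G1 = c("At|a1", "Sl|s1", "Sl|s2")))
#' @export
OrthologyMap <- function(groups, warn = TRUE) {
  stopifnot(is.list(groups))
  if (length(groups) && is.null(names(groups)))
    names(groups) <- paste0("GROUP_", seq_along(groups))
  genes <- unlist(groups, use.names = FALSE)
  gname <- rep(names(groups), lengths(groups))
  index <- if (length(genes)) split(gname, genes)
           else structure(list(), names = character(0))
  dup <- names(index)[lengths(index) > 1L]
  if (warn && length(dup))
    warning(length(dup), " gene(s) belong to more than one group")
  new("OrthologyMap", groups = groups, index = index,
      duplicated = as.character(dup))
}

#' @describeIn OrthologyMap the named list of groups
#' @param x,object an \code{OrthologyMap}
#' @export
orthoGroups <- function(x) x@groups

#' @describeIn OrthologyMap number of groups
#' @export
nGroups <- function(x) length(x@groups)

#' @describeIn OrthologyMap species labels occurring in the map
#' @export
mapSpecies <- function(x)
  sort(unique(geneSpecies(unlist(x@groups, use.names = FALSE))))

setMethod("show", "OrthologyMap", function(object) {
  cat("OrthologyMap: ", length(object@groups), " groups, ",
      length(object@index), " genes, species: ",
      paste(mapSpecies(object), collapse = ", "), "\n", sep = "")
  if (length(object@duplicated))
    cat("  ", length(object@duplicated), " gene(s) in multiple groups\n")
})

#' Synthetic multi-species world
#'
#' Bundle of per-species expression matrices
#' (\linkS4class{SummarizedExperiment}s with a study/condition/control
#' design), an ortholog group map, the curated seed (DELLA-interactor) list
#' in the reference species, and the generator's ground-truth record.
#'
#' @slot expression named list of \code{SummarizedExperiment}, one per species
#' @slot orthology an [OrthologyMap-class]
#' @slot seeds seed gene ids in the reference species
#' @slot reference reference species label
#' @slot truth list recording planted module assignments, per-species module
#'   realizations, seed modules, density multipliers and the RNG seed
#' @seealso [simulateWorld()]
#' @export
setClass("SyntheticWorld",
  representation(expression = "list", orthology = "OrthologyMap",
                 seeds = "character", reference = "character",
                 truth = "list"))

setValidity("SyntheticWorld", function(object) {
  if (is.null(names(object@expression))) return("expression list must be named by species")
  ref <- object@reference
  if (!ref %in% names(object@expression)) return("reference species has no expression matrix")
  universe <- rownames(object@expression[[ref]])
  if (!all(object@seeds %in% universe))
    return("every seed gene must exist in the reference species' gene universe")
  TRUE
})

setMethod("show", "SyntheticWorld", function(object) {
  cat("SyntheticWorld: ", length(object@expression), " species (",
      paste(names(object@expression), collapse = ", "), "), ",
      nGroups(object@orthology), " ortholog groups, ",
      length(object@seeds), " seed genes in ", object@reference, "\n", sep = "")
})

#' @describeIn SyntheticWorld named list of per-species expression matrices
#' @param x,object a \code{SyntheticWorld}
#' @export
worldExpression <- function(x) x@expression

#' @describeIn SyntheticWorld the ortholog group map
#' @export
worldOrthology <- function(x) x@orthology

#' @describeIn SyntheticWorld seed genes in the reference species
#' @export
worldSeeds <- function(x) x@seeds

#' @describeIn SyntheticWorld generator ground truth record
#' @export
worldTruth <- function(x) x@truth

#' @describeIn SyntheticWorld reference species label
#' @export
worldReference <- function(x) x@reference
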