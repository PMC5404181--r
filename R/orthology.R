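#' Read an OrthoMCL-style ortholog groups file
#'
#' Expected format, one group per line:
#' \preformatted{GROUP_1: At|g0001 Sl|g0007 Sl|g0012}
#' The text before the first colon is the group name; members are
#' whitespace-separated species-prefixed gene ids. Genes listed in more
#' than one group keep all memberships (with a warning).
#'
#' @param path path to the groups file
#' @return an [OrthologyMap-class]
#' @export
readOrthoGroups <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty ortholog groups file: ", path)
    return(OrthologyMap(list(), warn = FALSE))
  }
  bad <- grep(":", lines, fixed = TRUE, invert = TRUE)
  if (length(bad))
    stop("malformed groups line ", bad[1], " (no ':'): ", lines[bad[1]])
  name <- trimws(sub(":.*$", "", lines))
  body <- trimws(sub("^[^:]*:", "", lines))
  groups <- strsplit(body, "[[:space:]]+")
  empty <- !vapply(groups, function(g) length(g) > 0 && all(nzchar(g)), logical(1))
  if (any(empty))
    stop("malformed groups line ", which(empty)[1], " (no members)")
  noprefix <- vapply(groups, function(g) any(!grepl("|", g, fixed = TRUE)), logical(1))
  if (any(noprefix))
    stop("malformed groups line ", which(noprefix)[1],
         " (member without species prefix 'Sp|gene')")
  names(groups) <- name
  OrthologyMap(groups)
}

#' Write an OrthologyMap in OrthoMCL groups format
#'
#' @param map an [OrthologyMap-class]
#' @param path output file
#' @return invisibly, the path
#' @export
writeOrthoGroups <- function(map, path) {
  lines <- paste0(names(orthoGroups(map)), ": ",
                  vapply(orthoGroups(map), paste, "", collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Orthologs (or paralogs) of a gene
#'
#' Returns the union, over all groups containing \code{gene}, of members
#' belonging to \code{target_species}. When the target species equals the
#' gene's own species the result is its paralogs, with the gene itself
#' excluded. A gene in no group yields an empty set.
#'
#' @param map an [OrthologyMap-class]
#' @param gene species-prefixed gene id
#' @param target_species species label to project into
#' @return character vector of gene ids (possibly empty)
#' @examples
#' m <- OrthologyMap(list(G1 = c("At|a1", "Sl|s1", "Sl|s2")))
#' orthologsOf(m, "At|a1", "Sl")
#' orthologsOf(m, "Sl|s1", "Sl")  # paralog, self excluded
#' @export
orthologsOf <- function(map, gene, target_species) {
  grps <- map@index[[gene]]
  if (is.null(grps)) return(character(0))
  members <- unique(unlist(map@groups[grps], use.names = FALSE))
  hits <- members[geneSpecies(members) == target_species]
  if (geneSpecies(gene) == target_species) hits <- setdiff(hits, gene)
  hits
}

#' Group membership counts per species combination
#'
#' For each non-empty subset of \code{species_list}, counts the groups whose
#' set of represented species (restricted to \code{species_list}) is exactly
#' that subset — the counts behind an OrthoMCL-group Venn diagram. Cell
#' counts sum to the number of groups containing at least one listed
#' species.
#'
#' @param map an [OrthologyMap-class]
#' @param species_list species labels to cross-tabulate
#' @return data.frame with columns \code{combination} (labels joined by
#'   \code{"&"}) and \code{n_groups}
#' @examples
#' m <- OrthologyMap(list(G1 = "A|x", G2 = c("A|y", "B|y"), G3 = c("A|z", "B|z")))
#' membershipVenn(m, c("A", "B"))
#' @export
membershipVenn <- function(map, species_list = mapSpecies(map)) {
  stopifnot(length(species_list) >= 1)
  known <- mapSpecies(map)
  unknown <- setdiff(species_list, known)
  if (length(unknown))
    stop("unknown species label(s): ", paste(unknown, collapse = ", "))
  combos <- vapply(orthoGroups(map), function(g) {
    sp <- intersect(species_list, unique(geneSpecies(g)))
    paste(sp, collapse = "&")
  }, "")
  combos <- combos[nzchar(combos)]
  tab <- table(combos)
  data.frame(combination = names(tab), n_groups = as.integer(tab),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fraction of groups containing each species
#'
#' @param map an [OrthologyMap-class]
#' @return named numeric vector, one fraction per species
#' @export
speciesPresenceFraction <- function(map) {
  sp <- mapSpecies(map)
  pres <- vapply(sp, function(s)
    mean(vapply(orthoGroups(map),
                function(g) s %in% geneSpecies(g), logical(1))), 0)
  pres
}
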