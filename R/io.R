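#' @importFrom utils read.delim write.table
NULL

#' Write / read a network in SIF format
#'
#' Simple interaction format: one edge per line, \code{"geneA co geneB"};
#' isolated nodes are written as a line containing only the node name.
#' Edges are written in a canonical sorted order so identical networks
#' produce byte-identical files.
#'
#' @param net a [CoexpressionNetwork-class]
#' @param path file path
#' @param relation interaction type token (default \code{"co"})
#' @return \code{writeSIF}: the path, invisibly. \code{readSIF}: a
#'   [CoexpressionNetwork-class].
#' @export
writeSIF <- function(net, path, relation = "co") {
  g <- netGraph(net)
  el <- igraph::as_edgelist(g, names = TRUE)
  lines <- character(0)
  if (nrow(el)) {
    a <- pmin(el[, 1], el[, 2]); b <- pmax(el[, 1], el[, 2])
    o <- order(a, b)
    lines <- paste(a[o], relation, b[o])
  }
  iso <- netNodes(net)[igraph::degree(g) == 0]
  writeLines(c(lines, sort(iso)), path)
  invisible(path)
}

#' @rdname writeSIF
#' @param species species label for the read network (default inferred
#'   from the first gene id)
#' @export
readSIF <- function(path, species = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  n_tok <- lengths(parts)
  if (any(!n_tok %in% c(1L, 3L)))
    stop("malformed SIF line ", which(!n_tok %in% c(1L, 3L))[1])
  edges <- do.call(rbind, lapply(parts[n_tok == 3L],
                                 function(p) p[c(1, 3)]))
  iso <- unlist(lapply(parts[n_tok == 1L], `[`, 1))
  g <- if (is.null(edges))
    igraph::make_empty_graph(0, directed = FALSE)
  else
    igraph::graph_from_edgelist(edges, directed = FALSE)
  miss <- setdiff(iso, if (igraph::gorder(g)) igraph::V(g)$name else character(0))
  if (length(miss)) g <- g + igraph::vertices(miss)
  CoexpressionNetwork(igraph::simplify(g), species = species)
}

#' Write / read a network in GML format
#'
#' Thin wrappers over \pkg{igraph}'s GML writer/reader that preserve gene
#' identifiers through the vertex \code{label} attribute.
#'
#' @inheritParams writeSIF
#' @export
writeGML <- function(net, path) {
  g <- netGraph(net)
  igraph::V(g)$label <- igraph::V(g)$name
  igraph::write_graph(g, path, format = "gml")
  invisible(path)
}

#' @rdname writeGML
#' @export
readGML <- function(path, species = NULL) {
  g <- igraph::read_graph(path, format = "gml")
  if (!is.null(igraph::V(g)$label)) igraph::V(g)$name <- igraph::V(g)$label
  g <- igraph::delete_vertex_attr(g, "label")
  if ("id" %in% igraph::vertex_attr_names(g))
    g <- igraph::delete_vertex_attr(g, "id")
  CoexpressionNetwork(igraph::simplify(igraph::as_undirected(g)),
                      species = species)
}

#' Write an expression matrix and its design table as TSV
#'
#' @param se a \code{SummarizedExperiment} with study/condition/is_control
#'   design columns
#' @param expr_path,design_path output file paths
#' @return invisibly, the expression path
#' @export
writeExpressionTSV <- function(se, expr_path, design_path) {
  mat <- SummarizedExperiment::assay(se)
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  write.table(df, expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  dd <- data.frame(sample = rownames(cd), cd, check.names = FALSE)
  write.table(dd, design_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(expr_path)
}

#' Read an expression matrix TSV plus design TSV
#'
#' @param expr_path genes-by-samples TSV with a \code{gene} column
#' @param design_path sample design TSV (\code{sample}, \code{study},
#'   \code{condition}, \code{is_control})
#' @return a \code{SummarizedExperiment}
#' @export
readExpressionTSV <- function(expr_path, design_path) {
  df <- read.delim(expr_path, check.names = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  dd <- read.delim(design_path, check.names = FALSE)
  rn <- dd[[1]]
  dd <- dd[, -1, drop = FALSE]
  rownames(dd) <- rn
  dd$is_control <- as.logical(dd$is_control)
  mat <- mat[, rn, drop = FALSE]
  SummarizedExperiment::SummarizedExperiment(
    assays = list(fpkm = mat), colData = S4Vectors::DataFrame(dd))
}

#' Write a SyntheticWorld to a directory of plain-text files
#'
#' Emits, per species, \code{<sp>_expression.tsv} and
#' \code{<sp>_design.tsv}; plus \code{groups.txt} (OrthoMCL format),
#' \code{seeds.txt} (one gene per line) and \code{truth.json}.
#'
#' @param world a [SyntheticWorld-class]
#' @param outdir output directory (created if needed)
#' @return invisibly, the output directory
#' @export
writeWorld <- function(world, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (sp in names(worldExpression(world)))
    writeExpressionTSV(worldExpression(world)[[sp]],
                       file.path(outdir, paste0(sp, "_expression.tsv")),
                       file.path(outdir, paste0(sp, "_design.tsv")))
  writeOrthoGroups(worldOrthology(world), file.path(outdir, "groups.txt"))
  writeLines(worldSeeds(world), file.path(outdir, "seeds.txt"))
  truth <- worldTruth(world)
  truth$modules <- lapply(truth$modules, as.list)
  jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
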