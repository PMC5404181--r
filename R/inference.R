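#' @importFrom SummarizedExperiment assay colData
#' @importFrom stats cor
NULL

.checkDesign <- function(se) {
  cd <- as.data.frame(colData(se))
  need <- c("study", "condition", "is_control")
  if (!all(need %in% colnames(cd)))
    stop("design must contain columns: ", paste(need, collapse = ", "))
  ctrl <- tapply(cd$is_control, cd$study, any)
  if (!all(ctrl))
    stop("design error: study without a control sample: ",
         paste(names(ctrl)[!ctrl], collapse = ", "))
  if (anyDuplicated(rownames(assay(se))))
    stop("duplicate gene identifiers in expression matrix")
  invisible(cd)
}

#' Select differentially expressed genes by fold change
#'
#' Within each study, compares every non-control condition's mean FPKM
#' against that study's control mean, gene by gene. The fold change is
#' two-sided (the larger of ratio and inverse ratio) with a pseudocount
#' added to both means so all-zero genes are handled. A gene is selected
#' when it reaches the threshold in at least one comparison of at least one
#' study.
#'
#' @param expr \code{SummarizedExperiment}; FPKM-like assay, colData with
#'   \code{study}, \code{condition}, \code{is_control}
#' @param fc_threshold minimum fold change (default 2), must be > 1
#' @param pseudocount added to both means before taking the ratio
#' @return character vector of selected gene ids
#' @examples
#' se <- exampleExpressionSE()
#' head(selectDifferentialGenes(se))
#' @export
selectDifferentialGenes <- function(expr, fc_threshold = 2, pseudocount = 0.01) {
  stopifnot(fc_threshold > 1)
  cd <- .checkDesign(expr)
  mat <- assay(expr)
  selected <- rep(FALSE, nrow(mat))
  for (st in unique(cd$study)) {
    in_st <- cd$study == st
    ctrl_cols <- which(in_st & cd$is_control)
    cmean <- rowMeans(mat[, ctrl_cols, drop = FALSE]) + pseudocount
    for (cond in unique(cd$condition[in_st & !cd$is_control])) {
      tcols <- which(in_st & !cd$is_control & cd$condition == cond)
      if (!length(tcols)) next
      tmean <- rowMeans(mat[, tcols, drop = FALSE]) + pseudocount
      fc <- pmax(tmean / cmean, cmean / tmean)
      selected <- selected | fc >= fc_threshold
    }
  }
  rownames(mat)[selected]
}

#' Build a co-expression network by thresholding Pearson correlation
#'
#' Computes the Pearson correlation between every pair of gene expression
#' profiles over all samples jointly and draws an edge when the signed
#' correlation exceeds \code{r_threshold} (strictly greater). Negative
#' correlations never produce edges. Genes with zero-variance profiles have
#' undefined correlations and participate in no edges (counted in a
#' message).
#'
#' @param expr \code{SummarizedExperiment} with an FPKM-like assay
#' @param genes gene ids to include (e.g. from [selectDifferentialGenes()]);
#'   default all genes
#' @param r_threshold correlation threshold in (0, 1); default 0.95
#' @param species species label for the resulting network
#' @return a [CoexpressionNetwork-class]
#' @examples
#' se <- exampleExpressionSE()
#' buildNetwork(se, r_threshold = 0.9)
#' @export
buildNetwork <- function(expr, genes = rownames(expr), r_threshold = 0.95,
                         species = NULL) {
  stopifnot(r_threshold > 0, r_threshold < 1)
  mat <- assay(expr)
  genes <- intersect(genes, rownames(mat))
  if (length(genes) < 2) stop("need at least 2 genes to build a network")
  if (ncol(mat) < 3) stop("insufficient data: need at least 3 samples")
  sub <- t(mat[genes, , drop = FALSE])
  sds <- apply(sub, 2, stats::sd)
  n_const <- sum(sds == 0 | !is.finite(sds))
  if (n_const > 0)
    message(n_const, " zero-variance gene profile(s): no edges for these genes")
  cc <- suppressWarnings(cor(sub, method = "pearson"))
  adj <- !is.na(cc) & cc > r_threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  CoexpressionNetwork(g, species = species)
}

#' Prune a co-expression network
#'
#' Applies, in order: removal of self-edges (only edges between two
#' non-identical nodes are kept), removal of nodes absent from a reference
#' proteome (when one is supplied), and deletion of every connected
#' component with fewer than \code{min_component} nodes. The result is the
#' species' "complete network". Pruning is idempotent.
#'
#' @param net a [CoexpressionNetwork-class] (need not be simple yet)
#' @param min_component components with fewer nodes than this are removed
#'   (default 7, i.e. components of six or fewer nodes are dropped)
#' @param proteome optional character vector of gene ids considered present
#'   in the reference proteome
#' @return pruned [CoexpressionNetwork-class] (possibly empty)
#' @export
pruneNetwork <- function(net, min_component = 7, proteome = NULL) {
  g <- if (is(net, "CoexpressionNetwork")) net@graph else net
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  if (!is.null(proteome)) {
    drop <- setdiff(igraph::V(g)$name, proteome)
    if (length(drop)) {
      message(length(drop), " node(s) not in proteome removed")
      g <- igraph::delete_vertices(g, drop)
    }
  }
  comp <- igraph::components(g)
  small <- which(comp$csize < min_component)
  if (length(small))
    g <- igraph::delete_vertices(g, which(comp$membership %in% small))
  sp <- if (is(net, "CoexpressionNetwork")) net@species else NULL
  CoexpressionNetwork(g, species = sp)
}

#' One-call network inference
#'
#' Convenience wrapper chaining [selectDifferentialGenes()],
#' [buildNetwork()] and [pruneNetwork()] with the standard thresholds
#' (fold change 2, Pearson r > 0.95, minimum component size 7).
#'
#' @inheritParams selectDifferentialGenes
#' @inheritParams buildNetwork
#' @inheritParams pruneNetwork
#' @return a pruned [CoexpressionNetwork-class]
#' @export
inferNetwork <- function(expr, fc_threshold = 2, r_threshold = 0.95,
                         min_component = 7, proteome = NULL, species = NULL) {
  de <- selectDifferentialGenes(expr, fc_threshold = fc_threshold)
  if (length(de) < 2) stop("fewer than 2 differentially expressed genes")
  net <- buildNetwork(expr, genes = de, r_threshold = r_threshold,
                      species = species)
  pruneNetwork(net, min_component = min_component, proteome = proteome)
}
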