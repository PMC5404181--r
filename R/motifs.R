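#' @useDynLib dellanet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' The eight connected undirected motif classes on 3-4 nodes
#'
#' Two classes on three nodes (path, triangle) and six on four nodes
#' (path, star, cycle, tadpole = triangle with a pendant edge, diamond =
#' cycle with one chord, clique). Each class is uniquely identified by its
#' sorted induced degree sequence.
#'
#' @return character vector of the 8 class names in canonical order
#' @export
motifClasses <- function() {
  c("path3", "triangle", "path4", "star4", "cycle4", "tadpole4",
    "diamond4", "clique4")
}

.motifSizes <- c(path3 = 3L, triangle = 3L, path4 = 4L, star4 = 4L,
                 cycle4 = 4L, tadpole4 = 4L, diamond4 = 4L, clique4 = 4L)

#' Census of connected 3- and 4-node motifs
#'
#' Counts induced occurrences of the eight connected undirected motif
#' classes on 3 and 4 nodes by ESU-style connected-subgraph enumeration
#' (only connected node subsets are ever visited), classifying each
#' enumerated subgraph by its sorted degree sequence. Counting is
#' induced-occurrence: a triangle never also counts as a 3-path.
#'
#' Frequencies normalize counts by the number of possible node
#' combinations, \eqn{C(N,3)} for 3-node and \eqn{C(N,4)} for 4-node
#' classes, so networks of different sizes are comparable.
#'
#' For large dense networks, uniform subgraph sampling (RAND-ESU) with a
#' Horvitz-Thompson count estimator is available: \code{sample_prob} keeps
#' each enumeration branch with the given per-depth probability, and
#' recorded subgraphs are up-weighted by the inverse inclusion
#' probability. The default is exact enumeration.
#'
#' @param net a [CoexpressionNetwork-class] or igraph graph (simple,
#'   undirected)
#' @param sample_prob \code{NULL} for exact counts, or a probability in
#'   (0, 1]: each enumeration level keeps branches with this probability
#' @return data.frame with columns \code{class}, \code{size},
#'   \code{count}, \code{denominator}, \code{frequency}
#' @examples
#' g <- igraph::make_full_graph(4)
#' igraph::V(g)$name <- paste0("Sp|g", 1:4)
#' motifCensus(g)  # 4 triangles, 1 clique4
#' @export
motifCensus <- function(net, sample_prob = NULL) {
  g <- if (is(net, "CoexpressionNetwork")) netGraph(net) else net
  stopifnot(!igraph::is_directed(g), igraph::is_simple(g))
  n <- igraph::gorder(g)
  el <- igraph::as_edgelist(g, names = FALSE) - 1L
  counts <- numeric(8)
  names(counts) <- motifClasses()
  if (n >= 3) {
    pr3 <- if (is.null(sample_prob)) rep(1, 3) else rep(sample_prob, 3)
    counts[1:2] <- .esuCensus(as.integer(el[, 1]), as.integer(el[, 2]),
                              as.integer(n), 3L, pr3)
  }
  if (n >= 4) {
    pr4 <- if (is.null(sample_prob)) rep(1, 4) else rep(sample_prob, 4)
    counts[3:8] <- .esuCensus(as.integer(el[, 1]), as.integer(el[, 2]),
                              as.integer(n), 4L, pr4)
  }
  denom <- ifelse(.motifSizes == 3L, choose(n, 3), choose(n, 4))
  freq <- ifelse(denom > 0, counts / denom, 0)
  data.frame(class = motifClasses(), size = unname(.motifSizes),
             count = unname(counts), denominator = unname(denom),
             frequency = unname(freq), stringsAsFactors = FALSE)
}

#' Motif enrichment ratios between a subnetwork and its full network
#'
#' Per class, the ratio of the subnetwork's normalized motif frequency to
#' the full network's. Identical censuses give ratios of 1; classes absent
#' from the full network have an undefined ratio (\code{NA}, flagged).
#'
#' @param sub_census,full_census data.frames from [motifCensus()]
#' @return data.frame with columns \code{class}, \code{ratio},
#'   \code{defined}
#' @export
enrichmentRatios <- function(sub_census, full_census) {
  stopifnot(identical(sub_census$class, full_census$class))
  defined <- full_census$frequency > 0
  ratio <- ifelse(defined, sub_census$frequency / full_census$frequency,
                  NA_real_)
  data.frame(class = sub_census$class, ratio = ratio, defined = defined,
             stringsAsFactors = FALSE)
}

#' Compare motif enrichment across species (ANOVA + Tukey HSD)
#'
#' One-way ANOVA of per-class enrichment ratios across species, followed by
#' Tukey HSD pairwise comparisons and a compact letter display (species
#' sharing no letter differ significantly at \code{alpha}).
#'
#' @param ratio_sets named list: species -> numeric vector of per-class
#'   enrichment ratios (NAs dropped)
#' @param alpha significance level for the Tukey grouping (default 0.01)
#' @return list with \code{anova_F}, \code{anova_p}, \code{tukey}
#'   (pairwise data.frame), and \code{letters} (named character vector)
#' @export
compareEnrichment <- function(ratio_sets, alpha = 0.01) {
  stopifnot(length(ratio_sets) >= 2)
  ratio_sets <- lapply(ratio_sets, function(x) x[is.finite(x)])
  ns <- lengths(ratio_sets)
  if (any(ns < 2))
    stop("insufficient data: each group needs at least 2 ratio values")
  df <- data.frame(
    ratio = unlist(ratio_sets, use.names = FALSE),
    species = factor(rep(names(ratio_sets), ns)))
  if (stats::var(df$ratio) < 1e-24) {
    letters <- stats::setNames(rep("a", length(ratio_sets)), names(ratio_sets))
    return(list(anova_F = 0, anova_p = 1,
                tukey = NULL, letters = letters))
  }
  fit <- stats::aov(ratio ~ species, data = df)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$species
  pair <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                     p_adj = tk[, "p adj"], row.names = NULL)
  letters <- .compactLetters(levels(df$species), pair, alpha)
  list(anova_F = an[["F value"]][1], anova_p = an[["Pr(>F)"]][1],
       tukey = pair, letters = letters)
}

# insert-and-absorb compact letter display from pairwise p-values
.compactLetters <- function(groups, pair, alpha) {
  k <- length(groups)
  sig <- matrix(FALSE, k, k, dimnames = list(groups, groups))
  for (i in seq_len(nrow(pair))) {
    gs <- strsplit(pair$comparison[i], "-", fixed = TRUE)[[1]]
    if (length(gs) == 2 && pair$p_adj[i] < alpha) {
      sig[gs[1], gs[2]] <- TRUE
      sig[gs[2], gs[1]] <- TRUE
    }
  }
  # start with one column (letter) containing all groups; for each
  # significant pair found together in a column, duplicate the column and
  # split them; absorb redundant columns
  cols <- list(rep(TRUE, k))
  for (a in seq_len(k)) for (b in seq_len(k)) {
    if (b <= a || !sig[a, b]) next
    for (ci in seq_along(cols)) {
      col <- cols[[ci]]
      if (col[a] && col[b]) {
        new1 <- col; new1[b] <- FALSE
        new2 <- col; new2[a] <- FALSE
        cols[[ci]] <- new1
        cols[[length(cols) + 1L]] <- new2
      }
    }
    # absorb: drop columns whose membership is a subset of another's
    keep <- rep(TRUE, length(cols))
    for (i in seq_along(cols)) for (j in seq_along(cols)) {
      if (i != j && keep[i] && keep[j] &&
          all(cols[[i]] <= cols[[j]]) && any(cols[[i]] < cols[[j]]))
        keep[i] <- FALSE
      else if (i < j && keep[i] && keep[j] &&
               all(cols[[i]] == cols[[j]]))
        keep[j] <- FALSE
    }
    cols <- cols[keep]
  }
  lab <- rep("", k)
  for (ci in seq_along(cols))
    lab[cols[[ci]]] <- paste0(lab[cols[[ci]]], letters[ci])
  stats::setNames(lab, groups)
}

#' Motif enrichment table across species
#'
#' Runs [motifCensus()] on each species' full network and Orthologs
#' subnetwork, computes per-class enrichment ratios, and (when at least
#' two species have enough defined ratios) the cross-species ANOVA/Tukey
#' grouping.
#'
#' @param nets named list of full networks
#' @param subnets result of [buildSubnetworks()]
#' @param alpha significance level for the Tukey grouping
#' @param sample_prob passed to [motifCensus()]
#' @return list with \code{ratios} (long data.frame) and \code{comparison}
#'   (output of [compareEnrichment()] or NULL)
#' @export
motifEnrichmentTable <- function(nets, subnets, alpha = 0.01,
                                 sample_prob = NULL) {
  rows <- list(); sets <- list()
  for (sp in names(nets)) {
    full <- motifCensus(nets[[sp]], sample_prob = sample_prob)
    sub <- motifCensus(subnets$orthologs[[sp]], sample_prob = sample_prob)
    er <- enrichmentRatios(sub, full)
    rows[[sp]] <- cbind(species = sp, er)
    sets[[sp]] <- er$ratio
  }
  usable <- vapply(sets, function(x) sum(is.finite(x)) >= 2, logical(1))
  cmp <- if (sum(usable) >= 2)
    compareEnrichment(sets[usable], alpha = alpha) else NULL
  list(ratios = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       comparison = cmp)
}
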