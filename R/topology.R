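#' Topology summary of a network
#'
#' Node count, edge count, average degree (2E/N), average shortest path
#' length and diameter. Path metrics are computed over all unordered
#' connected node pairs; pairs in different components are excluded rather
#' than assigned infinity, so multi-component networks report finite
#' values. On an edgeless network the path metrics are undefined and
#' returned as \code{NA}.
#'
#' @param net a [CoexpressionNetwork-class] or igraph graph
#' @return data.frame with one row: \code{n_nodes}, \code{n_edges},
#'   \code{avg_degree}, \code{avg_shortest_path}, \code{diameter}
#' @examples
#' g <- igraph::make_full_graph(3)
#' igraph::V(g)$name <- paste0("Sp|g", 1:3)
#' summarizeTopology(g)  # avg_degree 2, path 1, diameter 1
#' @export
summarizeTopology <- function(net) {
  g <- if (is(net, "CoexpressionNetwork")) netGraph(net) else net
  n <- igraph::gorder(g)
  if (n == 0) stop("network is empty")
  e <- igraph::gsize(g)
  if (e == 0) {
    message("edgeless network: path metrics undefined")
    asp <- NA_real_; diam <- NA_real_
  } else {
    asp <- igraph::mean_distance(g, directed = FALSE, unconnected = TRUE)
    diam <- igraph::diameter(g, directed = FALSE, unconnected = TRUE)
  }
  data.frame(n_nodes = n, n_edges = e, avg_degree = 2 * e / n,
             avg_shortest_path = asp, diameter = diam)
}

#' Shortest-path-length distribution
#'
#' Exact histogram of shortest-path lengths over all unordered connected
#' node pairs. Lengths are reported in both conventions: number of edges
#' and number of intermediate nodes (edges minus one, the convention used
#' when plotting how many nodes separate two random genes).
#'
#' @param net a [CoexpressionNetwork-class] or igraph graph with at least
#'   one edge
#' @return data.frame with columns \code{length_edges},
#'   \code{intermediate_nodes}, \code{count}, \code{frequency}
#'   (frequencies sum to 1 over connected pairs)
#' @export
pathLengthDistribution <- function(net) {
  g <- if (is(net, "CoexpressionNetwork")) netGraph(net) else net
  if (igraph::gsize(g) == 0) stop("network has no edges")
  res <- igraph::distance_table(g, directed = FALSE)$res
  res <- res[seq_len(max(which(res > 0)))]
  data.frame(length_edges = seq_along(res),
             intermediate_nodes = seq_along(res) - 1L,
             count = res,
             frequency = res / sum(res))
}

#' Power-law check on the degree distribution
#'
#' Least-squares fit of log10(relative frequency) against log10(degree) on
#' the raw (unbinned) degree distribution, dropping zero-frequency degrees
#' and degrees below \code{min_degree}. Returns the slope and R-squared;
#' no pass/fail verdict is applied. Scale-free networks show approximately
#' linear decay with slope around -2 to -3. Logarithmic binning
#' (averaging frequencies within degree bins of geometrically growing
#' width) is available for heavy-tailed tails.
#'
#' @param net a [CoexpressionNetwork-class] or igraph graph
#' @param min_degree smallest degree included in the fit
#' @param log_bins if TRUE, fit on logarithmically binned degrees
#' @return list with \code{slope}, \code{r_squared}, \code{n_degrees}, and
#'   the fitted \code{data}
#' @export
scaleFreeFit <- function(net, min_degree = 1, log_bins = FALSE) {
  g <- if (is(net, "CoexpressionNetwork")) netGraph(net) else net
  deg <- igraph::degree(g)
  deg <- deg[deg >= min_degree & deg > 0]
  tab <- table(deg)
  if (length(tab) < 5)
    stop("insufficient data: need at least 5 distinct degree values, got ",
         length(tab))
  d <- as.numeric(names(tab))
  f <- as.numeric(tab) / igraph::gorder(g)
  if (log_bins) {
    brk <- 2^(0:ceiling(log2(max(d) + 1)))
    bin <- cut(d, breaks = unique(c(0, brk)), right = FALSE)
    d <- tapply(d, bin, mean, na.rm = TRUE)
    f <- tapply(f, bin, mean, na.rm = TRUE)
    ok <- !is.na(d) & !is.na(f)
    d <- d[ok]; f <- f[ok]
  }
  fit <- stats::lm(log10(f) ~ log10(d))
  list(slope = unname(stats::coef(fit)[2]),
       r_squared = summary(fit)$r.squared,
       n_degrees = length(d),
       data = data.frame(degree = d, frequency = f))
}

#' Table of topology summaries for full networks and subnetworks
#'
#' @param nets named list of per-species full networks
#' @param subnets result of [buildSubnetworks()] (or NULL for full only)
#' @return long data.frame: species, network (Full/Neigh/Ortho), metrics
#' @export
topologyTable <- function(nets, subnets = NULL) {
  rows <- list()
  for (sp in names(nets)) {
    sets <- list(Full = nets[[sp]])
    if (!is.null(subnets)) {
      sets$Neigh <- subnets$neighbors[[sp]]
      sets$Ortho <- subnets$orthologs[[sp]]
    }
    for (kind in names(sets)) {
      g <- netGraph(sets[[kind]])
      if (igraph::gorder(g) == 0) next
      s <- suppressMessages(summarizeTopology(sets[[kind]]))
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(species = sp, network = kind), s)
    }
  }
  do.call(rbind, rows)
}
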