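#' Read a pipeline run configuration
#'
#' YAML configuration with either a \code{simulate} block (passed to
#' [simulateWorld()]) or per-species \code{expression}/\code{design} file
#' paths plus \code{groups} and \code{seeds} paths, and optional
#' \code{thresholds} overrides (\code{fc}, \code{r}, \code{min_component},
#' \code{alpha}, \code{motif_alpha}).
#'
#' @param path YAML file
#' @return the configuration list
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  .validateRunConfig(cfg)
  cfg
}

.validateRunConfig <- function(cfg) {
  if (is.null(cfg$simulate)) {
    for (f in c("groups", "seeds"))
      if (is.null(cfg[[f]]) || !file.exists(cfg[[f]]))
        stop("configuration error: missing file for '", f, "'")
    if (is.null(cfg$species) || !length(cfg$species))
      stop("configuration error: no species entries")
    for (sp in names(cfg$species)) for (f in c("expression", "design")) {
      p <- cfg$species[[sp]][[f]]
      if (is.null(p) || !file.exists(p))
        stop("configuration error: species ", sp, " missing ", f, " file")
    }
  }
  th <- cfg$thresholds
  if (!is.null(th$r) && (th$r <= 0 || th$r >= 1))
    stop("configuration error: r threshold out of range")
  if (!is.null(th$fc) && th$fc <= 1)
    stop("configuration error: fc threshold must be > 1")
  invisible(TRUE)
}

.defaultThresholds <- function(th = NULL) {
  out <- list(fc = 2, r = 0.95, min_component = 7, alpha = 0.05,
              motif_alpha = 0.01)
  for (nm in names(th)) out[[nm]] <- th[[nm]]
  out
}

#' Run the full comparative co-expression analysis
#'
#' Orchestrates the end-to-end study: obtain per-species expression
#' (simulated or from files), infer pruned co-expression networks, build
#' Neighbors and Orthologs subnetworks from the seed list via orthology,
#' then compute the topology table, pairwise conservation table,
#' path-length histograms and motif census/enrichment tables. All result
#' tables are written as TSV under \code{outdir} together with a JSON run
#' manifest containing the configuration snapshot, package version and
#' per-file MD5 checksums; re-running with the same configuration and seed
#' reproduces identical checksums.
#'
#' @param config configuration list (see [readRunConfig()]) or path to a
#'   YAML file
#' @param outdir output directory
#' @param seed integer RNG seed (overrides \code{config$seed})
#' @return invisibly, a list with all in-memory results and the manifest
#' @export
runPipeline <- function(config, outdir, seed = NULL) {
  if (is.character(config)) config <- readRunConfig(config)
  .validateRunConfig(config)
  if (is.null(seed)) seed <- if (!is.null(config$seed)) config$seed else 1L
  th <- .defaultThresholds(config$thresholds)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- "ingest"
  res <- tryCatch({
    if (!is.null(config$simulate)) {
      args <- config$simulate
      if (!is.null(args$specs))
        args$specs <- lapply(args$specs, function(s) do.call(speciesSpec, s))
      args$seed <- seed
      world <- do.call(simulateWorld, args)
      exprs <- worldExpression(world)
      map <- worldOrthology(world)
      seeds <- worldSeeds(world)
      reference <- worldReference(world)
      writeWorld(world, file.path(outdir, "world"))
    } else {
      world <- NULL
      exprs <- lapply(config$species, function(s)
        readExpressionTSV(s$expression, s$design))
      map <- readOrthoGroups(config$groups)
      seeds <- readLines(config$seeds)
      reference <- if (!is.null(config$reference)) config$reference
                   else geneSpecies(seeds[1])
    }

    stage <- "infer"
    nets <- list()
    for (sp in names(exprs)) {
      nets[[sp]] <- inferNetwork(exprs[[sp]], fc_threshold = th$fc,
                                 r_threshold = th$r,
                                 min_component = th$min_component,
                                 species = sp)
      writeSIF(nets[[sp]], file.path(outdir, paste0(sp, "_full.sif")))
    }

    stage <- "subnetworks"
    subnets <- buildSubnetworks(nets, seeds, map, reference)
    for (sp in names(nets)) {
      writeSIF(subnets$neighbors[[sp]],
               file.path(outdir, paste0(sp, "_neighbors.sif")))
      writeSIF(subnets$orthologs[[sp]],
               file.path(outdir, paste0(sp, "_orthologs.sif")))
    }

    stage <- "topology"
    topo <- topologyTable(nets, subnets)
    write.table(topo, file.path(outdir, "topology.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    hists <- list()
    for (sp in names(nets)) for (kind in c("full", "orthologs")) {
      net <- if (kind == "full") nets[[sp]] else subnets$orthologs[[sp]]
      if (igraph::gsize(netGraph(net)) == 0) next
      h <- pathLengthDistribution(net)
      hists[[paste(sp, kind, sep = "_")]] <- h
      write.table(h, file.path(outdir, paste0(sp, "_", kind, "_paths.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }

    stage <- "conservation"
    cons <- conservationTable(nets, subnets, map, alpha = th$alpha)
    write.table(cons, file.path(outdir, "conservation.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

    stage <- "motifs"
    mot <- motifEnrichmentTable(nets, subnets, alpha = th$motif_alpha)
    write.table(mot$ratios, file.path(outdir, "motif_enrichment.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    censuses <- lapply(nets, motifCensus)
    for (sp in names(censuses))
      write.table(censuses[[sp]],
                  file.path(outdir, paste0(sp, "_motif_census.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)

    list(world = world, networks = nets, subnets = subnets,
         topology = topo, histograms = hists, conservation = cons,
         motifs = mot)
  }, error = function(e) {
    writeLines(paste("FAILED at stage:", stage, "-", conditionMessage(e)),
               file.path(outdir, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  stage <- "manifest"
  files <- sort(setdiff(list.files(outdir, recursive = TRUE),
                        "manifest.json"))
  sums <- tools::md5sum(file.path(outdir, files))
  manifest <- list(
    config = config, seed = seed, thresholds = th,
    version = as.character(utils::packageVersion("dellanet")),
    checksums = as.list(stats::setNames(unname(sums), files)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}
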