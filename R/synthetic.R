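#' @importFrom withr with_seed
#' @importFrom stats rnorm runif rbinom setNames var
#' @importFrom S4Vectors DataFrame
#' @importFrom SummarizedExperiment SummarizedExperiment
NULL

#' Describe one simulated species
#'
#' @param species_id short label used as gene-id prefix (e.g. "At")
#' @param n_genes number of genes (>= 50)
#' @param della_status \code{"ga_regulated"} (DELLA degraded via
#'   gibberellin signaling, as in angiosperms), \code{"ga_independent"}
#'   (DELLA present but GA-insensitive, as in mosses) or \code{"absent"}
#'   (no DELLA, as in green algae)
#' @param ortholog_retention probability in [0,1] that a universal gene
#'   family has a member in this species
#' @return a \code{speciesSpec} list
#' @export
speciesSpec <- function(species_id, n_genes = 500,
                        della_status = c("ga_regulated", "ga_independent",
                                         "absent"),
                        ortholog_retention = 0.7) {
  della_status <- match.arg(della_status)
  if (n_genes < 50) stop("configuration error: n_genes must be >= 50")
  if (ortholog_retention < 0 || ortholog_retention > 1)
    stop("configuration error: ortholog_retention must be in [0,1]")
  structure(list(species_id = species_id, n_genes = as.integer(n_genes),
                 della_status = della_status,
                 ortholog_retention = ortholog_retention),
            class = "speciesSpec")
}

#' Default four-species study design
#'
#' Mirrors the comparative setting of the analysis: two species with
#' GA-regulated DELLAs (high ortholog retention, like Arabidopsis and
#' tomato), one with GA-independent DELLAs (moderate retention, like
#' Physcomitrella), and one alga without DELLA (low retention, like
#' Chlamydomonas).
#'
#' @param n_genes genes per species
#' @return list of [speciesSpec()] entries
#' @export
defaultSpeciesSpecs <- function(n_genes = 500) {
  list(speciesSpec("At", n_genes, "ga_regulated", 0.75),
       speciesSpec("Sl", n_genes, "ga_regulated", 0.70),
       speciesSpec("Pp", n_genes, "ga_independent", 0.50),
       speciesSpec("Cr", n_genes, "absent", 0.30))
}

#' Simulate a multi-species co-expression world
#'
#' Generates per-species FPKM-like expression matrices with planted
#' co-expression modules, an OrthoMCL-style ortholog group map with
#' per-species phylogenetic dropout, and a curated seed (DELLA-interactor)
#' list in the reference species.
#'
#' Genes are assigned to latent modules; within a module, log-scale
#' expression is a shared per-sample latent level plus i.i.d. Gaussian
#' noise of sd \code{noise_sd}, exponentiated to an FPKM-like positive
#' scale. Each study has one control and two treatment conditions with
#' \code{samples_per_study} replicates each; every module receives a
#' planted >= 2.5-fold latent shift in at least one treatment so its genes
#' pass a fold-change-2 filter, while a fraction of species-specific
#' "flat" genes does not. Module latent profiles are redrawn until no two
#' modules correlate above 0.9, so at \code{noise_sd = 0} the inferred
#' network components are exactly the planted modules.
#'
#' DELLA regimes: designated seed modules are the largest modules; species
#' with \code{della_status = "ga_regulated"} keep seed-module family genes
#' in place with high fidelity (shuffle probability \code{seed_shuffle}
#' instead of the background \code{module_shuffle}), give them reduced
#' noise (\code{noise_sd / seed_density_multiplier}, i.e. denser planted
#' neighborhoods), and attract extra species-specific genes into seed
#' modules. Species with \code{della_status = "absent"} have the seed
#' families relocated into small modules at background density;
#' \code{"ga_independent"} species treat seed families like background
#' families.
#'
#' The same seed always reproduces a bit-identical world.
#'
#' @param specs list of [speciesSpec()] entries (>= 2 species)
#' @param n_modules number of latent modules (>= 2)
#' @param samples_per_study replicates per condition
#' @param n_studies number of studies (each: 1 control + 2 treatments)
#' @param noise_sd per-gene log-scale noise sd (>= 0)
#' @param seed integer RNG seed
#' @param n_seed_modules number of DELLA-target modules
#' @param seed_density_multiplier noise divisor for seed modules in
#'   ga_regulated species (density of planted seed neighborhoods)
#' @param module_shuffle background probability that a family's module is
#'   reassigned in a given species (lineage-specific rewiring)
#' @param seed_shuffle the same probability for seed families in
#'   ga_regulated species
#' @param n_seeds number of seed genes drawn in the reference species
#' @param p_paralog probability of a second (paralog) copy per present
#'   family per species
#' @param flat_fraction fraction of species-specific genes that are
#'   non-differential background genes
#' @param reference reference species (defaults to the first ga_regulated
#'   species)
#' @return a [SyntheticWorld-class]
#' @examples
#' w <- simulateWorld(defaultSpeciesSpecs(100), n_modules = 6, seed = 1)
#' w
#' @export
simulateWorld <- function(specs = defaultSpeciesSpecs(),
                          n_modules = 20, samples_per_study = 2,
                          n_studies = 3, noise_sd = 0.2, seed = 1,
                          n_seed_modules = 3,
                          seed_density_multiplier = 2,
                          module_shuffle = 0.35, seed_shuffle = 0.05,
                          n_seeds = 12, p_paralog = 0.05,
                          flat_fraction = 0.1, reference = NULL) {
  if (length(specs) < 2) stop("configuration error: need >= 2 species")
  if (n_modules < 2) stop("configuration error: n_modules must be >= 2")
  if (noise_sd < 0) stop("configuration error: noise_sd must be >= 0")
  if (samples_per_study < 1 || n_studies < 1)
    stop("configuration error: non-positive dimensions")
  specs <- lapply(specs, function(s)
    if (inherits(s, "speciesSpec")) s else do.call(speciesSpec, s))
  sids <- vapply(specs, `[[`, "", "species_id")
  names(specs) <- sids
  if (anyDuplicated(sids)) stop("duplicate species_id")
  status <- vapply(specs, `[[`, "", "della_status")
  if (is.null(reference)) {
    reference <- if (any(status == "ga_regulated"))
      sids[which(status == "ga_regulated")[1]] else sids[1]
  }
  with_seed(as.integer(seed), .simulateWorldImpl(
    specs, n_modules, samples_per_study, n_studies, noise_sd, seed,
    n_seed_modules, seed_density_multiplier, module_shuffle, seed_shuffle,
    n_seeds, p_paralog, flat_fraction, reference))
}

.simulateWorldImpl <- function(specs, n_modules, samples_per_study,
                               n_studies, noise_sd, seed, n_seed_modules,
                               seed_density_multiplier, module_shuffle,
                               seed_shuffle, n_seeds, p_paralog,
                               flat_fraction, reference) {
  sids <- names(specs)
  n_seed_modules <- min(n_seed_modules, n_modules - 1L)

  ## module weights; seed modules are the largest, the small pool the
  ## smallest quartile
  w <- stats::rgamma(n_modules, shape = 4, rate = 1) + 0.1
  w <- w / sum(w)
  ord <- order(w, decreasing = TRUE)
  seed_modules <- ord[seq_len(n_seed_modules)]
  small_pool <- rev(ord)[seq_len(max(1L, floor(n_modules / 4)))]
  small_pool <- setdiff(small_pool, seed_modules)
  if (!length(small_pool)) small_pool <- rev(ord)[1]

  ## universal gene families with base module assignment
  n_families <- ceiling(0.85 * max(vapply(specs, `[[`, 1L, "n_genes")))
  fam_ids <- sprintf("f%04d", seq_len(n_families))
  base_module <- sample.int(n_modules, n_families, replace = TRUE, prob = w)
  names(base_module) <- fam_ids
  seed_family <- base_module %in% seed_modules

  ## per-species realization: presence, paralogs, realized module
  genes <- list(); modules <- list(); flat <- list()
  groups_members <- setNames(vector("list", n_families), fam_ids)
  for (sp in sids) {
    st <- specs[[sp]]$della_status
    present <- as.logical(rbinom(n_families, 1, specs[[sp]]$ortholog_retention))
    mod <- base_module
    reassign <- switch(st,
      ga_regulated = ifelse(seed_family,
                            rbinom(n_families, 1, seed_shuffle),
                            rbinom(n_families, 1, module_shuffle)) == 1,
      ga_independent = ifelse(seed_family,
                              rbinom(n_families, 1,
                                     min(1, 2 * module_shuffle)),
                              rbinom(n_families, 1, module_shuffle)) == 1,
      absent = !seed_family & rbinom(n_families, 1, module_shuffle) == 1)
    mod[reassign] <- sample.int(n_modules, sum(reassign), replace = TRUE)
    if (st == "absent" && any(seed_family))
      mod[seed_family] <- sample(rep(small_pool, 2), sum(seed_family),
                                 replace = TRUE)
    has_paralog <- present & rbinom(n_families, 1, p_paralog) == 1
    # paste0() recycles zero-length arguments to "", so guard explicitly
    fam_genes <- if (any(present))
      paste0(sp, "|", fam_ids[present]) else character(0)
    fam_mods <- mod[present]
    par_genes <- if (any(has_paralog))
      paste0(sp, "|", fam_ids[has_paralog], "b") else character(0)
    par_mods <- mod[has_paralog]
    for (i in which(present))
      groups_members[[i]] <- c(groups_members[[i]],
                               paste0(sp, "|", fam_ids[i]))
    for (i in which(has_paralog))
      groups_members[[i]] <- c(groups_members[[i]],
                               paste0(sp, "|", fam_ids[i], "b"))
    ## species-specific genes fill up to n_genes
    n_fill <- specs[[sp]]$n_genes - length(fam_genes) - length(par_genes)
    if (n_fill < 0) {
      drop <- sample(seq_along(fam_genes), -n_fill)
      fam_genes <- fam_genes[-drop]; fam_mods <- fam_mods[-drop]
      n_fill <- 0
    }
    n_flat <- round(flat_fraction * n_fill)
    n_mod_fill <- n_fill - n_flat
    fill_w <- w
    if (st == "ga_regulated") fill_w[seed_modules] <- 3 * fill_w[seed_modules]
    if (st == "absent") fill_w[seed_modules] <- 0.2 * fill_w[seed_modules]
    fill_genes <- sprintf("%s|s%04d", sp, seq_len(n_fill))
    fill_mods <- c(sample.int(n_modules, n_mod_fill, replace = TRUE,
                              prob = fill_w),
                   rep(NA_integer_, n_flat))
    genes[[sp]] <- c(fam_genes, par_genes, fill_genes)
    modules[[sp]] <- setNames(c(fam_mods, par_mods, fill_mods), genes[[sp]])
    flat[[sp]] <- fill_genes[n_mod_fill + seq_len(n_flat)]
  }

  groups <- groups_members[lengths(groups_members) > 0]
  names(groups) <- sprintf("GROUP_%d", seq_along(groups))
  map <- OrthologyMap(groups, warn = FALSE)

  ## seeds: reference-species family genes realized inside seed modules
  ref_mod <- modules[[reference]]
  ref_fam <- grepl("\\|f", names(ref_mod))
  cand <- names(ref_mod)[ref_fam & !is.na(ref_mod) &
                           ref_mod %in% seed_modules]
  if (length(cand) < n_seeds) {
    warning("only ", length(cand), " seed candidates available")
    n_seeds <- length(cand)
  }
  seeds <- sort(sample(cand, n_seeds))

  ## expression per species
  exprs <- list()
  cells_per_study <- 3L  # control + 2 treatments
  n_cells <- n_studies * cells_per_study
  design <- data.frame(
    study = rep(sprintf("study%d", seq_len(n_studies)),
                each = cells_per_study * samples_per_study),
    condition = rep(rep(c("control", "trt1", "trt2"),
                        each = samples_per_study), n_studies),
    stringsAsFactors = FALSE)
  design$is_control <- design$condition == "control"
  rownames(design) <- sprintf("s%02d_%s_%s_r%d",
                              rep(seq_len(n_cells), each = samples_per_study),
                              design$study, design$condition,
                              rep(seq_len(samples_per_study), n_cells))
  cell_of_sample <- rep(seq_len(n_cells), each = samples_per_study)

  for (sp in sids) {
    lv <- .moduleLevels(n_modules, n_studies, cells_per_study)
    mods <- modules[[sp]]
    gnames <- genes[[sp]]
    n_samples <- nrow(design)
    mu <- rnorm(length(gnames), mean = 2, sd = 1)
    sd_g <- rep(noise_sd, length(gnames))
    if (specs[[sp]]$della_status == "ga_regulated")
      sd_g[!is.na(mods) & mods %in% seed_modules] <-
        noise_sd / seed_density_multiplier
    logx <- matrix(0, length(gnames), n_samples,
                   dimnames = list(gnames, rownames(design)))
    for (i in seq_along(gnames)) {
      base <- if (is.na(mods[i])) rep(0, n_samples)
              else lv[mods[i], cell_of_sample]
      eps <- if (sd_g[i] > 0) rnorm(n_samples, 0, sd_g[i]) else 0
      logx[i, ] <- mu[i] + base + eps
    }
    exprs[[sp]] <- SummarizedExperiment(
      assays = list(fpkm = exp(logx)),
      colData = DataFrame(design))
  }

  truth <- list(seed = as.integer(seed),
                base_module = base_module,
                modules = modules,
                flat_genes = flat,
                seed_modules = seed_modules,
                small_pool = small_pool,
                module_weights = w,
                seed_density_multiplier = seed_density_multiplier,
                module_shuffle = module_shuffle,
                seed_shuffle = seed_shuffle,
                noise_sd = noise_sd,
                della_status = vapply(specs, `[[`, "", "della_status"),
                ortholog_retention =
                  vapply(specs, `[[`, 1, "ortholog_retention"))

  new("SyntheticWorld", expression = exprs, orthology = map,
      seeds = seeds, reference = reference, truth = truth)
}

## per-module latent log-expression levels per (study, condition) cell;
## redrawn until no two modules' exponentiated profiles correlate > 0.9,
## and with a planted >= 2.5-fold shift in one treatment cell per module
.moduleLevels <- function(n_modules, n_studies, cells_per_study) {
  n_cells <- n_studies * cells_per_study
  draw_one <- function() {
    lv <- numeric(n_cells)
    for (st in seq_len(n_studies)) {
      base <- rnorm(1)
      idx <- (st - 1) * cells_per_study
      lv[idx + 1] <- base
      lv[idx + 2:cells_per_study] <-
        base + rnorm(cells_per_study - 1, 0, 0.8)
    }
    de_study <- sample.int(n_studies, 1)
    de_cond <- sample(2:cells_per_study, 1)
    shift <- sample(c(-1, 1), 1) * log(runif(1, 2.5, 6))
    i <- (de_study - 1) * cells_per_study + de_cond
    lv[i] <- lv[(de_study - 1) * cells_per_study + 1] + shift
    lv
  }
  lv <- t(vapply(seq_len(n_modules), function(i) draw_one(),
                 numeric(n_cells)))
  for (iter in seq_len(200)) {
    cc <- suppressWarnings(stats::cor(t(exp(lv))))
    diag(cc) <- 0
    worst <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (max(cc) <= 0.9) break
    lv[worst[2], ] <- draw_one()
  }
  lv
}

#' Simulate a scale-free (preferential attachment) network
#'
#' Barabasi-Albert-style construction: start from a complete graph on
#' \code{m + 1} nodes, then attach each new node to \code{m} distinct
#' existing nodes chosen with probability proportional to their current
#' degree. Every node therefore has degree >= m and the edge count is
#' exactly \code{choose(m + 1, 2) + (n - m - 1) * m}. Used to exercise the
#' topology and motif modules directly, without expression matrices.
#'
#' @param n number of nodes (> m)
#' @param m edges added per new node (>= 1)
#' @param seed integer RNG seed (same seed, same edge list)
#' @param species label for the resulting network
#' @return a [CoexpressionNetwork-class]
#' @examples
#' net <- simulateScaleFreeNetwork(100, 3, seed = 1)
#' summarizeTopology(net)
#' @export
simulateScaleFreeNetwork <- function(n, m, seed = 1, species = "Sim") {
  if (m < 1) stop("configuration error: m must be >= 1")
  if (n <= m) stop("configuration error: need n > m")
  with_seed(as.integer(seed), {
    deg <- integer(n)
    from <- integer(0); to <- integer(0)
    init <- seq_len(m + 1)
    for (i in init) for (j in init) if (i < j) {
      from <- c(from, i); to <- c(to, j)
    }
    deg[init] <- m
    if (n > m + 1) for (v in (m + 2):n) {
      targets <- sample(seq_len(v - 1), m, prob = deg[seq_len(v - 1)])
      from <- c(from, rep(v, m)); to <- c(to, targets)
      deg[targets] <- deg[targets] + 1L
      deg[v] <- m
    }
    ids <- sprintf("%s|g%05d", species, seq_len(n))
    g <- igraph::graph_from_edgelist(cbind(ids[from], ids[to]),
                                     directed = FALSE)
    miss <- setdiff(ids, igraph::V(g)$name)
    if (length(miss)) g <- g + igraph::vertices(miss)
    CoexpressionNetwork(igraph::simplify(g), species = species)
  })
}

#' Tiny deterministic expression example
#'
#' Six genes, two studies (control + one treatment, three replicates
#' each): two correlated module genes, two anti-correlated genes, one
#' non-differential gene and one constant gene. Used in documentation
#' examples.
#'
#' @return a \code{SummarizedExperiment}
#' @export
exampleExpressionSE <- function() {
  design <- data.frame(
    study = rep(c("study1", "study2"), each = 6),
    condition = rep(rep(c("control", "trt"), each = 3), 2),
    is_control = rep(rep(c(TRUE, FALSE), each = 3), 2))
  rownames(design) <- sprintf("s%02d", 1:12)
  base <- c(1, 1.1, 0.9, 4, 4.2, 3.9, 2, 2.1, 1.9, 6, 6.1, 5.8)
  mat <- rbind(
    "Ex|g1" = base,
    "Ex|g2" = 2 * base,
    "Ex|g3" = 10 - base,
    "Ex|g4" = 2 * (10 - base),
    "Ex|g5" = c(rep(1, 6), rep(1.1, 6)),
    "Ex|g6" = rep(3, 12))
  SummarizedExperiment(assays = list(fpkm = mat),
                       colData = DataFrame(design))
}
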