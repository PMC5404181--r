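test_that("the same seed reproduces a bit-identical world", {
  w1 <- simulateWorld(defaultSpeciesSpecs(120), n_modules = 6, seed = 42)
  w2 <- simulateWorld(defaultSpeciesSpecs(120), n_modules = 6, seed = 42)
  for (sp in names(worldExpression(w1))) {
    expect_identical(
      SummarizedExperiment::assay(worldExpression(w1)[[sp]]),
      SummarizedExperiment::assay(worldExpression(w2)[[sp]]))
  }
  expect_identical(orthoGroups(worldOrthology(w1)),
                   orthoGroups(worldOrthology(w2)))
  expect_identical(worldSeeds(w1), worldSeeds(w2))
  w3 <- simulateWorld(defaultSpeciesSpecs(120), n_modules = 6, seed = 43)
  expect_false(identical(worldSeeds(w1), worldSeeds(w3)) &&
                 identical(SummarizedExperiment::assay(
                   worldExpression(w1)[[1]]),
                   SummarizedExperiment::assay(worldExpression(w3)[[1]])))
})

test_that("simulateWorld does not disturb the caller's RNG stream", {
  withr::with_seed(99, before <- rnorm(3))
  withr::with_seed(99, {
    simulateWorld(defaultSpeciesSpecs(100), n_modules = 4, seed = 7)
    after <- rnorm(3)
  })
  expect_identical(before, after)
})

test_that("world dimensions and design follow the configuration", {
  w <- simulateWorld(defaultSpeciesSpecs(150), n_modules = 8,
                     samples_per_study = 3, n_studies = 2, seed = 2)
  ex <- worldExpression(w)
  expect_setequal(names(ex), c("At", "Sl", "Pp", "Cr"))
  for (sp in names(ex)) {
    se <- ex[[sp]]
    expect_equal(nrow(se), 150)
    # 2 studies x 3 cells x 3 replicates
    expect_equal(ncol(se), 2 * 3 * 3)
    cd <- SummarizedExperiment::colData(se)
    expect_true(all(cd$is_control == (cd$condition == "control")))
    expect_true(all(table(cd$study) == 9))
    expect_true(all(SummarizedExperiment::assay(se) > 0))
    expect_true(all(startsWith(rownames(se), paste0(sp, "|"))))
  }
  expect_equal(worldReference(w), "At")
  expect_true(all(startsWith(worldSeeds(w), "At|")))
  expect_equal(length(worldSeeds(w)), 12)
  # seeds really sit in seed modules of the reference species
  tr <- worldTruth(w)
  expect_true(all(tr$modules$At[worldSeeds(w)] %in% tr$seed_modules))
})

test_that("invalid configurations are rejected up front", {
  expect_error(speciesSpec("X", 10), "n_genes")
  expect_error(speciesSpec("X", 100, ortholog_retention = 1.2), "retention")
  expect_error(simulateWorld(defaultSpeciesSpecs(100)[1]), ">= 2 species")
  expect_error(simulateWorld(defaultSpeciesSpecs(100), n_modules = 1),
               "n_modules")
  expect_error(simulateWorld(defaultSpeciesSpecs(100), noise_sd = -1),
               "noise_sd")
})

test_that("at zero noise, same-module genes correlate exactly and
          cross-module genes stay under the correlation guard", {
  w <- simulateWorld(defaultSpeciesSpecs(100), n_modules = 5, noise_sd = 0,
                     seed = 6)
  tr <- worldTruth(w)
  mat <- SummarizedExperiment::assay(worldExpression(w)$At)
  mods <- tr$modules$At[rownames(mat)]
  cc <- suppressWarnings(stats::cor(t(log(mat))))
  for (m in unique(stats::na.omit(mods))) {
    idx <- which(mods == m)
    if (length(idx) >= 2)
      expect_true(all(abs(cc[idx, idx] - 1) < 1e-12))
  }
  # log-scale module profiles are distinct across modules
  reps <- vapply(unique(stats::na.omit(mods)),
                 function(m) which(mods == m)[1], 0L)
  off <- stats::cor(t(mat[reps, , drop = FALSE]))
  diag(off) <- 0
  expect_true(max(off) <= 0.9 + 1e-12)
})

test_that("planted modules are recovered as network components at zero noise", {
  w <- simulateWorld(defaultSpeciesSpecs(150), n_modules = 6, noise_sd = 0,
                     seed = 12)
  tr <- worldTruth(w)
  se <- worldExpression(w)$At
  net <- suppressMessages(
    inferNetwork(se, species = "At", min_component = 2))
  comp <- igraph::components(netGraph(net))$membership
  mods <- tr$modules$At[names(comp)]
  # every recovered component maps to exactly one planted module
  expect_true(all(tapply(mods, comp, function(x) length(unique(x))) == 1))
  # and non-flat module genes are recovered (modules with >= 2 members)
  tab <- table(stats::na.omit(tr$modules$At))
  big <- names(tab)[tab >= 2]
  in_net <- names(tr$modules$At)[!is.na(tr$modules$At) &
                                   tr$modules$At %in% as.integer(big)]
  expect_true(all(in_net %in% names(comp)))
})

test_that("flat genes are never selected as differential", {
  w <- simulateWorld(defaultSpeciesSpecs(200), n_modules = 8, noise_sd = 0,
                     seed = 3)
  tr <- worldTruth(w)
  for (sp in c("At", "Cr")) {
    sel <- selectDifferentialGenes(worldExpression(w)[[sp]])
    expect_length(intersect(sel, tr$flat_genes[[sp]]), 0)
    # module genes all carry a planted >= 2.5-fold shift, so they pass
    mods <- tr$modules[[sp]]
    expect_true(all(names(mods)[!is.na(mods)] %in% sel))
  }
})

test_that("ortholog groups are well-formed and paralogs are rare", {
  w <- simulateWorld(defaultSpeciesSpecs(400), seed = 9)
  map <- worldOrthology(w)
  groups <- orthoGroups(map)
  expect_true(all(grepl("^GROUP_\\d+$", names(groups))))
  genes <- unlist(groups, use.names = FALSE)
  expect_equal(anyDuplicated(genes), 0)
  # every group gene exists in its species' expression matrix
  ex <- worldExpression(w)
  for (sp in names(ex))
    expect_true(all(genes[geneSpecies(genes) == sp] %in%
                      rownames(ex[[sp]])))
  # paralog copies ("...b" suffix) occur at roughly p_paralog of members
  frac_b <- mean(grepl("b$", genes))
  expect_lt(frac_b, 0.12)
  expect_gt(frac_b, 0.005)
})
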