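test_that("there are exactly eight connected motif classes on 3-4 nodes", {
  expect_equal(length(motifClasses()), 8)
  expect_equal(anyDuplicated(motifClasses()), 0)
  # completeness check: enumerate all labelled graphs on 3 and 4 nodes and
  # collect the distinct connected isomorphism classes
  allPerms <- function(k) {
    m <- as.matrix(expand.grid(rep(list(seq_len(k)), k)))
    m <- m[apply(m, 1, function(r) length(unique(r)) == k), , drop = FALSE]
    lapply(seq_len(nrow(m)), function(i) m[i, ])
  }
  countClasses <- function(k) {
    pairs <- utils::combn(k, 2)
    perms <- allPerms(k)
    sigs <- character(0)
    for (mask in 0:(2^ncol(pairs) - 1)) {
      edges <- pairs[, bitwAnd(mask, 2^(seq_len(ncol(pairs)) - 1)) > 0,
                     drop = FALSE]
      g <- igraph::make_empty_graph(k, directed = FALSE)
      if (ncol(edges)) g <- igraph::add_edges(g, as.vector(edges))
      if (!igraph::is_connected(g)) next
      # canonical form: lexicographic minimum over all node relabellings
      A <- as.matrix(igraph::as_adjacency_matrix(g))
      sigs <- c(sigs, min(vapply(perms, function(p)
        paste(A[p, p], collapse = ""), "")))
    }
    length(unique(sigs))
  }
  expect_equal(countClasses(3), 2)
  expect_equal(countClasses(4), 6)
})

test_that("closed-form censuses: cliques, paths, cycles, stars", {
  k3 <- namedGraph(t(utils::combn(3, 2)), 3)
  c3 <- motifCensus(k3)
  expect_equal(c3$count[c3$class == "triangle"], 1)
  expect_equal(sum(c3$count), 1)

  k4 <- namedGraph(t(utils::combn(4, 2)), 4)
  c4 <- motifCensus(k4)
  got <- stats::setNames(c4$count, c4$class)
  expect_equal(got[["clique4"]], 1)
  expect_equal(got[["triangle"]], 4)   # every 3-subset of K4
  expect_equal(got[["path3"]], 0)
  expect_equal(got[["diamond4"]], 0)   # induced counting

  p4 <- namedGraph(rbind(c(1, 2), c(2, 3), c(3, 4)), 4)
  cp <- motifCensus(p4)
  gp <- stats::setNames(cp$count, cp$class)
  expect_equal(gp[["path4"]], 1)
  expect_equal(gp[["path3"]], 2)
  expect_equal(sum(cp$count), 3)

  star <- namedGraph(cbind(1, 2:4), 4)
  gs <- stats::setNames(motifCensus(star)$count, motifClasses())
  expect_equal(gs[["star4"]], 1)
  expect_equal(gs[["path3"]], 3)

  c5 <- namedGraph(cbind(1:5, c(2:5, 1)), 5)  # 5-cycle
  g5 <- stats::setNames(motifCensus(c5)$count, motifClasses())
  expect_equal(g5[["path3"]], 5)
  expect_equal(g5[["path4"]], 5)
  expect_equal(g5[["cycle4"]], 0)
})

test_that("census equals brute-force subset enumeration on random graphs", {
  for (s in 1:4) {
    g <- randomGnp(25, 0.2, seed = s)
    got <- motifCensus(g)
    oracle <- bruteForceCensus(g)
    expect_equal(stats::setNames(got$count, got$class), oracle,
                 info = paste("seed", s))
  }
  # a denser graph and a sparser one
  expect_equal(stats::setNames(motifCensus(randomGnp(18, 0.5, seed = 9))$count,
                               motifClasses()),
               bruteForceCensus(randomGnp(18, 0.5, seed = 9)))
  expect_equal(stats::setNames(motifCensus(randomGnp(40, 0.05, seed = 10))$count,
                               motifClasses()),
               bruteForceCensus(randomGnp(40, 0.05, seed = 10)))
})

test_that("3-node counts cross-check against igraph's motif machinery", {
  for (s in c(2, 6)) {
    g <- randomGnp(30, 0.15, seed = s)
    mine <- motifCensus(g)
    ig <- igraph::motifs(g, 3)  # undirected classes: last two are connected
    expect_equal(mine$count[mine$class == "path3"], ig[3])
    expect_equal(mine$count[mine$class == "triangle"], ig[4])
  }
})

test_that("count identities hold: triangles via trace, path3 via degrees", {
  g <- randomGnp(40, 0.1, seed = 13)
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  cc <- motifCensus(g)
  tri <- sum(diag(A %*% A %*% A)) / 6
  expect_equal(cc$count[cc$class == "triangle"], tri)
  # paths of length 2 = sum C(deg,2) minus 3 per triangle (induced)
  p3 <- sum(choose(rowSums(A), 2)) - 3 * tri
  expect_equal(cc$count[cc$class == "path3"], p3)
  # frequencies are counts over C(n,k)
  expect_equal(cc$frequency,
               cc$count / ifelse(cc$size == 3, choose(40, 3), choose(40, 4)))
})

test_that("sampling with probability one reproduces exact counts; fractional
          sampling is an unbiased-looking estimator", {
  g <- randomGnp(30, 0.15, seed = 17)
  exact <- motifCensus(g)
  expect_equal(motifCensus(g, sample_prob = 1)$count, exact$count)
  ests <- replicate(40, motifCensus(g, sample_prob = 0.7)$count)
  rel <- rowMeans(ests) / exact$count
  rel <- rel[is.finite(rel) & exact$count >= 20]
  expect_true(all(abs(rel - 1) < 0.25))
})

test_that("enrichment ratios are one for identical censuses and NA where the
          full network lacks the class", {
  g <- randomGnp(20, 0.25, seed = 3)
  cc <- motifCensus(g)
  er <- enrichmentRatios(cc, cc)
  expect_true(all(er$ratio[er$defined] == 1))
  full <- motifCensus(namedGraph(rbind(c(1, 2), c(2, 3), c(3, 4)), 4))
  sub <- motifCensus(namedGraph(t(utils::combn(4, 2)), 4))
  er2 <- enrichmentRatios(sub, full)
  expect_true(is.na(er2$ratio[er2$class == "clique4"]))
  expect_false(er2$defined[er2$class == "clique4"])
  # ratio arithmetic on a defined class
  expect_equal(er2$ratio[er2$class == "path3"],
               sub$frequency[sub$class == "path3"] /
                 full$frequency[full$class == "path3"])
})

test_that("ANOVA F matches the textbook between/within computation", {
  withr::with_seed(5, {
    sets <- list(A = rnorm(8, 10), B = rnorm(8, 12), C = rnorm(8, 10.5))
  })
  res <- compareEnrichment(sets, alpha = 0.05)
  expect_equal(res$anova_F, anovaFByHand(sets), tolerance = 1e-10)
  expect_equal(res$anova_p,
               stats::pf(res$anova_F, 2, 21, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("compact letters: identical groups share a letter, separated
          groups get disjoint letters", {
  withr::with_seed(7, {
    same <- list(A = rnorm(10, 5, 0.5), B = rnorm(10, 5, 0.5))
    apart <- list(A = rnorm(10, 0, 0.1), B = rnorm(10, 10, 0.1),
                  C = rnorm(10, 20, 0.1))
  })
  r1 <- compareEnrichment(same, alpha = 0.01)
  expect_equal(unname(r1$letters["A"]), unname(r1$letters["B"]))
  r2 <- compareEnrichment(apart, alpha = 0.01)
  expect_equal(anyDuplicated(unname(r2$letters)), 0)
  expect_true(all(nchar(r2$letters) == 1))
  # middle case: A ~ B, both differ from C
  withr::with_seed(8, {
    mid <- list(A = rnorm(12, 5, 0.3), B = rnorm(12, 5.1, 0.3),
                C = rnorm(12, 15, 0.3))
  })
  r3 <- compareEnrichment(mid, alpha = 0.01)
  shares <- function(x, y)
    length(intersect(strsplit(x, "")[[1]], strsplit(y, "")[[1]])) > 0
  expect_true(shares(r3$letters[["A"]], r3$letters[["B"]]))
  expect_false(shares(r3$letters[["A"]], r3$letters[["C"]]))
  expect_false(shares(r3$letters[["B"]], r3$letters[["C"]]))
})

test_that("degenerate enrichment comparisons are handled explicitly", {
  expect_error(compareEnrichment(list(A = 1:3, B = 2)), "at least 2")
  flat <- compareEnrichment(list(A = c(1, 1, 1), B = c(1, 1, 1)))
  expect_equal(flat$anova_F, 0)
  expect_equal(flat$anova_p, 1)
  expect_equal(unname(flat$letters), c("a", "a"))
  # non-finite values are dropped before testing
  withr::with_seed(3, {
    ok <- compareEnrichment(list(A = c(rnorm(5), NA, Inf), B = rnorm(5)))
  })
  expect_true(is.finite(ok$anova_F))
})
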