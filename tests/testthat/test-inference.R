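makeSE <- function(mat, study, condition, is_control) {
  colnames(mat) <- sprintf("s%02d", seq_len(ncol(mat)))
  design <- S4Vectors::DataFrame(study = study, condition = condition,
                                 is_control = is_control,
                                 row.names = colnames(mat))
  SummarizedExperiment::SummarizedExperiment(assays = list(fpkm = mat),
                                             colData = design)
}

test_that("fold-change selection is two-sided with a threshold of two", {
  mat <- rbind(
    "X|up"   = c(10, 10, 25, 25),   # FC 2.5 up -> selected
    "X|mild" = c(10, 10, 15, 15),   # FC 1.5 -> not selected
    "X|down" = c(10, 10, 4, 4),     # FC 2.5 down -> selected
    "X|edge" = c(10, 10, 20.02, 20.02)) # FC just above 2 with pseudocount
  se <- makeSE(mat, rep("study1", 4), c("control", "control", "trt", "trt"),
               c(TRUE, TRUE, FALSE, FALSE))
  sel <- selectDifferentialGenes(se, fc_threshold = 2)
  expect_setequal(sel, c("X|up", "X|down", "X|edge"))
  # the two-sided rule: max(t/c, c/t) with pseudocount 0.01
  expect_true(max(4.01 / 10.01, 10.01 / 4.01) >= 2)
})

test_that("a gene qualifies if differential in at least one study", {
  mat <- rbind("X|a" = c(10, 11, 10, 30),
               "X|b" = c(10, 11, 10, 12))
  se <- makeSE(mat, c("study1", "study1", "study2", "study2"),
               c("control", "trt", "control", "trt"),
               c(TRUE, FALSE, TRUE, FALSE))
  expect_setequal(selectDifferentialGenes(se), "X|a")
})

test_that("design validation rejects studies without controls", {
  mat <- rbind("X|a" = c(1, 2))
  se <- makeSE(mat, c("study1", "study1"), c("trt1", "trt2"), c(FALSE, FALSE))
  expect_error(selectDifferentialGenes(se), "control")
})

test_that("edges require signed correlation above threshold", {
  base <- c(1, 2, 3, 5, 8, 13)
  mat <- rbind("X|a" = base,
               "X|b" = 2 * base + 1,        # r = 1 with a
               "X|c" = 20 - base,           # r = -1 with a: no edge
               "X|d" = c(5, 5, 5, 5, 5, 5)) # zero variance: no edges
  se <- makeSE(mat, rep("study1", 6),
               c("control", "c1", "c2", "c3", "c4", "c5"),
               c(TRUE, rep(FALSE, 5)))
  net <- suppressMessages(buildNetwork(se, r_threshold = 0.95))
  g <- netGraph(net)
  expect_true(igraph::are_adjacent(g, "X|a", "X|b"))
  expect_false(igraph::are_adjacent(g, "X|a", "X|c"))
  expect_equal(igraph::degree(g)[["X|d"]], 0)
})

test_that("edge set matches a brute-force pairwise Pearson recomputation", {
  withr::with_seed(42, {
    mat <- matrix(exp(rnorm(4 * 6)), 4, 6,
                  dimnames = list(sprintf("X|g%d", 1:4), NULL))
  })
  se <- makeSE(mat, rep("study1", 6), c("control", paste0("c", 1:5)),
               c(TRUE, rep(FALSE, 5)))
  thr <- 0.2  # low threshold so the toy matrix produces edges
  net <- buildNetwork(se, r_threshold = thr)
  pearson <- function(x, y) {
    # textbook formula
    n <- length(x)
    (sum(x * y) - n * mean(x) * mean(y)) /
      sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  }
  for (i in 1:3) for (j in (i + 1):4) {
    r <- pearson(mat[i, ], mat[j, ])
    expect_equal(
      igraph::are_adjacent(netGraph(net), rownames(mat)[i], rownames(mat)[j]),
      r > thr, info = paste(i, j))
  }
})

test_that("network inference requires at least 3 samples", {
  mat <- matrix(1:4, 2, 2, dimnames = list(c("X|a", "X|b"), NULL))
  se <- makeSE(mat, c("study1", "study1"), c("control", "trt"), c(TRUE, FALSE))
  expect_error(buildNetwork(se), "3 samples")
})

test_that("edges are invariant under positive affine rescaling of a profile", {
  for (s in 1:5) {
    withr::with_seed(s, {
      mat <- matrix(exp(rnorm(6 * 8)), 6, 8,
                    dimnames = list(sprintf("X|g%d", 1:6), NULL))
      a <- runif(1, 0.1, 10); b <- runif(1, 0, 5)
    })
    se1 <- makeSE(mat, rep("study1", 8), c("control", paste0("c", 1:7)),
                  c(TRUE, rep(FALSE, 7)))
    mat2 <- mat
    mat2[1, ] <- a * mat[1, ] + b
    se2 <- makeSE(mat2, rep("study1", 8), c("control", paste0("c", 1:7)),
                  c(TRUE, rep(FALSE, 7)))
    n1 <- buildNetwork(se1, r_threshold = 0.3)
    n2 <- buildNetwork(se2, r_threshold = 0.3)
    e1 <- igraph::as_edgelist(netGraph(n1))
    e2 <- igraph::as_edgelist(netGraph(n2))
    expect_identical(e1[order(e1[, 1], e1[, 2]), , drop = FALSE],
                     e2[order(e2[, 1], e2[, 2]), , drop = FALSE])
  }
})

test_that("pruning removes small components at the documented boundary", {
  # one 7-node path + one 6-node path
  edges <- rbind(cbind(1:6, 2:7), cbind(8:12, 9:13))
  g <- namedGraph(edges, 13)
  net <- CoexpressionNetwork(g, "T")
  pruned <- pruneNetwork(net, min_component = 7)
  expect_equal(igraph::gorder(netGraph(pruned)), 7)
  comp <- igraph::components(netGraph(pruned))
  expect_true(all(comp$csize >= 7))
})

test_that("a graph of only self-loops prunes to an empty network", {
  g <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(g)$name <- paste0("T|g", 1:3)
  g <- igraph::add_edges(g, c("T|g1", "T|g1", "T|g2", "T|g2"))
  pruned <- pruneNetwork(g)  # raw graph: loops stripped, nodes then pruned
  expect_equal(igraph::gorder(netGraph(pruned)), 0)
  # the network class itself refuses non-simple graphs
  expect_error(CoexpressionNetwork(g, "T"), "simple")
})

test_that("pruning is idempotent and matches independent component labelling", {
  g <- randomGnp(100, 0.02, seed = 7)
  p1 <- pruneNetwork(CoexpressionNetwork(g, "T"), min_component = 7)
  p2 <- pruneNetwork(p1, min_component = 7)
  expect_identical(sort(netNodes(p1)), sort(netNodes(p2)))
  expect_equal(igraph::gsize(netGraph(p1)), igraph::gsize(netGraph(p2)))
  # brute-force component labelling by BFS
  n <- igraph::gorder(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (r in seq_len(nrow(el))) {
    adj[[el[r, 1]]] <- c(adj[[el[r, 1]]], el[r, 2])
    adj[[el[r, 2]]] <- c(adj[[el[r, 2]]], el[r, 1])
  }
  lab <- rep(NA_integer_, n); cur <- 0L
  for (i in seq_len(n)) if (is.na(lab[i])) {
    cur <- cur + 1L
    members <- which(!is.na(bfsFrom(adj, i)))
    lab[members] <- cur
  }
  sizes <- table(lab)
  keep <- names(igraph::V(g))[lab %in% as.integer(names(sizes)[sizes >= 7])]
  expect_setequal(netNodes(p1), igraph::V(g)$name[lab %in%
    as.integer(names(sizes)[sizes >= 7])])
})

test_that("proteome filtering removes unlisted nodes before component pruning", {
  edges <- cbind(1:7, c(2:7, 1))  # 7-cycle
  g <- namedGraph(edges, 7)
  net <- CoexpressionNetwork(g, "T")
  pruned <- suppressMessages(
    pruneNetwork(net, min_component = 3, proteome = netNodes(net)[1:5]))
  expect_setequal(netNodes(pruned), netNodes(net)[1:5])
})
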