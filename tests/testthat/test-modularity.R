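pathNet <- makeNet(c("b", "b", "d"), c("a", "c", "c"))  # path a-b-c-d

test_that("modularity of reference partitions matches direct evaluation", {
  # all nodes in one community
  memb1 <- setNames(rep(1L, 4), c("a", "c", "b", "d"))
  expect_equal(modularityScore(pathNet, memb1), 0)
  # two disconnected equal components split by component
  two <- makeNet(c("v1", "v2"), c("p1", "p2"))
  memb2 <- c(p1 = 1L, p2 = 2L, v1 = 1L, v2 = 2L)
  expect_equal(modularityScore(two, memb2), 0.5)
  # 4-node path split in the middle: direct evaluation of the Q sum
  membP <- c(a = 1L, b = 1L, c = 2L, d = 2L)
  expect_equal(modularityScore(pathNet, membP, weighted = FALSE), 1 / 6)
  expect_error(modularityScore(pathNet, c(a = 1L)), "cover every node")
})

test_that("modularity matches the brute-force Q sum on small random graphs", {
  for (seed in 1:10) {
    e <- randomEdges(sample(2:4, 1), sample(2:4, 1), p = 0.6, seed = seed)
    net <- buildNetwork(e)
    labels <- c(pathogenNodes(net), vectorNodes(net))
    n <- length(labels)
    set.seed(seed + 100)
    memb <- setNames(sample.int(min(3L, n), n, replace = TRUE), labels)
    for (weighted in c(TRUE, FALSE)) {
      A <- matrix(0, n, n, dimnames = list(labels, labels))
      et <- edgeTable(net)
      w <- if (weighted) et$score else rep(1, nrow(et))
      A[cbind(match(et$pathogen, labels), match(et$vector, labels))] <- w
      A <- A + t(A)
      expect_equal(modularityScore(net, memb, weighted = weighted),
                   bruteModularity(A, memb[labels]), tolerance = 1e-12)
    }
  }
})

test_that("weighted modularity matches igraph on a random partition", {
  e <- randomEdges(5, 7, p = 0.4, seed = 3)
  net <- buildNetwork(e)
  g <- asIgraph(net)
  labels <- igraph::V(g)$name
  set.seed(42)
  memb <- setNames(sample.int(3, length(labels), replace = TRUE), labels)
  expect_equal(modularityScore(net, memb, weighted = TRUE),
               igraph::modularity(g, memb[labels],
                                  weights = igraph::E(g)$weight))
})

test_that("louvain finds components of disconnected cliques with Q = 0.5", {
  e1 <- expand.grid(vector = paste0("v", 1:3), pathogen = paste0("p", 1:3),
                    stringsAsFactors = FALSE)
  e2 <- expand.grid(vector = paste0("w", 1:3), pathogen = paste0("q", 1:3),
                    stringsAsFactors = FALSE)
  e <- rbind(e1, e2)
  e$score <- 1L
  lv <- louvainCommunities(buildNetwork(e), seed = 1)
  expect_equal(lv$nCommunities, 2L)
  expect_equal(lv$modularity, 0.5)
  memb <- lv$membership
  expect_length(unique(memb[c(paste0("p", 1:3), paste0("v", 1:3))]), 1L)
  expect_length(unique(memb[c(paste0("q", 1:3), paste0("w", 1:3))]), 1L)
})

test_that("louvain merges a single edge into one community", {
  lv <- louvainCommunities(makeNet("v", "p"), seed = 1)
  expect_equal(lv$nCommunities, 1L)
})

test_that("louvain is deterministic given seed and improves on singletons", {
  net <- buildNetwork(randomEdges(6, 9, p = 0.35, seed = 8))
  a <- louvainCommunities(net, seed = 7, nRestarts = 3)
  b <- louvainCommunities(net, seed = 7, nRestarts = 3)
  expect_identical(a, b)
  labels <- c(pathogenNodes(net), vectorNodes(net))
  singles <- setNames(seq_along(labels), labels)
  expect_gte(a$modularity, modularityScore(net, singles))
  # Q is non-decreasing in the number of restarts
  qs <- vapply(1:4, function(r) {
    louvainCommunities(net, seed = 7, nRestarts = r)$modularity
  }, numeric(1))
  expect_true(all(diff(qs) >= -1e-12))
})

test_that("louvain recovers well-separated planted clusters (small)", {
  p <- synthParams(nPathogens = 12, nVectors = 24, nClusters = 2,
                   pIn = 1, pOut = 0, hubFraction = 0, knownFraction = 0,
                   seed = 5)
  truth <- groundTruth(p)
  net <- buildNetwork(scoreEvidence(generateEvidence(p)))
  # unweighted: the planted signal is topological, edge scores are noise
  lv <- louvainCommunities(net, weighted = FALSE, seed = 1)
  planted <- c(truth$pathogenCluster, truth$vectorCluster)
  common <- names(lv$membership)
  expect_equal(
    mclust::adjustedRandIndex(lv$membership[common], planted[common]), 1)
})
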