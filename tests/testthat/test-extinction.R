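test_that("targeted removal order puts hubs first and obeys tie-breaks", {
  # hub vector h touches 3 pathogens, v1/v2 one each
  e <- data.frame(vector = c("h", "h", "h", "v1", "v2"),
                  pathogen = c("p1", "p2", "p3", "p1", "p2"), score = 1L)
  net <- buildNetwork(e)
  b <- betweennessCentrality(net)
  ord <- removalOrder(net, "targeted", bci = b)
  expect_equal(ord[1], "h")
  # all-zero BCI falls back to degree order, then name
  zero <- setNames(rep(0, 3), c("h", "v1", "v2"))
  expect_equal(removalOrder(net, "targeted", bci = zero), c("h", "v1", "v2"))
  expect_equal(removalOrder(net, "targeted", orderMetric = "degree"),
               c("h", "v1", "v2"))
  expect_error(removalOrder(net, "targeted", bci = zero[1:2]), "every vector")
})

test_that("random removal order is a seeded permutation", {
  net <- buildNetwork(randomEdges(4, 6, seed = 2))
  o1 <- removalOrder(net, "random", seed = 99)
  o2 <- removalOrder(net, "random", seed = 99)
  expect_identical(o1, o2)
  expect_setequal(o1, vectorNodes(net))
  expect_error(removalOrder(net, "random"), "seed")
})

test_that("extinction curves on reference topologies are exact", {
  # 1 vector x 1 pathogen
  c1 <- simulateExtinction(makeNet("v", "p"), "v")
  expect_equal(c1@points$y, c(1, 0))
  expect_equal(curveBreakPoint(c1), 1L)
  expect_equal(curveRobustness(c1), 0.5)
  # complete bipartite 3 vectors x 2 pathogens: survival until the last
  cb <- makeNet(rep(c("a", "b", "c"), 2), rep(c("P1", "P2"), each = 3))
  c2 <- simulateExtinction(cb, c("b", "a", "c"))
  expect_equal(c2@points$y, c(1, 1, 1, 0))
  expect_equal(curveBreakPoint(c2), 3L)
  expect_equal(curveRobustness(c2), (2 / 3) + (1 / 3) / 2)
  # perfect matching n = 4: one extinction per removal, straight line
  pm <- makeNet(paste0("v", 1:4), paste0("p", 1:4))
  c3 <- simulateExtinction(pm, paste0("v", c(3, 1, 4, 2)))
  expect_equal(c3@points$y, c(1, .75, .5, .25, 0))
  expect_equal(curveRobustness(c3), 0.5)
  expect_error(simulateExtinction(pm, paste0("v", c(1, 1, 2, 3))),
               "permutation")
})

test_that("simulated curves match literal stepwise removal", {
  for (seed in 1:6) {
    e <- randomEdges(sample(3:6, 1), sample(3:6, 1), p = 0.45,
                     seed = seed + 40)
    e <- e[!duplicated(e[, c("vector", "pathogen")]), ]
    net <- buildNetwork(e)
    ord <- removalOrder(net, "random", seed = seed)
    crv <- simulateExtinction(net, ord)
    expect_equal(crv@points$y, stepwiseCurve(edgeTable(net), ord))
    expect_true(all(diff(crv@points$y) <= 1e-12))   # non-increasing
    V <- nVectors(net)
    expect_gte(curveRobustness(crv), 1 / (2 * V))
    expect_lte(curveRobustness(crv), 1 - 1 / (2 * V))
  }
})

test_that("monte carlo aggregates match exact enumeration on toy networks", {
  # pathogen A held by both vectors, B by vector 1 only -> mean break 1.5
  e <- data.frame(vector = c("v1", "v2", "v1"),
                  pathogen = c("A", "A", "B"), score = 1L)
  net <- buildNetwork(e)
  exact <- exhaustiveExtinction(edgeTable(net))
  expect_equal(exact$breakPoint, 1.5)
  mc <- monteCarloExtinction(net, "random", replicates = 400, seed = 1)
  se <- mc@breakPointSd / sqrt(mc@replicates)
  expect_lt(abs(mc@breakPoint - exact$breakPoint), 3 * se + 1e-9)
  # 1 x 1 network: break point exactly 1 whatever the replicates
  mc1 <- monteCarloExtinction(makeNet("v", "p"), "random", replicates = 5,
                              seed = 2)
  expect_equal(mc1@breakPoint, 1)
  expect_equal(mc1@robustness, 0.5)
})

test_that("targeted policy is deterministic with a single replicate", {
  e <- randomEdges(4, 6, p = 0.5, seed = 13)
  net <- buildNetwork(e)
  b <- betweennessCentrality(net)
  res <- monteCarloExtinction(net, "targeted", replicates = 50, bci = b)
  expect_equal(res@replicates, 1L)
  ord <- removalOrder(net, "targeted", bci = b)
  crv <- simulateExtinction(net, ord)
  expect_equal(res@robustness, curveRobustness(crv))
  expect_equal(res@breakPoint, as.numeric(curveBreakPoint(crv)))
  expect_equal(res@curve$yMean, crv@points$y)
})

test_that("adaptive re-ranking removes the currently best-connected vector", {
  # v1 degree 3; after removing v1, v3 (degree 2) outranks v2 by degree
  e <- data.frame(vector = c("v1", "v1", "v1", "v2", "v3", "v3"),
                  pathogen = c("p1", "p2", "p3", "p1", "p2", "p3"),
                  score = 1L)
  net <- buildNetwork(e)
  res <- monteCarloExtinction(net, "targeted", orderMetric = "degree",
                              recompute = TRUE)
  expect_s4_class(res, "RobustnessResult")
  expect_equal(res@replicates, 1L)
})

test_that("adding a redundant vector to every pathogen never hurts robustness", {
  for (seed in c(3, 15)) {
    e <- randomEdges(4, 5, p = 0.45, seed = seed)
    e <- e[!duplicated(e[, c("vector", "pathogen")]), ]
    net <- buildNetwork(e)
    extra <- data.frame(vector = "omni", pathogen = pathogenNodes(net),
                        score = 1L)
    net2 <- buildNetwork(rbind(edgeTable(net), extra))
    exact <- exhaustiveExtinction(edgeTable(net))
    exact2 <- exhaustiveExtinction(edgeTable(net2))
    expect_gte(exact2$robustness, exact$robustness - 1e-12)
  }
})
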