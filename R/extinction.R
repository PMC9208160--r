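#' Vector removal order for extinction simulations
#'
#' Produces the sequence in which vectors are removed from the network.
#' `policy = "random"` draws a seeded uniform permutation of all vectors.
#' `policy = "targeted"` removes the most connected vectors first: sorted
#' by the chosen metric descending (BCI values supplied via `bci`, or node
#' degree), with ties broken by degree descending and then by name
#' ascending. The targeted order is computed once on the intact network —
#' the static attack studied by the extinction analysis; adaptive
#' re-ranking is available in [monteCarloExtinction()] via `recompute`.
#'
#' @param net a [BipartiteNetwork][BipartiteNetwork-class].
#' @param policy `"random"` or `"targeted"`.
#' @param seed integer seed, required for `policy = "random"`.
#' @param orderMetric `"bci"` or `"degree"` (targeted only).
#' @param bci named numeric of betweenness values covering every vector
#'   (required when `orderMetric = "bci"`), e.g. from
#'   [betweennessCentrality()].
#' @return character vector: a permutation of `vectorNodes(net)`.
#' @export
removalOrder <- function(net, policy = c("targeted", "random"), seed = NULL,
                         orderMetric = c("bci", "degree"), bci = NULL) {
  policy <- match.arg(policy)
  vecs <- vectorNodes(net)
  if (policy == "random") {
    if (is.null(seed)) stop("random removal requires a seed", call. = FALSE)
    return(.withSeed(as.integer(seed), sample(vecs)))
  }
  orderMetric <- match.arg(orderMetric)
  deg <- nodeDegree(net, vecs)
  metric <- if (orderMetric == "degree") {
    as.numeric(deg)
  } else {
    if (is.null(bci) || !all(vecs %in% names(bci))) {
      stop("targeted removal by BCI requires bci values for every vector",
           call. = FALSE)
    }
    as.numeric(bci[vecs])
  }
  vecs[order(-metric, -as.numeric(deg), vecs)]
}

#' Simulate secondary pathogen extinctions along a removal order
#'
#' Removes the network's vectors one by one in the given order and tracks
#' the proportion of pathogens that still have at least one surviving
#' vector after each removal. A pathogen goes secondarily extinct exactly
#' when its last associated vector is removed; pathogens are never removed
#' directly (the vector-pathogen network is asymmetrical — only vectors
#' are attacked).
#'
#' @param net a [BipartiteNetwork][BipartiteNetwork-class].
#' @param order character: a permutation of all vector nodes.
#' @return an [ExtinctionCurve][ExtinctionCurve-class].
#' @export
#' @examples
#' pairs <- data.frame(vector = c("v1", "v2", "v3"),
#'                     pathogen = c("p1", "p1", "p1"), score = rep(1L, 3))
#' net <- buildNetwork(pairs)
#' crv <- simulateExtinction(net, c("v1", "v2", "v3"))
#' curveRobustness(crv)
simulateExtinction <- function(net, order) {
  vecs <- vectorNodes(net)
  if (length(order) != length(vecs) || !setequal(order, vecs) ||
      anyDuplicated(order)) {
    stop("order must be a permutation of all vector nodes", call. = FALSE)
  }
  V <- length(vecs)
  P <- nPathogens(net)
  pos <- setNames(seq_len(V), order)           # removal step of each vector
  e <- edgeTable(net)
  # a pathogen dies at the step its last vector is removed
  extinctAt <- vapply(split(pos[e$vector], e$pathogen), max, numeric(1))
  deaths <- tabulate(extinctAt, nbins = V)     # extinctions per step
  y <- (P - cumsum(c(0, deaths))) / P
  new("ExtinctionCurve",
      points = data.frame(k = 0:V, x = (0:V) / V, y = y),
      V = as.integer(V), P = as.integer(P))
}

#' Robustness and break point of an extinction curve
#'
#' `curveRobustness()` is the area under the extinction curve by the
#' trapezoidal rule on the uniform grid `x = k/V`, between 0 (fragile: the
#' first removals already strip pathogens of all their vectors) and 1
#' (resilient). `curveBreakPoint()` is the number of removals at the first
#' secondary extinction — the point where the network "breaks".
#'
#' @param curve an [ExtinctionCurve][ExtinctionCurve-class].
#' @return a numeric robustness in \[0, 1\], or an integer break point in
#'   `1..V`.
#' @export
curveRobustness <- function(curve) {
  stopifnot(is(curve, "ExtinctionCurve"))
  y <- curve@points$y
  sum((y[-1] + y[-length(y)]) / 2) / curve@V
}

#' @rdname curveRobustness
#' @export
curveBreakPoint <- function(curve) {
  stopifnot(is(curve, "ExtinctionCurve"))
  p <- curve@points
  as.integer(p$k[which(p$y < 1 - 1e-12)[1]])
}

# Adaptive most-connected-first order: re-rank surviving vectors after each
# removal. Metric "degree" is cheap; "bci" recomputes Brandes each step.
.adaptiveOrder <- function(net, orderMetric) {
  out <- character(0)
  cur <- net
  while (nVectors(cur) > 0L) {
    vecs <- vectorNodes(cur)
    deg <- nodeDegree(cur, vecs)
    metric <- if (orderMetric == "bci" && nPathogens(cur) + length(vecs) >= 3L) {
      b <- betweennessCentrality(cur)
      as.numeric(b[vecs])
    } else {
      as.numeric(deg)
    }
    pick <- vecs[order(-metric, -as.numeric(deg), vecs)][1]
    out <- c(out, pick)
    if (nVectors(cur) == 1L) break
    cur <- removeVector(cur, pick)
  }
  out
}

#' Monte-Carlo extinction experiment
#'
#' Runs [simulateExtinction()] over many removal orders and aggregates the
#' result. For `policy = "random"`, `replicates` independent seeded
#' permutations are drawn (replicate r uses seed `seed + r - 1`) and the
#' mean and standard deviation of the per-replicate robustness and break
#' point are reported, together with the pointwise-mean curve and the area
#' under that mean curve. For `policy = "targeted"` the order is
#' deterministic, so `replicates` is forced to 1; with `recompute = TRUE`
#' the most-connected-first ranking is recomputed on the surviving network
#' after every removal instead of once up front.
#'
#' @param net a [BipartiteNetwork][BipartiteNetwork-class].
#' @param policy `"random"` or `"targeted"`.
#' @param replicates number of random replicates (default 1000).
#' @param seed integer root seed.
#' @param orderMetric,bci passed to [removalOrder()] for targeted attacks.
#' @param recompute logical; adaptive re-ranking for targeted attacks.
#' @return a [RobustnessResult][RobustnessResult-class].
#' @export
monteCarloExtinction <- function(net, policy = c("random", "targeted"),
                                 replicates = 1000L, seed = 1L,
                                 orderMetric = c("bci", "degree"),
                                 bci = NULL, recompute = FALSE) {
  policy <- match.arg(policy)
  orderMetric <- match.arg(orderMetric)
  V <- nVectors(net)
  if (policy == "targeted") {
    replicates <- 1L
    order <- if (recompute) {
      .adaptiveOrder(net, orderMetric)
    } else {
      if (orderMetric == "bci" && is.null(bci)) bci <- betweennessCentrality(net)
      removalOrder(net, "targeted", orderMetric = orderMetric, bci = bci)
    }
    orders <- list(order)
  } else {
    stopifnot(replicates >= 1L)
    orders <- lapply(seq_len(replicates), function(r) {
      removalOrder(net, "random", seed = as.integer(seed) + r - 1L)
    })
  }
  ys <- matrix(NA_real_, length(orders), V + 1L)
  rob <- bp <- numeric(length(orders))
  for (i in seq_along(orders)) {
    crv <- simulateExtinction(net, orders[[i]])
    ys[i, ] <- crv@points$y
    rob[i] <- curveRobustness(crv)
    bp[i] <- curveBreakPoint(crv)
  }
  yMean <- colMeans(ys)
  ySd <- if (nrow(ys) > 1L) apply(ys, 2, sd) else rep(0, V + 1L)
  new("RobustnessResult",
      robustness = mean(rob),
      robustnessSd = if (length(rob) > 1L) sd(rob) else 0,
      robustnessMeanCurve = sum((yMean[-1] + yMean[-length(yMean)]) / 2) / V,
      breakPoint = mean(bp),
      breakPointSd = if (length(bp) > 1L) sd(bp) else 0,
      replicates = as.integer(length(orders)),
      policy = policy,
      curve = data.frame(k = 0:V, x = (0:V) / V, yMean = yMean, ySd = ySd))
}
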