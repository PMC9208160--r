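#' Parameters of the synthetic evidence generator
#'
#' Bundles and validates the parameters of the planted-partition bipartite
#' generator ([generateEvidence()]). The defaults emulate the shape of the
#' curated global mosquito-pathogen dataset: 78 pathogens and 331 vectors
#' in 11 clusters, within/between-cluster edge probabilities in a 20:1
#' ratio solved so that the expected edge count is 894, 10 hub vectors
#' (3%) with a 4-fold edge-probability boost playing the role of the
#' generalist species, and a 108/894 chance that an edge carries
#' known-vector status. Non-known edges draw their 1-4 score from
#' `scoreDistribution`.
#'
#' @param nPathogens,nVectors node counts per mode.
#' @param nClusters number of planted clusters (at most
#'   `min(nPathogens, nVectors)`).
#' @param pIn,pOut within- and between-cluster edge probabilities.
#' @param hubFraction fraction of vectors designated hubs.
#' @param hubBoost multiplier on a hub's edge probabilities (capped at 1).
#' @param knownFraction probability that an edge is a known-vector edge.
#' @param scoreDistribution probabilities over scores 1-4 for non-known
#'   edges; must sum to 1.
#' @param seed integer RNG seed; the whole draw is deterministic given it.
#' @return a validated list of class `synthParams`.
#' @export
#' @examples
#' p <- synthParams(nPathogens = 10, nVectors = 30, nClusters = 3, seed = 7)
#' head(generateEvidence(p))
synthParams <- function(nPathogens = 78L, nVectors = 331L, nClusters = 11L,
                        pIn = 0.23284, pOut = 0.011642,
                        hubFraction = 10 / 331, hubBoost = 4,
                        knownFraction = 108 / 894,
                        scoreDistribution = c(0.45, 0.25, 0.20, 0.10),
                        seed = 1L) {
  p <- list(nPathogens = as.integer(nPathogens), nVectors = as.integer(nVectors),
            nClusters = as.integer(nClusters), pIn = pIn, pOut = pOut,
            hubFraction = hubFraction, hubBoost = hubBoost,
            knownFraction = knownFraction,
            scoreDistribution = scoreDistribution, seed = as.integer(seed))
  stopifnot(
    p$nPathogens >= 1L, p$nVectors >= 1L,
    p$nClusters >= 1L, p$nClusters <= min(p$nPathogens, p$nVectors),
    p$pIn >= 0, p$pIn <= 1, p$pOut >= 0, p$pOut <= 1,
    p$hubFraction >= 0, p$hubFraction <= 1, p$hubBoost >= 1,
    p$knownFraction >= 0, p$knownFraction <= 1,
    length(p$scoreDistribution) == 4L, all(p$scoreDistribution >= 0),
    abs(sum(p$scoreDistribution) - 1) < 1e-8
  )
  if (p$pIn == 0 && p$pOut == 0) stop("expected edge count is zero", call. = FALSE)
  class(p) <- "synthParams"
  p
}

# Cluster assignments and hub choice; drawn first under the seed so that
# generateEvidence() and groundTruth() agree.
.synthLayout <- function(params) {
  pathogens <- sprintf("P%0*d", nchar(params$nPathogens), seq_len(params$nPathogens))
  vectors <- sprintf("V%0*d", nchar(params$nVectors), seq_len(params$nVectors))
  pc <- setNames(sample.int(params$nClusters, params$nPathogens, replace = TRUE),
                 pathogens)
  vc <- setNames(sample.int(params$nClusters, params$nVectors, replace = TRUE),
                 vectors)
  nHubs <- round(params$hubFraction * params$nVectors)
  hubs <- if (nHubs > 0) sort(sample(vectors, nHubs)) else character(0)
  list(pathogens = pathogens, vectors = vectors,
       pathogenCluster = pc, vectorCluster = vc, hubs = hubs)
}

# Minimal evidence-record sets realizing each score; where two routes give
# the same maximum score one is picked at random, keeping the generator
# honest against the scoring rules instead of emitting scores directly.
.realizations <- list(
  `1` = list("lab_infection", "wild_infection"),
  `2` = list("lab_dissemination", c("lab_infection", "wild_infection")),
  `3` = list("lab_transmission", c("lab_dissemination", "wild_infection")),
  `4` = list(c("lab_transmission", "wild_infection")),
  `5` = list("known_vector")
)

#' Generate a synthetic evidence table with planted structure
#'
#' Samples a sparse bipartite vector-pathogen network with planted
#' community structure and hub vectors, then emits, for every sampled
#' edge, a minimal set of literature evidence records whose score under
#' [scorePair()] equals the drawn edge score — the generator is honest
#' against the scoring rules rather than emitting scores directly.
#'
#' Pathogens and vectors are assigned uniformly to `nClusters` clusters;
#' each vector-pathogen edge is drawn Bernoulli with probability `pIn`
#' within a cluster and `pOut` between, multiplied by `hubBoost` (capped
#' at 1) for hub vectors. Every pathogen is guaranteed at least one edge
#' by forced attachment to a random in-cluster (else any) vector. Each
#' edge is a known-vector edge with probability `knownFraction` (score 5),
#' otherwise its score is drawn from `scoreDistribution`. Fully
#' deterministic given `params$seed`.
#'
#' @param params a [synthParams()] object.
#' @return evidence data.frame (`vector`, `pathogen`, `evidence`), one row
#'   per record, ready for [scoreEvidence()].
#' @export
generateEvidence <- function(params) {
  stopifnot(inherits(params, "synthParams"))
  .withSeed(params$seed, {
    lay <- .synthLayout(params)
    prob <- matrix(params$pOut, params$nPathogens, params$nVectors,
                   dimnames = list(lay$pathogens, lay$vectors))
    same <- outer(lay$pathogenCluster, lay$vectorCluster, "==")
    prob[same] <- params$pIn
    prob[, lay$hubs] <- pmin(1, prob[, lay$hubs, drop = FALSE] * params$hubBoost)
    edge <- matrix(runif(length(prob)) < prob, nrow(prob), ncol(prob),
                   dimnames = dimnames(prob))
    # forced attachment: no pathogen may be left without a vector
    for (p in which(rowSums(edge) == 0L)) {
      inCl <- which(lay$vectorCluster == lay$pathogenCluster[p])
      pool <- if (length(inCl)) inCl else seq_len(params$nVectors)
      edge[p, pool[sample.int(length(pool), 1L)]] <- TRUE
    }
    idx <- which(edge, arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    nE <- nrow(idx)
    known <- runif(nE) < params$knownFraction
    score <- ifelse(known, 5L,
                    sample.int(4L, nE, replace = TRUE,
                               prob = params$scoreDistribution))
    recs <- lapply(seq_len(nE), function(i) {
      opts <- .realizations[[score[i]]]
      cats <- opts[[sample.int(length(opts), 1L)]]
      data.frame(vector = lay$vectors[idx[i, 2]],
                 pathogen = lay$pathogens[idx[i, 1]],
                 evidence = cats)
    })
    out <- do.call(rbind, recs)
    rownames(out) <- NULL
    out
  })
}

#' Planted ground truth of a synthetic draw
#'
#' Returns the cluster labels and hub list that [generateEvidence()] uses
#' under the same `params` (identical seed, identical layout), enabling
#' community-recovery and hub-centrality tests against known truth.
#'
#' @param params a [synthParams()] object.
#' @return list with `pathogenCluster` and `vectorCluster` (named integer
#'   vectors of planted labels) and `hubs` (character).
#' @export
groundTruth <- function(params) {
  stopifnot(inherits(params, "synthParams"))
  .withSeed(params$seed, .synthLayout(params))
}
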