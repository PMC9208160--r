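# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# One Louvain local-moving phase on a dense symmetric adjacency matrix
# (diagonal stores twice the collapsed internal weight), starting from the
# given community assignment. Returns the assignment (integers, not
# necessarily contiguous).
.louvainLocalMove <- function(A, init = seq_len(nrow(A))) {
  n <- nrow(A)
  m2 <- sum(A)
  k <- rowSums(A)
  comm <- init
  sumTot <- numeric(max(n, max(comm)))   # total degree per community id
  agg <- tapply(k, comm, sum)
  sumTot[as.integer(names(agg))] <- agg
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (i in sample.int(n)) {
      ci <- comm[i]
      wRow <- A[i, ]
      neigh <- which(wRow > 0 & seq_len(n) != i)
      cand <- unique(c(ci, comm[neigh]))
      # links from i to each candidate community (excluding i itself)
      kiIn <- vapply(cand, function(c) sum(wRow[comm == c & seq_len(n) != i]),
                     numeric(1))
      # remove i from its community before comparing
      tot <- sumTot[cand] - ifelse(cand == ci, k[i], 0)
      gain <- kiIn - k[i] * tot / m2
      # ties: largest gain, then lowest community id
      best <- cand[order(-gain, cand)][1]
      if (best != ci && gain[match(best, cand)] > gain[match(ci, cand)] + 1e-12) {
        sumTot[ci] <- sumTot[ci] - k[i]
        sumTot[best] <- sumTot[best] + k[i]
        comm[i] <- best
        improved <- TRUE
      }
    }
  }
  comm
}

# Aggregate the graph by communities; the diagonal of the community graph
# becomes twice the collapsed internal weight.
.aggregateGraph <- function(A, remap) {
  C <- matrix(0, nrow(A), max(remap))
  C[cbind(seq_len(nrow(A)), remap)] <- 1
  t(C) %*% A %*% C
}

# One full Louvain run with iterated node-level refinement: the standard
# local-moving + aggregation hierarchy, then local moving again on the
# original graph initialized from the solution, repeated until modularity
# stops improving. Returns contiguous community ids per node.
.louvainOnce <- function(A0) {
  n0 <- nrow(A0)
  m2 <- sum(A0)
  k0 <- rowSums(A0)
  qOf <- function(comm) {
    q <- 0
    for (g in split(seq_len(n0), comm)) {
      q <- q + sum(A0[g, g, drop = FALSE]) / m2 - (sum(k0[g]) / m2)^2
    }
    q
  }
  nodeComm <- seq_len(n0)
  qPrev <- -Inf
  repeat {
    # refine at the level of original nodes, then rebuild the hierarchy
    nodeComm <- .louvainLocalMove(A0, nodeComm)
    nodeComm <- match(nodeComm, sort(unique(nodeComm)))
    A <- .aggregateGraph(A0, nodeComm)
    while (nrow(A) > 1L) {
      comm <- .louvainLocalMove(A)
      ids <- sort(unique(comm))
      if (length(ids) == nrow(A)) break
      remap <- match(comm, ids)
      nodeComm <- remap[nodeComm]
      A <- .aggregateGraph(A, remap)
    }
    q <- qOf(nodeComm)
    if (q <= qPrev + 1e-12) break
    qPrev <- q
  }
  match(nodeComm, unique(nodeComm))
}

#' Louvain community detection on the vector-pathogen network
#'
#' Standard two-phase Louvain (greedy local moving followed by graph
#' aggregation, resolution 1) maximising Newman-Girvan modularity on the
#' two-mode graph treated as a plain undirected graph, weighted by the 1-5
#' evidence scores by default. Node visit order is shuffled by a seeded
#' RNG; the best of `nRestarts` independent restarts (seeds `seed`,
#' `seed + 1`, ...) by modularity is returned, so results are
#' deterministic given `(seed, nRestarts)` and the achieved Q is
#' non-decreasing in `nRestarts`. Ties during local moves are broken by
#' largest modularity gain, then lowest community id.
#'
#' @param net a [BipartiteNetwork][BipartiteNetwork-class].
#' @param weighted logical; use evidence scores as edge weights.
#' @param seed integer RNG seed.
#' @param nRestarts number of independent restarts.
#' @return list with `membership` (named integer vector, community ids
#'   contiguous from 1), `modularity` (Q of the returned partition) and
#'   `nCommunities`.
#' @export
#' @examples
#' pairs <- data.frame(vector = c("v1", "v2"), pathogen = c("p1", "p2"),
#'                     score = c(1L, 1L))
#' louvainCommunities(buildNetwork(pairs), seed = 1)$nCommunities  # 2
louvainCommunities <- function(net, weighted = TRUE, seed = 1L, nRestarts = 10L) {
  stopifnot(is(net, "BipartiteNetwork"), nRestarts >= 1L)
  A <- .adjacency(net, weighted = weighted)
  labels <- rownames(A)
  best <- NULL
  bestQ <- -Inf
  for (r in seq_len(nRestarts)) {
    comm <- .withSeed(as.integer(seed) + r - 1L, .louvainOnce(A))
    q <- modularityScore(net, setNames(comm, labels), weighted = weighted)
    if (q > bestQ + 1e-12) {
      bestQ <- q
      best <- comm
    }
  }
  membership <- setNames(match(best, unique(best)), labels)
  list(membership = membership, modularity = bestQ,
       nCommunities = length(unique(best)))
}
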