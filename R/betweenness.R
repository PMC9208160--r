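#' Normalized betweenness centrality (BCI)
#'
#' Shortest-path betweenness of every node of the two-mode network,
#' computed on the unweighted graph with Brandes' accumulation and
#' normalized by `(n - 1)(n - 2) / 2`, the number of node pairs a node
#' could mediate in an undirected graph, so values lie in \[0, 1\]. Pairs
#' in different connected components contribute nothing. Evidence scores
#' are not used as distances: higher evidence does not mean a shorter
#' path, and no principled transform is given, so paths are hop counts
#' (see the package vignette for discussion).
#'
#' A high-BCI mosquito bridges clusters of pathogens and other vectors —
#' the network's generalists.
#'
#' @param net a [BipartiteNetwork][BipartiteNetwork-class] with at least 3
#'   nodes.
#' @return named numeric vector over all nodes (pathogens then vectors).
#' @export
#' @examples
#' # star: one vector shared by three pathogens
#' pairs <- data.frame(vector = "hub", pathogen = c("p1", "p2", "p3"),
#'                     score = rep(1L, 3))
#' betweennessCentrality(buildNetwork(pairs))["hub"]  # 1
betweennessCentrality <- function(net) {
  stopifnot(is(net, "BipartiteNetwork"))
  adj <- .adjList(net)
  n <- length(adj)
  if (n < 3L) stop("betweenness needs at least 3 nodes", call. = FALSE)
  bc <- numeric(n)
  for (s in seq_len(n)) {
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(-1L, n); dist[s] <- 0L
    preds <- vector("list", n)
    order <- integer(0)
    queue <- s
    head <- 1L
    while (head <= length(queue)) {
      v <- queue[head]; head <- head + 1L
      order <- c(order, v)
      for (w in adj[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (w in rev(order)) {
      for (v in preds[[w]]) {
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      }
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  # each unordered pair was counted from both endpoints
  setNames(bc / 2 / ((n - 1) * (n - 2) / 2), names(adj))
}
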