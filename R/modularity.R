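#' Newman-Girvan modularity of a node partition
#'
#' Evaluates `Q = (1/2m) * sum_ij (A_ij - k_i k_j / 2m) * delta(c_i, c_j)`
#' on the two-mode network treated as a plain undirected graph, the form
#' optimised by Louvain clustering. With `weighted = TRUE` (the default)
#' `A_ij` is the 1-5 evidence score of the edge, matching the use of
#' scores as importance weights; with `weighted = FALSE` every edge counts
#' 1. Q is near 0 for a partition no better than chance and approaches 1
#' for strongly compartmentalised networks; it can be slightly negative.
#'
#' @param net a [BipartiteNetwork][BipartiteNetwork-class].
#' @param membership named integer vector mapping every node label (all
#'   pathogens and vectors) to a community id, e.g. from
#'   [louvainCommunities()].
#' @param weighted logical; use evidence scores as edge weights.
#' @return numeric Q.
#' @export
#' @examples
#' pairs <- data.frame(vector = c("v1", "v2"), pathogen = c("p1", "p2"),
#'                     score = c(1L, 1L))
#' net <- buildNetwork(pairs)  # two disconnected edges
#' memb <- c(p1 = 1L, p2 = 2L, v1 = 1L, v2 = 2L)
#' modularityScore(net, memb)  # 0.5
modularityScore <- function(net, membership, weighted = TRUE) {
  stopifnot(is(net, "BipartiteNetwork"))
  labels <- c(net@pathogens, net@vectors)
  if (is.null(names(membership)) || !all(labels %in% names(membership))) {
    stop("membership must cover every node of the network", call. = FALSE)
  }
  comm <- membership[labels]
  A <- .adjacency(net, weighted = weighted)
  m2 <- sum(A)                      # 2m
  if (m2 == 0) stop("network has no edges", call. = FALSE)
  k <- rowSums(A)
  groups <- split(seq_along(labels), comm)
  q <- 0
  for (g in groups) {
    q <- q + sum(A[g, g, drop = FALSE]) / m2 - (sum(k[g]) / m2)^2
  }
  q
}
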