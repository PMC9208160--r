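#' Build a bipartite vector-pathogen network from scored pairs
#'
#' Constructs the two-mode network whose edges are the scored
#' vector-pathogen pairs and whose edge weights are the 1-5 evidence
#' scores. With `knownOnly = TRUE` only known-vector edges (score 5) are
#' kept and nodes left isolated by the filter are dropped, reproducing the
#' restriction of the full network to consensus known vectors. Node
#' ordering is lexicographic so that seeded downstream analyses are
#' reproducible.
#'
#' @param pairs data.frame with columns `vector`, `pathogen`, `score`
#'   (one row per pair, as returned by [scoreEvidence()] or
#'   [readScoredPairs()]).
#' @param knownOnly logical; keep only score-5 edges.
#' @return a [BipartiteNetwork][BipartiteNetwork-class].
#' @export
#' @examples
#' pairs <- data.frame(vector = c("A", "B"), pathogen = c("P1", "P1"),
#'                     score = c(5L, 2L))
#' buildNetwork(pairs)                     # 2 vectors, 1 pathogen
#' buildNetwork(pairs, knownOnly = TRUE)   # 1 vector, 1 pathogen
buildNetwork <- function(pairs, knownOnly = FALSE) {
  stopifnot(is.data.frame(pairs),
            all(c("vector", "pathogen", "score") %in% names(pairs)))
  e <- data.frame(vector = .trimLabel(pairs$vector),
                  pathogen = .trimLabel(pairs$pathogen),
                  score = as.integer(pairs$score))
  if (anyDuplicated(e[, c("vector", "pathogen")])) {
    stop("duplicate vector-pathogen pairs; collapse evidence with scoreEvidence() first",
         call. = FALSE)
  }
  if (knownOnly) e <- e[e$score == 5L, , drop = FALSE]
  if (nrow(e) == 0L) stop("empty network", call. = FALSE)
  e <- e[order(e$pathogen, e$vector), , drop = FALSE]
  rownames(e) <- NULL
  new("BipartiteNetwork",
      vectors = sort(unique(e$vector)),
      pathogens = sort(unique(e$pathogen)),
      edges = e)
}

#' @rdname network-accessors
#' @export
setMethod("vectorNodes", "BipartiteNetwork", function(x) x@vectors)

#' @rdname network-accessors
#' @export
setMethod("pathogenNodes", "BipartiteNetwork", function(x) x@pathogens)

#' @rdname network-accessors
#' @export
setMethod("edgeTable", "BipartiteNetwork", function(x) x@edges)

#' @rdname network-accessors
#' @export
setMethod("nVectors", "BipartiteNetwork", function(x) length(x@vectors))

#' @rdname network-accessors
#' @export
setMethod("nPathogens", "BipartiteNetwork", function(x) length(x@pathogens))

#' @rdname network-accessors
#' @export
setMethod("nEdges", "BipartiteNetwork", function(x) nrow(x@edges))

#' Binary incidence matrix of a bipartite network
#'
#' Returns the pathogens x vectors presence/absence matrix underlying the
#' network: cell (i, j) is 1 iff pathogen i is associated with vector j.
#' Evidence scores are deliberately dropped — nestedness (NODF) and the
#' extinction simulation operate on the binary structure.
#'
#' @param x a [BipartiteNetwork][BipartiteNetwork-class]
#' @return integer matrix with pathogen row names and vector column names.
#' @export
setMethod("incidenceMatrix", "BipartiteNetwork", function(x) {
  m <- matrix(0L, length(x@pathogens), length(x@vectors),
              dimnames = list(x@pathogens, x@vectors))
  m[cbind(match(x@edges$pathogen, x@pathogens),
          match(x@edges$vector, x@vectors))] <- 1L
  m
})

#' Node degree in a bipartite network
#'
#' Number of incident edges per node. Pathogen nodes orphaned by
#' [removeVector()] have degree 0.
#'
#' @param x a [BipartiteNetwork][BipartiteNetwork-class]
#' @param nodes character of node labels, or `NULL` for all nodes
#'   (pathogens first, then vectors).
#' @return named integer vector of degrees.
#' @export
setMethod("nodeDegree", "BipartiteNetwork", function(x, nodes = NULL) {
  all <- c(x@pathogens, x@vectors)
  if (is.null(nodes)) nodes <- all
  unknown <- setdiff(nodes, all)
  if (length(unknown)) {
    stop("unknown node(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  deg <- table(factor(c(x@edges$pathogen, x@edges$vector), levels = all))
  setNames(as.integer(deg[nodes]), nodes)
})

#' Remove a vector node and its incident edges
#'
#' Deletes one vector from the network together with all its edges.
#' Pathogen nodes are never deleted: a pathogen whose last vector is
#' removed stays in the node set with degree 0, representing its secondary
#' extinction while keeping the pathogen denominator of extinction curves
#' fixed.
#'
#' @param x a [BipartiteNetwork][BipartiteNetwork-class]
#' @param name vector node label.
#' @return the reduced network.
#' @export
setMethod("removeVector", "BipartiteNetwork", function(x, name) {
  if (length(name) != 1L || !name %in% x@vectors) {
    stop("unknown vector node: ", paste(name, collapse = ", "), call. = FALSE)
  }
  e <- x@edges[x@edges$vector != name, , drop = FALSE]
  rownames(e) <- NULL
  new("BipartiteNetwork",
      vectors = setdiff(x@vectors, name),
      pathogens = x@pathogens,
      edges = e)
})

#' Convert to an igraph object
#'
#' Builds the equivalent undirected igraph graph with vertex attributes
#' `name` and `mode` (`"vector"` or `"pathogen"`, also set as the logical
#' `type` used by igraph's bipartite layouts) and edge attributes `score`
#' and `weight` (equal). Used for interoperability and for GraphML export;
#' all structure metrics in this package are computed natively.
#'
#' @param x a [BipartiteNetwork][BipartiteNetwork-class]
#' @return an `igraph` graph.
#' @export
setMethod("asIgraph", "BipartiteNetwork", function(x) {
  verts <- data.frame(
    name = c(x@pathogens, x@vectors),
    mode = c(rep("pathogen", length(x@pathogens)),
             rep("vector", length(x@vectors))),
    type = c(rep(FALSE, length(x@pathogens)), rep(TRUE, length(x@vectors)))
  )
  edges <- data.frame(from = x@edges$pathogen, to = x@edges$vector,
                      score = x@edges$score, weight = x@edges$score)
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = verts)
})

#' Export a network to GraphML or edge-list CSV
#'
#' `writeGraphML()` writes the graph (vertex attribute `mode`, edge
#' attribute `score`) in GraphML for use in external network tools;
#' `writeEdgeList()` writes a plain `vector,pathogen,score` CSV.
#'
#' @param x a [BipartiteNetwork][BipartiteNetwork-class]
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGraphML <- function(x, path) {
  igraph::write_graph(asIgraph(x), path, format = "graphml")
  invisible(path)
}

#' @rdname writeGraphML
#' @export
writeEdgeList <- function(x, path) {
  write.csv(edgeTable(x), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

# Dense symmetric adjacency over nodes c(pathogens, vectors); weights are
# evidence scores when weighted, else 1. Shared by the one-mode metrics.
.adjacency <- function(net, weighted = TRUE) {
  n <- length(net@pathogens) + length(net@vectors)
  labels <- c(net@pathogens, net@vectors)
  A <- matrix(0, n, n, dimnames = list(labels, labels))
  i <- match(net@edges$pathogen, labels)
  j <- match(net@edges$vector, labels)
  w <- if (weighted) net@edges$score else rep(1, nrow(net@edges))
  A[cbind(i, j)] <- w
  A[cbind(j, i)] <- w
  A
}

# Neighbor index lists for the unweighted graph (pathogens then vectors).
.adjList <- function(net) {
  labels <- c(net@pathogens, net@vectors)
  i <- match(net@edges$pathogen, labels)
  j <- match(net@edges$vector, labels)
  adj <- vector("list", length(labels))
  for (k in seq_along(labels)) adj[[k]] <- integer()
  if (length(i)) {
    adj1 <- split(j, factor(i, levels = seq_along(labels)))
    adj2 <- split(i, factor(j, levels = seq_along(labels)))
    adj <- mapply(function(a, b) sort(c(a, b)), adj1, adj2, SIMPLIFY = FALSE)
  }
  names(adj) <- labels
  adj
}
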