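#' @include AllClasses.R
NULL

#' Node accessors for a bipartite network
#'
#' `vectorNodes()` and `pathogenNodes()` return the sorted node labels of
#' each mode; `edgeTable()` returns the edge data.frame (`vector`,
#' `pathogen`, `score`); `nVectors()`, `nPathogens()` and `nEdges()` the
#' corresponding counts.
#'
#' @param x a [BipartiteNetwork][BipartiteNetwork-class]
#' @return character vectors, a data.frame, or integer counts.
#' @name network-accessors
#' @examples
#' net <- buildNetwork(data.frame(
#'   vector = c("Ae. aegypti", "Cx. pipiens"),
#'   pathogen = c("DENV", "WNV"), score = c(5L, 3L)
#' ))
#' vectorNodes(net)
#' nEdges(net)
NULL

#' @rdname network-accessors
#' @export
setGeneric("vectorNodes", function(x) standardGeneric("vectorNodes"))

#' @rdname network-accessors
#' @export
setGeneric("pathogenNodes", function(x) standardGeneric("pathogenNodes"))

#' @rdname network-accessors
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname network-accessors
#' @export
setGeneric("nVectors", function(x) standardGeneric("nVectors"))

#' @rdname network-accessors
#' @export
setGeneric("nPathogens", function(x) standardGeneric("nPathogens"))

#' @rdname network-accessors
#' @export
setGeneric("nEdges", function(x) standardGeneric("nEdges"))

#' @rdname incidenceMatrix
#' @export
setGeneric("incidenceMatrix", function(x) standardGeneric("incidenceMatrix"))

#' @rdname nodeDegree
#' @export
setGeneric("nodeDegree", function(x, nodes = NULL) standardGeneric("nodeDegree"))

#' @rdname removeVector
#' @export
setGeneric("removeVector", function(x, name) standardGeneric("removeVector"))

#' @rdname asIgraph
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))
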