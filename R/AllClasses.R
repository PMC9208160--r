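#' BipartiteNetwork: a two-mode vector-pathogen network
#'
#' The central container of the package: an undirected two-mode graph whose
#' nodes are mosquito vectors on one side and human pathogens on the other,
#' and whose edges carry the 1-5 evidence score of the association. Edges
#' connect only vectors to pathogens; there are no within-mode edges by
#' construction. Vector nodes always have degree >= 1 (a vector is deleted
#' together with its last edge), whereas pathogen nodes may reach degree 0
#' during extinction simulations: a pathogen with no surviving vector is
#' extinct but is kept in the node set so that curve denominators stay fixed.
#'
#' Build objects with [buildNetwork()]; do not call `new()` directly.
#'
#' @slot vectors character, sorted vector node labels.
#' @slot pathogens character, sorted pathogen node labels.
#' @slot edges data.frame with columns `vector`, `pathogen`, `score`
#'   (integer 1-5); one row per vector-pathogen pair.
#'
#' @seealso [buildNetwork()], [incidenceMatrix()], [removeVector()]
#' @export
setClass("BipartiteNetwork",
  representation(
    vectors   = "character",
    pathogens = "character",
    edges     = "data.frame"
  )
)

setValidity("BipartiteNetwork", function(object) {
  msgs <- character()
  e <- object@edges
  need <- c("vector", "pathogen", "score")
  if (!all(need %in% names(e))) {
    return(paste("edges must have columns", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(object@vectors)) msgs <- c(msgs, "duplicate vector labels")
  if (anyDuplicated(object@pathogens)) msgs <- c(msgs, "duplicate pathogen labels")
  if (nrow(e) > 0) {
    if (!all(e$vector %in% object@vectors)) {
      msgs <- c(msgs, "edge references unknown vector node")
    }
    if (!all(e$pathogen %in% object@pathogens)) {
      msgs <- c(msgs, "edge references unknown pathogen node")
    }
    if (!all(e$score %in% 1:5)) {
      msgs <- c(msgs, "edge scores must be integers in 1..5")
    }
    if (anyDuplicated(e[, c("vector", "pathogen")])) {
      msgs <- c(msgs, "duplicate edges for a vector-pathogen pair")
    }
  }
  # vectors enter the network only via edges; pathogens may be orphaned
  # (extinct) after removals.
  if (length(object@vectors) > 0 && !all(object@vectors %in% e$vector)) {
    msgs <- c(msgs, "vector node with degree 0 (vectors exist only via edges)")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' @describeIn BipartiteNetwork-class compact summary of node and edge counts
#' @param object a `BipartiteNetwork`
#' @export
setMethod("show", "BipartiteNetwork", function(object) {
  nk <- sum(object@edges$score == 5L)
  cat(sprintf(
    "BipartiteNetwork: %d pathogens x %d vectors, %d edges (%d known-vector)\n",
    length(object@pathogens), length(object@vectors),
    nrow(object@edges), nk
  ))
  invisible(NULL)
})

#' ExtinctionCurve: pathogen survival as vectors are removed
#'
#' Records, for one full removal sequence over all `V` vectors of a network,
#' the proportion of pathogens that still have at least one surviving vector
#' after `k` removals, for `k = 0, ..., V`. The first point is always
#' `(0, 1)` and the last `(V, 0)` because every pathogen has at least one
#' vector at the start and none at the end.
#'
#' @slot points data.frame with columns `k` (vectors removed), `x` (`k/V`)
#'   and `y` (surviving proportion of pathogens).
#' @slot V integer, total number of vectors.
#' @slot P integer, total number of pathogens (fixed denominator).
#'
#' @seealso [simulateExtinction()], [curveRobustness()], [curveBreakPoint()]
#' @export
setClass("ExtinctionCurve",
  representation(points = "data.frame", V = "integer", P = "integer")
)

setValidity("ExtinctionCurve", function(object) {
  p <- object@points
  if (!all(c("k", "x", "y") %in% names(p))) return("points needs k, x, y")
  if (nrow(p) != object@V + 1L) return("points must have V + 1 rows")
  if (!isTRUE(all.equal(p$k, 0:object@V))) return("k must run 0..V")
  if (abs(p$y[1] - 1) > 1e-12) return("curve must start at y = 1")
  if (abs(p$y[nrow(p)]) > 1e-12) return("curve must end at y = 0")
  if (any(diff(p$y) > 1e-12)) return("y must be non-increasing")
  TRUE
})

#' @describeIn ExtinctionCurve-class one-line summary with robustness
#' @param object an `ExtinctionCurve`
#' @export
setMethod("show", "ExtinctionCurve", function(object) {
  cat(sprintf(
    "ExtinctionCurve: %d vectors, %d pathogens, break point %d, robustness %.4f\n",
    object@V, object@P, curveBreakPoint(object), curveRobustness(object)
  ))
  invisible(NULL)
})

#' RobustnessResult: summary of an extinction experiment
#'
#' Aggregates one or many extinction-curve replicates. `robustness` is the
#' mean of the per-replicate areas under the curve, and
#' `robustnessMeanCurve` the area under the pointwise-mean curve; on the
#' fixed grid `k/V` the two coincide in expectation and are reported side
#' by side. `breakPoint` is the mean number of removals at the first
#' secondary pathogen extinction.
#'
#' @slot robustness numeric in \[0, 1\]: mean per-replicate area under the
#'   extinction curve.
#' @slot robustnessSd numeric: standard deviation over replicates (0 for a
#'   single deterministic replicate).
#' @slot robustnessMeanCurve numeric: area under the pointwise-mean curve.
#' @slot breakPoint numeric >= 1: mean break point over replicates.
#' @slot breakPointSd numeric.
#' @slot replicates integer.
#' @slot policy character, "random" or "targeted".
#' @slot curve data.frame `k, x, yMean, ySd`: the pointwise mean curve.
#'
#' @seealso [monteCarloExtinction()]
#' @export
setClass("RobustnessResult",
  representation(
    robustness          = "numeric",
    robustnessSd        = "numeric",
    robustnessMeanCurve = "numeric",
    breakPoint          = "numeric",
    breakPointSd        = "numeric",
    replicates          = "integer",
    policy              = "character",
    curve               = "data.frame"
  )
)

setValidity("RobustnessResult", function(object) {
  if (object@robustness < 0 || object@robustness > 1) {
    return("robustness must lie in [0, 1]")
  }
  if (object@breakPoint < 1) return("break point must be >= 1")
  TRUE
})

#' @export
setMethod("$", "RobustnessResult", function(x, name) slot(x, name))

#' @describeIn RobustnessResult-class compact summary
#' @param object a `RobustnessResult`
#' @export
setMethod("show", "RobustnessResult", function(object) {
  cat(sprintf(
    "RobustnessResult (%s, %d replicate%s): robustness %.4f, break point %.2f\n",
    object@policy, object@replicates, if (object@replicates == 1L) "" else "s",
    object@robustness, object@breakPoint
  ))
  invisible(NULL)
})
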