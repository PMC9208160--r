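#' Certainty-versus-scale profiles of pathogens
#'
#' For every pathogen, counts the total number of associated vectors (the
#' scale of the control problem) and the number of consensus known vectors
#' (score 5), and derives the certainty — the fraction of associated
#' vectors that are known. Each pathogen is then placed in one of four
#' quadrants: the scale threshold is the median total-vector count across
#' pathogens (computed from the data, midpoint rule for even counts) and
#' the certainty threshold is 0.5. "Large scale" means strictly more
#' vectors than the median and "high certainty" strictly more than half
#' known; boundary values classify as small/low.
#'
#' Pathogens with few vectors and high certainty are the easiest targets
#' for eradication; a large scale with low certainty marks the hardest
#' problems, with many redundant potential vectors and no obvious target.
#'
#' @param pairs scored-pair data.frame (`vector`, `pathogen`, `score`), as
#'   returned by [scoreEvidence()].
#' @return data.frame with one row per pathogen: `pathogen`, `nTotal`,
#'   `nKnown`, `certainty` and `quadrant` (one of
#'   `small_scale_low_certainty`, `small_scale_high_certainty`,
#'   `large_scale_low_certainty`, `large_scale_high_certainty`), sorted by
#'   pathogen. The scale threshold used is attached as attribute
#'   `medianTotal`.
#' @export
#' @examples
#' pairs <- data.frame(vector = c("a", "b", "c"),
#'                     pathogen = c("P1", "P1", "P2"),
#'                     score = c(5L, 5L, 1L))
#' profilePathogens(pairs)
profilePathogens <- function(pairs) {
  stopifnot(is.data.frame(pairs),
            all(c("vector", "pathogen", "score") %in% names(pairs)))
  if (nrow(pairs) == 0L) stop("no scored pairs", call. = FALSE)
  if (anyDuplicated(pairs[, c("vector", "pathogen")])) {
    stop("duplicate vector-pathogen pairs", call. = FALSE)
  }
  nTotal <- tapply(pairs$vector, pairs$pathogen, length)
  nKnown <- tapply(pairs$score == 5L, pairs$pathogen, sum)
  med <- median(as.numeric(nTotal))
  out <- data.frame(
    pathogen = names(nTotal),
    nTotal = as.integer(nTotal),
    nKnown = as.integer(nKnown),
    certainty = as.numeric(nKnown) / as.numeric(nTotal),
    row.names = NULL
  )
  scale <- ifelse(out$nTotal > med, "large_scale", "small_scale")
  cert <- ifelse(out$certainty > 0.5, "high_certainty", "low_certainty")
  out$quadrant <- paste(scale, cert, sep = "_")
  out <- out[order(out$pathogen), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "medianTotal") <- med
  out
}

#' Write pathogen profiles as CSV
#'
#' Writes the profile table with the header
#' `pathogen,n_total,n_known,certainty,quadrant`.
#'
#' @param profiles output of [profilePathogens()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeProfiles <- function(profiles, path) {
  out <- data.frame(pathogen = profiles$pathogen, n_total = profiles$nTotal,
                    n_known = profiles$nKnown, certainty = profiles$certainty,
                    quadrant = profiles$quadrant)
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Quadrant counts of a profile table
#'
#' @param profiles output of [profilePathogens()].
#' @return named integer vector over the four quadrants (zeros included).
#' @export
quadrantCounts <- function(profiles) {
  lev <- c("small_scale_low_certainty", "small_scale_high_certainty",
           "large_scale_low_certainty", "large_scale_high_certainty")
  table(factor(profiles$quadrant, levels = lev))
}
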