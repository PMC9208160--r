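#' NODF nestedness of a binary incidence matrix
#'
#' Nestedness metric based on Overlap and Decreasing Fill. For every
#' unordered pair of rows, the paired overlap is
#' `100 * (shared presences) / (fill of the sparser row)` when the two row
#' fills differ strictly, and 0 when they are equal (the decreasing-fill
#' condition); likewise for columns. NODF is the mean paired overlap over
#' all row pairs and column pairs, ranging from 0 (non-nested) to 100
#' (perfectly nested). The statistic is invariant to row/column permutation
#' and to transposition.
#'
#' @param m binary incidence matrix (pathogens x vectors, see
#'   [incidenceMatrix()]); needs at least 2 rows and 2 columns and no
#'   all-zero row or column.
#' @return numeric NODF in \[0, 100\].
#' @export
#' @examples
#' stair <- matrix(c(1, 1, 1, 1, 1, 1, 1, 0, 1, 1, 0, 0, 1, 0, 0, 0), 4, 4,
#'                 byrow = TRUE)
#' nodf(stair)        # 100: perfect nesting
#' nodf(diag(2))      # 0: equal fills never satisfy decreasing fill
nodf <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop("incidence matrix must have at least 2 rows and 2 columns",
         call. = FALSE)
  }
  if (!all(m %in% c(0, 1))) stop("incidence matrix must be binary", call. = FALSE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("incidence matrix must have no all-zero rows or columns", call. = FALSE)
  }
  pairedSum <- function(M) {
    fill <- rowSums(M)
    overlap <- M %*% t(M)
    fi <- outer(fill, fill, function(a, b) a)   # fill of row i
    fj <- t(fi)                                  # fill of row j
    # contribution of ordered pair (denser i, sparser j): strict decrease only
    contrib <- ifelse(fi > fj, 100 * overlap / fj, 0)
    sum(contrib[upper.tri(contrib)] + t(contrib)[upper.tri(contrib)])
  }
  nPairs <- choose(nrow(m), 2) + choose(ncol(m), 2)
  (pairedSum(m) + pairedSum(t(m))) / nPairs
}
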