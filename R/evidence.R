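#' @importFrom stats median runif setNames aggregate sd
#' @importFrom utils read.csv write.csv
NULL

# The five evidence categories and the lab-evidence ladder. Wild infection
# carries no ladder level of its own: alone it scores 1, alongside lab
# evidence it adds +1.
.labLevels <- c(lab_infection = 1L, lab_dissemination = 2L, lab_transmission = 3L)

#' Evidence categories recognised by the scoring scheme
#'
#' The five kinds of documented evidence linking a mosquito to a pathogen,
#' ordered from weakest to strongest: isolation from a wild-caught female
#' (`wild_infection`), infection after an infectious blood meal
#' (`lab_infection`), replication in vector tissue (`lab_dissemination`),
#' transmission to a host under laboratory conditions (`lab_transmission`),
#' and consensus known-vector status (`known_vector`).
#'
#' @return character vector of the five category tokens.
#' @export
#' @examples
#' evidenceCategories()
evidenceCategories <- function() {
  c("wild_infection", names(.labLevels), "known_vector")
}

.checkCategories <- function(categories, context = NULL) {
  bad <- setdiff(unique(categories), evidenceCategories())
  if (length(bad)) {
    where <- if (is.null(context)) "" else paste0(" (", context, ")")
    stop("unknown evidence category: ", paste(bad, collapse = ", "), where,
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Score one vector-pathogen pair from its evidence categories
#'
#' Collapses the set of documented evidence categories for a single
#' vector-pathogen pair into the 1-5 evidence score. Known-vector status
#' dominates and scores 5. Otherwise the score is the strongest laboratory
#' level present (infection 1, dissemination 2, transmission 3), plus one
#' if the pathogen was also isolated from a wild-caught mosquito, capped at
#' 4 so that 5 remains reserved for known vectors. Wild infection alone
#' scores 1. Duplicate categories are ignored (set semantics).
#'
#' @param categories character vector of evidence category tokens (see
#'   [evidenceCategories()]); must be non-empty.
#' @return integer score in 1..5.
#' @export
#' @examples
#' scorePair(c("lab_transmission", "wild_infection")) # 4
#' scorePair("wild_infection")                        # 1
#' scorePair(c("known_vector", "lab_infection"))      # 5
scorePair <- function(categories) {
  categories <- unique(as.character(categories))
  if (length(categories) == 0L) stop("no evidence", call. = FALSE)
  .checkCategories(categories)
  if ("known_vector" %in% categories) return(5L)
  lab <- .labLevels[intersect(names(.labLevels), categories)]
  wild <- "wild_infection" %in% categories
  if (length(lab) == 0L) return(1L)         # wild infection alone
  min(4L, max(lab) + as.integer(wild))
}

.trimLabel <- function(x) {
  gsub("[[:space:]]+", " ", trimws(as.character(x)))
}

#' Validate a long-format evidence table
#'
#' Checks the three-column evidence table (`vector`, `pathogen`,
#' `evidence`) used as input to [scoreEvidence()]: required columns,
#' non-empty labels after whitespace trimming, and recognised category
#' tokens. Errors cite the offending row numbers.
#'
#' @param records data.frame with columns `vector`, `pathogen`, `evidence`.
#' @return the validated data.frame with trimmed labels, invisibly usable
#'   downstream.
#' @export
validateEvidence <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("vector", "pathogen", "evidence")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("evidence table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  records$vector <- .trimLabel(records$vector)
  records$pathogen <- .trimLabel(records$pathogen)
  records$evidence <- trimws(as.character(records$evidence))
  if (nrow(records) == 0L) return(records[, need])
  empty <- which(records$vector == "" | records$pathogen == "")
  if (length(empty)) {
    stop("empty vector or pathogen label at row(s) ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  bad <- which(!records$evidence %in% evidenceCategories())
  if (length(bad)) {
    stop("unknown evidence category '", records$evidence[bad[1]],
         "' at row(s) ", paste(bad, collapse = ", "), call. = FALSE)
  }
  records[, need]
}

#' Collapse an evidence table into scored vector-pathogen pairs
#'
#' Applies [scorePair()] to every distinct (vector, pathogen) key of a
#' long-format evidence table, yielding exactly one scored pair per key.
#' Duplicate identical records are idempotent. The result is sorted by
#' pathogen then vector so repeated runs are byte-identical.
#'
#' @param records data.frame with columns `vector`, `pathogen`, `evidence`
#'   (see [validateEvidence()] for the contract); may be empty.
#' @return data.frame with columns `vector`, `pathogen`, `score` (integer
#'   1-5) and `known` (logical, `score == 5`).
#' @export
#' @examples
#' recs <- data.frame(
#'   vector = c("Ae. aegypti", "Ae. aegypti", "Cx. pipiens"),
#'   pathogen = c("DENV", "DENV", "WNV"),
#'   evidence = c("lab_transmission", "wild_infection", "known_vector")
#' )
#' scoreEvidence(recs)
scoreEvidence <- function(records) {
  records <- validateEvidence(records)
  if (nrow(records) == 0L) {
    return(data.frame(vector = character(), pathogen = character(),
                      score = integer(), known = logical()))
  }
  key <- interaction(records$pathogen, records$vector, drop = TRUE, sep = "\r")
  cats <- split(records$evidence, key)
  parts <- strsplit(names(cats), "\r", fixed = TRUE)
  out <- data.frame(
    vector   = vapply(parts, `[`, character(1), 2L),
    pathogen = vapply(parts, `[`, character(1), 1L),
    score    = vapply(cats, scorePair, integer(1)),
    row.names = NULL
  )
  out <- out[order(out$pathogen, out$vector), , drop = FALSE]
  rownames(out) <- NULL
  out$known <- out$score == 5L
  out
}

#' Read an evidence CSV
#'
#' Reads the package's evidence dialect: UTF-8, comma-delimited, header row
#' `vector,pathogen,evidence`, one literature observation per row. Genus
#' level entries must already be disambiguated per pathogen (e.g.
#' `"Mansonia sp. [Guama]"`); the package matches node labels by exact
#' string after whitespace normalisation and performs no taxonomic synonym
#' resolution.
#'
#' @param path file path.
#' @return validated evidence data.frame.
#' @export
readEvidence <- function(path) {
  validateEvidence(read.csv(path, stringsAsFactors = FALSE))
}

#' Write an evidence CSV
#'
#' @param records evidence data.frame (`vector`, `pathogen`, `evidence`).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeEvidence <- function(records, path) {
  records <- validateEvidence(records)
  write.csv(records, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read and write scored-pair CSVs
#'
#' The scored-pair dialect has header `vector,pathogen,score,is_known`.
#' `readScoredPairs()` returns the in-memory column names used throughout
#' the package (`known` instead of `is_known`).
#'
#' @param pairs scored-pair data.frame as returned by [scoreEvidence()].
#' @param path file path.
#' @return `writeScoredPairs()` returns `path` invisibly;
#'   `readScoredPairs()` the scored-pair data.frame.
#' @export
writeScoredPairs <- function(pairs, path) {
  stopifnot(all(c("vector", "pathogen", "score") %in% names(pairs)))
  out <- data.frame(vector = pairs$vector, pathogen = pairs$pathogen,
                    score = as.integer(pairs$score),
                    is_known = pairs$score == 5L)
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname writeScoredPairs
#' @export
readScoredPairs <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("vector", "pathogen", "score")
  if (!all(need %in% names(x))) {
    stop("scored-pair file is missing column(s): ",
         paste(setdiff(need, names(x)), collapse = ", "), call. = FALSE)
  }
  if (!all(x$score %in% 1:5)) stop("scores must be integers in 1..5", call. = FALSE)
  data.frame(vector = .trimLabel(x$vector), pathogen = .trimLabel(x$pathogen),
             score = as.integer(x$score), known = as.integer(x$score) == 5L)
}
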