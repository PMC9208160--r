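test_that("single categories score their ladder level", {
  expect_identical(scorePair("lab_infection"), 1L)
  expect_identical(scorePair("lab_dissemination"), 2L)
  expect_identical(scorePair("lab_transmission"), 3L)
  expect_identical(scorePair("wild_infection"), 1L)
  expect_identical(scorePair("known_vector"), 5L)
})

test_that("documented scoring combinations collapse correctly", {
  cases <- list(
    list(c("known_vector", "lab_infection"), 5L),       # known dominates
    list(c("lab_transmission", "wild_infection"), 4L),  # 3 + 1
    list(c("lab_dissemination", "wild_infection"), 3L), # 1 + 2
    list(c("lab_infection", "wild_infection"), 2L),     # 1 + 1
    list(c("lab_infection", "lab_dissemination"), 2L)   # max lab level
  )
  for (cs in cases) expect_identical(scorePair(cs[[1]]), cs[[2]])
  # duplicates are idempotent
  expect_identical(scorePair(rep("lab_transmission", 3)), 3L)
})

test_that("scorePair rejects empty and unknown inputs", {
  expect_error(scorePair(character(0)), "no evidence")
  expect_error(scorePair(c("lab_infection", "vibes")), "vibes")
})

test_that("scorePair agrees with the literal rule oracle on all 31 subsets", {
  for (s in allSubsets(evidenceCategories())) {
    expect_identical(scorePair(s), oracleScore(s), info = paste(s, collapse = "+"))
  }
})

test_that("adding evidence never decreases a pair's score", {
  subsets <- allSubsets(evidenceCategories())
  for (s in subsets) {
    for (extra in setdiff(evidenceCategories(), s)) {
      expect_gte(scorePair(c(s, extra)), scorePair(s))
    }
  }
})

test_that("scoreEvidence yields one sorted pair per distinct key", {
  recs <- data.frame(
    vector = c("b", "a", "a", "a"),
    pathogen = c("P1", "P1", "P1", "P2"),
    evidence = c("known_vector", "lab_infection", "wild_infection",
                 "lab_dissemination")
  )
  out <- scoreEvidence(recs)
  expect_equal(nrow(out), 3L)
  expect_equal(out$pathogen, c("P1", "P1", "P2"))   # pathogen then vector
  expect_equal(out$vector, c("a", "b", "a"))
  expect_equal(out$score, c(2L, 5L, 2L))
  expect_equal(out$known, c(FALSE, TRUE, FALSE))
  # empty input
  expect_equal(nrow(scoreEvidence(recs[0, ])), 0L)
  # union-of-evidence example: three records for one pair
  one <- data.frame(vector = "a", pathogen = "P",
                    evidence = c("lab_infection", "lab_dissemination",
                                 "wild_infection"))
  expect_equal(scoreEvidence(one)$score, 3L)
  # duplicate records do not change the result
  expect_identical(scoreEvidence(rbind(recs, recs)), scoreEvidence(recs))
})

test_that("labels are trimmed and internal whitespace collapsed", {
  recs <- data.frame(vector = c(" Aedes  aegypti ", "Aedes aegypti"),
                     pathogen = c("DENV", " DENV"),
                     evidence = c("lab_infection", "wild_infection"))
  out <- scoreEvidence(recs)
  expect_equal(nrow(out), 1L)
  expect_equal(out$vector, "Aedes aegypti")
  expect_equal(out$score, 2L)
})

test_that("malformed evidence tables fail with row context", {
  bad <- data.frame(vector = c("a", "b"), pathogen = c("P", "Q"),
                    evidence = c("lab_infection", "nonsense"))
  expect_error(validateEvidence(bad), "nonsense.*row.*2")
  expect_error(validateEvidence(data.frame(vector = " ", pathogen = "P",
                                           evidence = "lab_infection")),
               "empty.*row")
  expect_error(validateEvidence(data.frame(x = 1)), "missing column")
})

test_that("evidence and scored-pair CSVs round-trip", {
  recs <- data.frame(vector = c("a", "b"), pathogen = c("P1", "P2"),
                     evidence = c("known_vector", "lab_transmission"))
  f <- withr::local_tempfile(fileext = ".csv")
  writeEvidence(recs, f)
  expect_equal(readEvidence(f), validateEvidence(recs))
  pairs <- scoreEvidence(recs)
  g <- withr::local_tempfile(fileext = ".csv")
  writeScoredPairs(pairs, g)
  back <- readScoredPairs(g)
  expect_equal(back$score, pairs$score)
  expect_equal(back$known, pairs$known)
  expect_equal(names(read.csv(g)), c("vector", "pathogen", "score", "is_known"))
})
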