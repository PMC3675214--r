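## A hand-specified additive scorer: reference scores `base`, each listed
## mutation adds its gain, every other allowed mutation costs 1.
gainScorer <- function(reference, gains, base = 0) {
  scorer("gains", "higher", function(s) {
    muts <- diffMutations(reference, s)
    if (!length(muts)) return(base)
    g <- ifelse(muts %in% names(gains), gains[muts], -1)
    base + sum(g)
  })
}

test_that("initialization keeps exactly the improving single mutants", {
  sc <- gainScorer("RGTFEGKF", c(G2V = 2, F4W = 1))
  lib <- initializeLibrary("RGTFEGKF", sc)
  expect_identical(libSize(lib), 2L)
  expect_setequal(libraryMembers(lib)$sequence, c("RVTFEGKF", "RGTWEGKF"))
  expect_identical(unname(levelCounts(lib)["n1"]), 2L)
  ## brute-force cross-check over all singles
  refS <- scoreSequence(sc, "RGTFEGKF")
  expected <- Filter(function(m) {
    s <- peptideSequence(applyMutations("RGTFEGKF", m))
    scoreSequence(sc, s) > refS
  }, oracleSingles("RGTFEGKF"))
  expect_setequal(libraryMembers(lib)$mutations, expected)
})

test_that("a constant scorer yields an empty library", {
  flat <- scorer("flat", "higher", function(s) 1)
  lib <- initializeLibrary("RGTFEGKF", flat)
  expect_identical(libSize(lib), 0L)
  expect_true(all(levelCounts(lib) == 0L))
})

test_that("one combination cycle appends the compatible union", {
  sc <- gainScorer("RGTFEGKF", c(G2V = 2, F4W = 1))
  lib <- initializeLibrary("RGTFEGKF", sc)
  lib2 <- combinationCycle(lib, sc)
  expect_identical(libSize(lib2), 3L)
  m <- libraryMembers(lib2)
  expect_true("RVTWEGKF" %in% m$sequence)
  expect_identical(m$level[m$sequence == "RVTWEGKF"], 2L)
  expect_identical(m$cycle[m$sequence == "RVTWEGKF"], 1L)
  expect_equal(m$score[m$sequence == "RVTWEGKF"], 3)
  ## the input library is not modified in place
  expect_identical(libSize(lib), 2L)
})

test_that("same-position members produce no union", {
  sc <- gainScorer("RGTFEGKF", c(G2V = 2, G2I = 1))
  lib <- initializeLibrary("RGTFEGKF", sc)
  expect_identical(libSize(lib), 2L)
  lib2 <- combinationCycle(lib, sc)
  expect_identical(libSize(lib2), 2L)
  expect_identical(searchLog(lib2)$rej_conflict[2], 1L)
})

test_that("zero cycles returns the initialized library", {
  sc <- mockScorer("RGTF", seed = 3)
  expect_identical(
    memberTable(runSearch("RGTF", sc, config = searchConfig(maxCycles = 0))),
    memberTable(initializeLibrary("RGTF", sc)))
})

test_that("two cycles reach three- and four-point candidates", {
  gains <- c(G2V = 4, F4W = 3, G6V = 2, K7R = 1)
  sc <- gainScorer("RGTFEGKF", gains)
  lib <- runSearch("RGTFEGKF", sc)
  lc <- levelCounts(lib)
  ## all-positive additive gains at distinct positions: every union of
  ## accepted singles reachable within two cycles is accepted
  expect_identical(unname(lc), c(4L, 6L, 4L, 1L))
  expect_identical(libSize(lib), sum(lc))
  four <- libraryMembers(lib)[libraryMembers(lib)$level == 4L, ]
  expect_identical(four$sequence, "RVTWEVRF")
  expect_identical(four$cycle, 2L)
  expect_equal(four$score, 10)
})

test_that("level cap and target size stop the growth", {
  gains <- c(G2V = 4, F4W = 3, G6V = 2, K7R = 1)
  sc <- gainScorer("RGTFEGKF", gains)
  capped <- runSearch("RGTFEGKF", sc, config = searchConfig(maxLevel = 2))
  expect_true(all(libraryMembers(capped)$level <= 2L))
  sized <- runSearch("RGTFEGKF", sc,
                     config = searchConfig(targetSize = 4))
  expect_identical(libSize(sized), 4L)  # reached after initialization
})

test_that("veto predicate discards candidates like a failed pose check", {
  sc <- gainScorer("RGTFEGKF", c(G2V = 2, F4W = 1))
  noTrp <- function(p) !grepl("W", peptideSequence(p))
  lib <- runSearch("RGTFEGKF", sc, veto = noTrp)
  expect_identical(libSize(lib), 1L)
  expect_identical(libraryMembers(lib)$sequence, "RVTFEGKF")
})

test_that("duplicate unions update provenance without re-scoring", {
  gains <- c(G2V = 4, F4W = 3, G6V = 2)
  sc <- gainScorer("RGTFEGKF", gains)
  lib <- runSearch("RGTFEGKF", sc)
  m <- libraryMembers(lib)
  trip <- m[m$level == 3L, ]
  ## the 3-point member is reachable via three 1+2 and three 2+2 pairs
  expect_identical(nrow(trip), 1L)
  expect_identical(lengths(strsplit(trip$parents, ";")), 6L)
  expect_true(searchLog(lib)$rej_duplicate[3] > 0L)
})

test_that("library invariants hold on seeded mock searches", {
  for (seed in 1:10) {
    ref <- "RGTF"
    sc <- mockScorer(ref, seed = seed, interactionSd = 0.3)
    lib <- runSearch(ref, sc)
    m <- libraryMembers(lib)
    expect_false(anyDuplicated(m$sequence) > 0)
    expect_false(ref %in% m$sequence)
    expect_true(all(m$score > lib@referenceScore))
    expect_identical(sum(levelCounts(lib)), libSize(lib))
    expect_true(all(m$level <= 4L))
  }
})

test_that("searches are reproducible, including member order", {
  sc <- function() mockScorer("RGTFEGKF", seed = 17, interactionSd = 0.5)
  a <- runSearch("RGTFEGKF", sc())
  b <- runSearch("RGTFEGKF", sc())
  expect_identical(libraryMembers(a), libraryMembers(b))
  expect_identical(searchLog(a), searchLog(b))
})

test_that("search equals the independent recursion on seeded mock scorers", {
  set.seed(101)
  for (i in 1:25) {
    ref <- randomReference(sample(2:4, 1))
    sc <- mockScorer(ref, seed = i, interactionSd = 0.5)
    lib <- runSearch(ref, sc)
    orc <- oracleSearch(ref, function(s) scoreSequence(sc, s))
    expect_identical(lib@referenceScore, orc$refScore)
    got <- memberTable(lib)
    want <- orc$members
    rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("rescoring filters and ranks by the second scorer", {
  goldTab <- readScoreTable(table2Path("goldscore"))
  chem <- tableScorer(readScoreTable(table2Path("chemscore")))
  lib <- candidateLibrary("RGTFEGKF",
                          setdiff(names(goldTab@scores), "RGTFEGKF"),
                          tableScorer(goldTab))
  expect_identical(libSize(lib), 11L)
  ranked <- rescoreAndFilter(lib, chem)
  expect_identical(nrow(ranked), 11L)
  expect_identical(ranked$sequence[1:3],
                   c("RVTWEGKF", "RGTFEGRF", "RITFEIKF"))
  expect_true(all(diff(ranked$secondary) >= 0))  # best (most negative) first
  ## a second scorer that ties the reference everywhere keeps nothing
  tie <- scorer("tie", "lower", function(s) -7.13)
  expect_identical(nrow(rescoreAndFilter(lib, tie)), 0L)
})
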