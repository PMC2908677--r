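test_that("profile compilation expands N and validates its input", {
  p <- compileProfile("TGTANATA")
  sizes <- lengths(p@positions)
  expect_equal(sizes, c(1L, 1L, 1L, 1L, 4L, 1L, 1L, 1L))
  expect_equal(sort(p@positions[[5L]]), c("A", "C", "G", "T"))

  p2 <- compileProfile("AAAAAAAA")
  expect_true(all(lengths(p2@positions) == 1L))

  expect_error(compileProfile("TGTANAT"), "exactly 8")
  expect_error(compileProfile("TGTANATAX"), "exactly 8")
  expect_error(compileProfile("TGTAXATA"), "invalid profile symbol")
})

test_that("scanning finds exactly the admitted 8-mers, overlaps included", {
  p <- p3eProfile()
  expect_equal(scanSequence("TGTAAATA", p), 0L)
  expect_equal(scanSequence("CCCCCCCC", p), integer(0))
  expect_equal(scanSequence("TGTAAATATGTACATA", p), c(0L, 8L))
  ## N in the sequence matches nothing
  expect_equal(scanSequence("TGTANATA", p), integer(0))
  ## sequences shorter than the profile
  expect_equal(scanSequence("TGTA", p), integer(0))
  ## overlapping matches with a degenerate profile
  pA <- compileProfile("AAAAAAAA")
  expect_equal(scanSequence(strrep("A", 10L), pA), c(0L, 1L, 2L))
})

test_that("scanning agrees with the regex oracle on random sequences", {
  p <- p3eProfile()
  pat <- profileRegex("TGTANATA")
  set.seed(421)
  for (gc in c(0.2, 0.5)) {
    for (i in 1:75) {
      s <- randSeq(300L, gc)
      expect_identical(scanSequence(s, p), regexScanOracle(s, pat))
    }
  }
})

test_that("the reverse strand is never scanned", {
  p <- p3eProfile()
  ## reverse complement of an admitted 8-mer is not itself a match
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("TGTAAATA")))
  expect_equal(scanSequence(rc, p), integer(0))
})

test_that("window counting assigns by start and conserves totals", {
  m <- data.frame(gene_id = c("g1", "g1"), start = c(0L, 8L))
  wc <- countInWindows(m, c(g1 = 1000L))
  expect_equal(motifCounts(wc)[1L], 2L)  # independent events in one window
  expect_equal(sum(motifCounts(wc)), 2L)

  ## boundary: starts 49 and 50 fall in different windows
  m2 <- data.frame(gene_id = "g1", start = c(49L, 50L))
  wc2 <- countInWindows(m2, c(g1 = 1000L))
  expect_equal(motifCounts(wc2)[1:2], c(1L, 1L))

  ## no genes -> all zero
  wc0 <- countInWindows(data.frame(gene_id = character(0),
                                   start = integer(0)),
                        setNames(integer(0), character(0)))
  expect_true(all(motifCounts(wc0) == 0L))
  expect_true(all(eligiblePositions(wc0) == 0))

  expect_error(countInWindows(m, c(g1 = 1000L), windowSize = 0L),
               "positive")
  expect_error(countInWindows(m, c(g1 = 1000L), windowSize = 30L),
               "divide")
})

test_that("eligible start positions respect short sequences", {
  ## a 100 bp gene has 93 valid starts: 50 in window 1, 43 in window 2
  wc <- countInWindows(data.frame(gene_id = character(0),
                                  start = integer(0)),
                       c(g1 = 100L))
  expect_equal(eligiblePositions(wc)[1:3], c(50, 43, 0))
  ## a full-length gene: last window loses 7 starts
  wc2 <- countInWindows(data.frame(gene_id = character(0),
                                   start = integer(0)),
                        c(g1 = 1000L))
  expect_equal(eligiblePositions(wc2)[20L], 43)
  expect_equal(sum(eligiblePositions(wc2)), 993)
})

test_that("window count totals equal matches inside the region", {
  p <- p3eProfile()
  set.seed(99)
  for (i in 1:10) {
    seqs <- vapply(1:20, function(j) randSeq(sample(200:1000, 1L), 0.3),
                   character(1L))
    names(seqs) <- paste0("g", 1:20)
    m <- scanDownstream(Biostrings::DNAStringSet(seqs), p)
    wc <- countInWindows(m, nchar(seqs))
    expect_equal(sum(motifCounts(wc)), sum(m$start < 1000L))
    expect_true(all(eligiblePositions(wc) >= motifCounts(wc)))
  }
})

test_that("target calling requires the full element inside the UTR cutoff", {
  mk <- function(at) speciesDataset("sp", setNames(plantedSeq(1000L, at),
                                                   "g1"))
  p <- p3eProfile()
  ## start 242: element ends exactly at base 250 -> target
  expect_equal(targets(callTargets(mk(242L), p)), "g1")
  ## start 243: element ends at 251 -> not a target
  expect_equal(targets(callTargets(mk(243L), p)), character(0))
  ## no match at all
  ds <- speciesDataset("sp", c(g1 = strrep("C", 1000L)))
  expect_equal(targets(callTargets(ds, p)), character(0))
  ## but the 243-start gene is still in the universe
  expect_equal(geneUniverse(callTargets(mk(243L), p)), "g1")
})
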