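test_that("GC estimation pools bases and excludes N", {
  expect_equal(gcContent(estimateGC(Biostrings::DNAStringSet(
    c(g1 = "ACGT", g2 = "ACGT")))), 0.5)
  expect_equal(gcContent(estimateGC(Biostrings::DNAStringSet(
    c(g1 = "AAAA")))), 0)
  expect_equal(gcContent(estimateGC(Biostrings::DNAStringSet(
    c(g1 = "ANGC")))), 2 / 3)
  expect_error(estimateGC(Biostrings::DNAStringSet(c(g1 = "NNNN"))),
               "countable")

  ## utr250 uses only the first 250 bases
  s <- paste0(strrep("A", 250L), strrep("G", 750L))
  expect_equal(gcContent(estimateGC(Biostrings::DNAStringSet(c(g = s)),
                                    mode = "utr250")), 0)
  ## per_window returns one fraction per window
  gw <- estimateGC(Biostrings::DNAStringSet(c(g = s)), mode = "per_window")
  expect_length(gcContent(gw), 20L)
  expect_equal(gcContent(gw)[1:5], rep(0, 5))
  expect_equal(gcContent(gw)[6:20], rep(1, 15))
})

test_that("null generation is seed-deterministic and respects GC extremes", {
  gcm <- new("GCModel", mode = "full_region", gc = 0.4,
             windowSize = 50L, regionLength = 1000L)
  p <- p3eProfile()
  n1 <- generateNull(gcm, p, n = 300L, seed = 7L)
  n2 <- generateNull(gcm, p, n = 300L, seed = 7L)
  expect_identical(motifCounts(n1), motifCounts(n2))

  ## gc = 1: the AT-rich element cannot occur
  gc1 <- new("GCModel", mode = "full_region", gc = 1,
             windowSize = 50L, regionLength = 1000L)
  expect_equal(sum(motifCounts(generateNull(gc1, p, n = 200L, seed = 1L))),
               0L)

  ## random sequences reproduce byte-identically under the same seed
  expect_identical(as.character(randomSequences(5L, 100L, 0.4, seed = 3L)),
                   as.character(randomSequences(5L, 100L, 0.4, seed = 3L)))
})

test_that("closed-form match probability matches its definition", {
  p <- p3eProfile()
  ## the element has six fixed A/T sites, one fixed G site and one free
  ## site, so both GC extremes make it impossible
  expect_equal(profileMatchProbability(p, 0), 0)
  expect_equal(profileMatchProbability(p, 1), 0)
  gc <- 0.38
  expect_equal(profileMatchProbability(p, gc),
               (gc / 2) * ((1 - gc) / 2)^6)
  ## a profile without G/C content: probability (1/2)^7 at gc = 0
  pAT <- compileProfile("TATANATA")
  expect_equal(profileMatchProbability(pAT, 0), (1 / 2)^7)
})

test_that("expected null counts decrease with GC for the AT-rich element", {
  p <- p3eProfile()
  probs <- vapply(seq(0.2, 0.8, by = 0.1),
                  function(g) profileMatchProbability(p, g), numeric(1L))
  expect_true(all(diff(probs) < 0))
  ## and simulated counts follow at well-separated GC values
  totals <- vapply(c(0.2, 0.5, 0.8), function(g) {
    gcm <- new("GCModel", mode = "full_region", gc = g,
               windowSize = 50L, regionLength = 1000L)
    sum(motifCounts(generateNull(gcm, p, n = 1500L, seed = 11L)))
  }, numeric(1L))
  expect_true(all(diff(totals) < 0))
})

test_that("window enrichment p-values match the hypergeometric construction", {
  ## single-window geometry lets the 2x2 table be checked directly
  obs <- mkWindowCounts(10L, 1000, 50L, 50L)
  nul <- mkWindowCounts(10L, 10000, 50L, 50L)
  res <- windowEnrichmentTest(obs, nul)
  expect_equal(res$p_raw,
               hyperTailOracle(10L, K = 20L, n = 1000L, N = 11000L),
               tolerance = 1e-12)
  ## and Fisher's one-sided test agrees
  ft <- fisher.test(matrix(c(10L, 990L, 10L, 9990L), 2L, byrow = TRUE),
                    alternative = "greater")
  expect_equal(res$p_raw, ft$p.value, tolerance = 1e-12)

  ## zero observed -> p = 1
  res0 <- windowEnrichmentTest(mkWindowCounts(0L, 1000, 50L, 50L),
                               mkWindowCounts(0L, 10000, 50L, 50L))
  expect_equal(res0$p_raw, 1)

  ## Bonferroni is a plain multiplication, capped at 1
  res20 <- windowEnrichmentTest(obs, nul, nComparisons = 20L)
  expect_equal(res20$p_bonferroni, min(1, res20$p_raw * 20))

  ## corrupt counts (more matches than scannable starts) are rejected at
  ## construction
  expect_error(mkWindowCounts(10L, 5, 50L, 50L), "eligible")
})

test_that("GC regression validates input and recovers the negative trend", {
  p <- p3eProfile()
  mkSp <- function(id, gc, n = 250L) {
    set.seed(1000L + round(gc * 100))
    seqs <- vapply(seq_len(n), function(i) randSeq(1000L, gc),
                   character(1L))
    names(seqs) <- paste0(id, "_g", seq_len(n))
    speciesDataset(id, seqs)
  }
  sps <- lapply(seq(0.25, 0.55, length.out = 5L),
                function(g) mkSp(paste0("s", round(g * 100)), g))
  reg <- gcVsTargetRegression(sps, p)
  expect_lt(reg$slope, 0)
  expect_true(reg$r.squared > 0 && reg$r.squared <= 1)

  expect_error(gcVsTargetRegression(sps[1:2], p), "at least 3")
  same <- list(sps[[1L]], sps[[1L]], sps[[1L]])
  expect_error(gcVsTargetRegression(same, p), "zero variance")
})
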