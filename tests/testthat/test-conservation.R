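## helper: build TargetSet/OrthologMap lists from a logical gene x species
## presence/target specification
mkStudy <- function(present, target) {
  sp <- colnames(present)
  genes <- rownames(present)
  ts <- list(); om <- list()
  for (s in sp) {
    allIds <- paste0(s, "_", genes)
    spGenes <- allIds[present[, s]]
    om[[s]] <- orthologMap(data.frame(
      species_gene = spGenes,
      reference_gene = genes[present[, s]]), s)
    ts[[s]] <- new("TargetSet", speciesId = s,
                   targets = allIds[target[, s] & present[, s]],
                   universe = spGenes, utrCutoff = 250L)
  }
  list(ts = ts, om = om)
}

test_that("conservation states and row scores follow the any-ortholog rule", {
  genes <- c("R1", "R2", "R3")
  sp <- paste0("s", 1:10)
  present <- matrix(TRUE, 3, 10, dimnames = list(genes, sp))
  target <- matrix(FALSE, 3, 10, dimnames = list(genes, sp))
  target["R1", 1:8] <- TRUE          # 8 of 10 -> score 0.8
  present["R2", 6:10] <- FALSE       # present in 5, target in 2 -> 0.4
  target["R2", 1:2] <- TRUE
  st <- mkStudy(present, target)
  cm <- buildConservationMatrix(genes, st$ts, st$om)
  expect_equal(rowScores(cm)[rownames(conservationStates(cm)) == "R1"], 0.8)
  expect_equal(rowScores(cm)[rownames(conservationStates(cm)) == "R2"], 0.4)
  expect_equal(unname(conservationStates(cm)["R2", "s7"]), "A")
  expect_equal(unname(conservationStates(cm)["R3", "s1"]), "P")
  ## rows sorted by decreasing score
  expect_equal(rownames(conservationStates(cm)), c("R1", "R2", "R3"))
})

test_that("a gene absent everywhere is dropped with a warning", {
  genes <- c("R1", "R2")
  present <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2, byrow = TRUE,
                    dimnames = list(genes, c("s1", "s2")))
  target <- matrix(FALSE, 2, 2, dimnames = list(genes, c("s1", "s2")))
  st <- mkStudy(present, target)
  expect_warning(cm <- buildConservationMatrix(genes, st$ts, st$om),
                 "absent from every species")
  expect_equal(nrow(conservationStates(cm)), 1L)
})

test_that("any paralog being a target marks the cell as target", {
  om <- list(s1 = orthologMap(data.frame(
    species_gene = c("s1_a", "s1_b"),
    reference_gene = c("R1", "R1")), "s1"))
  ts <- list(s1 = new("TargetSet", speciesId = "s1", targets = "s1_b",
                      universe = c("s1_a", "s1_b"), utrCutoff = 250L))
  cm <- buildConservationMatrix("R1", ts, om)
  expect_equal(unname(conservationStates(cm)["R1", "s1"]), "T")
})

test_that("the matrix is invariant to species and gene-set order", {
  genes <- sprintf("R%02d", 1:20)
  sp <- paste0("s", 1:6)
  set.seed(5)
  present <- matrix(runif(120) < 0.9, 20, 6, dimnames = list(genes, sp))
  target <- present & matrix(runif(120) < 0.4, 20, 6)
  st <- mkStudy(present, target)
  cm1 <- buildConservationMatrix(genes, st$ts, st$om)
  cm2 <- buildConservationMatrix(rev(genes), st$ts[c(4:6, 1:3)],
                                 st$om[c(4:6, 1:3)])
  expect_equal(rowScores(cm1), rowScores(cm2))
  expect_equal(conservationStates(cm1)[, sp],
               conservationStates(cm2)[, sp])
})

test_that("sliding fractions recover planted functional structure", {
  ## top tier: 100 genes conserved at 0.9, 80% in the function set;
  ## bottom tier: 150 genes at 0.1, 4% in the set
  genes <- sprintf("R%03d", 1:250)
  sp <- paste0("s", 1:12)
  set.seed(31)
  rate <- c(rep(0.9, 100), rep(0.1, 150))
  present <- matrix(TRUE, 250, 12, dimnames = list(genes, sp))
  target <- matrix(runif(250 * 12) < rate, 250, 12,
                   dimnames = list(genes, sp))
  inSet <- c(sample(1:100, 80), sample(101:250, 6))
  st <- mkStudy(present, target)
  cm <- buildConservationMatrix(genes, st$ts, st$om)
  sf <- slidingFunctionFraction(cm, genes[inSet], window = 50L)
  expect_gt(sf$fraction[1L], 0.65)
  expect_lt(sf$fraction[nrow(sf)], 0.15)

  ## degenerate windows
  expect_equal(slidingFunctionFraction(cm, genes, window = 250L)$fraction,
               1)
  all250 <- slidingFunctionFraction(cm, genes[inSet], window = 250L)
  expect_equal(all250$fraction, length(inSet) / 250)
  expect_error(slidingFunctionFraction(cm, genes, window = 0L), "> 0")
  expect_error(slidingFunctionFraction(cm, genes, window = 300L),
               "exceeds")
})

test_that("sliding fractions over random labels show no trend", {
  genes <- sprintf("R%03d", 1:200)
  sp <- paste0("s", 1:8)
  ## overlapping windows autocorrelate strongly, so individual rank
  ## correlations are noisy; under the null their signed mean is centred
  ## on zero
  rhos <- vapply(1:20, function(r) {
    set.seed(r)
    present <- matrix(TRUE, 200, 8, dimnames = list(genes, sp))
    target <- matrix(runif(1600) < 0.5, 200, 8,
                     dimnames = list(genes, sp))
    st <- mkStudy(present, target)
    cm <- buildConservationMatrix(genes, st$ts, st$om)
    fset <- sample(genes, 60)  # labels independent of conservation
    sf <- slidingFunctionFraction(cm, fset, window = 50L)
    suppressWarnings(cor(sf$window_start, sf$fraction,
                         method = "spearman"))
  }, numeric(1L))
  expect_lt(abs(mean(rhos)), 0.4)
})
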