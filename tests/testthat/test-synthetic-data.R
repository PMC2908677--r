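test_that("simulated fixtures satisfy every container validator", {
  cfg <- simulationConfig(nSpeciesPerClade = c(2L, 2L), nGenes = 150L,
                          nMito = 45L, nCore = 18L, nRibosomal = 10L,
                          seed = 3L)
  for (i in 1:4) {
    sim <- simulateSpecies(cfg, i)
    expect_true(validObject(sim$dataset))
    expect_true(validObject(sim$orthologs))
    expect_length(sim$planted, 150L)
  }
  expect_true(validObject(referenceAnnotation(cfg)))
  expect_error(simulationConfig(nGenes = 100L, nMito = 200L), "nMito")
})

test_that("generated GC content tracks the configured value", {
  cfg <- simulationConfig(nSpeciesPerClade = c(1L, 1L), nGenes = 500L,
                          nMito = 0L, nCore = 0L, nRibosomal = 0L,
                          gc = c(0.42, 0.42), seed = 9L)
  sim <- simulateSpecies(cfg, 1, components = "downstream")
  gcm <- estimateGC(sim$dataset)
  expect_lt(abs(gcContent(gcm) - 0.42), 0.01)
})

test_that("planting rate 1 makes every designated gene a called target", {
  cfg <- simulationConfig(nSpeciesPerClade = c(1L, 1L), nGenes = 200L,
                          nMito = 80L, nCore = 80L,
                          mitoCoreRate = c(1, 0), backgroundRate = c(0, 0),
                          mitoPeripheralRate = c(0, 0), nRibosomal = 0L,
                          seed = 21L)
  sim <- simulateSpecies(cfg, 1, components = "downstream")
  ts <- callTargets(sim$dataset, p3eProfile())
  designated <- names(downstreamSeqs(sim$dataset))[sim$planted]
  expect_true(all(designated %in% targets(ts)))
})

test_that("with no planting, target counts match the chance-match closed form", {
  gc <- 0.5
  cfg <- simulationConfig(nSpeciesPerClade = c(1L, 1L), nGenes = 1000L,
                          nMito = 0L, nCore = 0L, nRibosomal = 0L,
                          backgroundRate = c(0, 0), gc = c(gc, gc),
                          seed = 33L)
  sim <- simulateSpecies(cfg, 1, components = "downstream")
  ts <- callTargets(sim$dataset, p3eProfile())
  p <- profileMatchProbability(p3eProfile(), gc)
  q <- 1 - (1 - p)^243  # 243 admissible starts in the first 250 bp
  expect_lt(abs(length(targets(ts)) - 1000 * q),
            3 * sqrt(1000 * q * (1 - q)) + 1)
})

test_that("the same master seed reproduces the study bundle byte for byte", {
  cfg <- simulationConfig(nSpeciesPerClade = c(1L, 1L), nGenes = 60L,
                          nMito = 20L, nCore = 8L, nRibosomal = 6L,
                          nConditions = 5L, seed = 12L)
  d1 <- file.path(tempdir(), "bundleA")
  d2 <- file.path(tempdir(), "bundleB")
  unlink(c(d1, d2), recursive = TRUE)
  writeSimulatedStudy(cfg, d1)
  writeSimulatedStudy(cfg, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_setequal(f1, list.files(d2, recursive = TRUE))
  for (f in f1)
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))), label = f)
})

test_that("expression blocks realise the configured correlation and shift", {
  cfg <- simulationConfig(nConditions = 1011L, rho = 0.5, delta = 1.0,
                          seed = 44L)
  withG <- sprintf("R%04d", 1:60)
  withoutG <- sprintf("R%04d", 61:120)
  X <- simulateExpression(cfg, withG, withoutG)
  pc <- pairwiseCorrelations(X, withG, withoutG)
  expect_lt(abs(mean(pc$within_a) - 0.5), 0.05)
  expect_lt(abs(mean(pc$within_b)), 0.05)
  ## the fermentative condition carries the down-shift for the motif group
  rcW <- classifyRegulation(X, cfg$fermentCondition, withG)
  rcWo <- classifyRegulation(X, cfg$fermentCondition, withoutG)
  expect_gt(rcW$n_down / rcW$n_genes, rcWo$n_down / rcWo$n_genes)

  ## rho = 0: mean absolute correlation shrinks with many conditions
  cfg0 <- simulationConfig(nConditions = 400L, rho = 0, delta = 0,
                           seed = 45L)
  X0 <- simulateExpression(cfg0, withG, withoutG)
  pc0 <- pairwiseCorrelations(X0, withG, withoutG)
  expect_lt(abs(mean(pc0$within_a)), 0.05)
  expect_error(simulateExpression(cfg, withG, withG), "disjoint")
})

test_that("fitness tables are seed-stable and carry the planted deficit", {
  cfg <- simulationConfig(fitnessEffect = 1.0, seed = 50L)
  withG <- sprintf("R%04d", 1:150)
  withoutG <- sprintf("R%04d", 151:300)
  f1 <- simulateFitness(cfg, withG, withoutG)
  f2 <- simulateFitness(cfg, withG, withoutG)
  expect_identical(f1, f2)
  nf <- f1[f1$condition == "non_fermentative", ]
  cmp <- groupCompare(nf$relative_growth[nf$gene %in% withG],
                      nf$relative_growth[nf$gene %in% withoutG])
  expect_lt(cmp$p.value, 0.01)
  expect_lt(cmp$meanA, cmp$meanB)
  ## zero effect: the fermentative condition shows no planted difference
  fm <- f1[f1$condition == "fermentative", ]
  cmp0 <- groupCompare(fm$relative_growth[fm$gene %in% withG],
                       fm$relative_growth[fm$gene %in% withoutG])
  expect_gt(cmp0$p.value, 0.001)
})
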