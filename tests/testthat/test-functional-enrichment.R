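test_that("category mapping inherits compartments through orthology", {
  om <- orthologMap(data.frame(
    species_gene = c("gX", "gY", "gZ", "gZ"),
    reference_gene = c("R1", "R9", "R1", "R2")), "spA")
  ann <- annotationTable(localization = c(R1 = "mitochondrion",
                                          R2 = "nucleus"))
  m <- mapCategories(om, ann)
  expect_equal(m$compartment[m$species_gene == "gX"], "mitochondrion")
  ## gY's ortholog is unannotated -> unassigned
  expect_false("gY" %in% m$species_gene)
  ## two orthologs in different compartments -> both memberships retained
  expect_setequal(m$compartment[m$species_gene == "gZ"],
                  c("mitochondrion", "nucleus"))
  ## best policy keeps only the first reference gene's compartments
  mb <- mapCategories(om, ann, policy = "best")
  expect_equal(mb$compartment[mb$species_gene == "gZ"], "mitochondrion")
})

test_that("hypergeometric category test reproduces direct combinatorics", {
  ## genome of 100 genes, 20 targets; category of 10 genes, all targets
  universe <- sprintf("g%03d", 1:100)
  ts <- new("TargetSet", speciesId = "spA", targets = universe[1:20],
            universe = universe, utrCutoff = 250L)
  cats <- data.frame(species_gene = universe[1:10],
                     compartment = "mitochondrion")
  res <- categoryTest(ts, cats)
  expect_equal(res$p_raw, choose(20, 10) / choose(100, 10),
               tolerance = 1e-12)
  expect_equal(res$n_category_targets, 10L)

  ## category = genome with equal counts -> p = 1
  catAll <- data.frame(species_gene = universe, compartment = "everything")
  expect_equal(categoryTest(ts, catAll)$p_raw, 1)

  ## zero targets genome-wide -> p = 1 for every category
  ts0 <- new("TargetSet", speciesId = "spA", targets = character(0),
             universe = universe, utrCutoff = 250L)
  expect_true(all(categoryTest(ts0, cats)$p_raw == 1))
})

test_that("hypergeometric p equals one-sided Fisher on the same table", {
  set.seed(77)
  for (i in 1:20) {
    N <- sample(50:400, 1L)
    K <- sample(5:(N / 2), 1L)
    n <- sample(5:(N / 2), 1L)
    universe <- sprintf("g%04d", seq_len(N))
    ts <- new("TargetSet", speciesId = "s", targets = sample(universe, K),
              universe = universe, utrCutoff = 250L)
    cats <- data.frame(species_gene = sample(universe, n),
                       compartment = "cat")
    p <- categoryTest(ts, cats)$p_raw
    k <- length(intersect(cats$species_gene, targets(ts)))
    tab <- matrix(c(k, n - k, K - k, N - K - (n - k)), 2L)
    expect_equal(p, fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-10)
  }
})

test_that("clade fraction comparison behaves at the degenerate point and detects planted effects", {
  f <- c(a1 = 0.5, a2 = 0.5, b1 = 0.5, b2 = 0.5)
  g <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  res <- cladeFractionCompare(f, g)
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 1)

  expect_error(cladeFractionCompare(c(a1 = 0.4, b1 = 0.2, b2 = 0.3),
                                    c(a1 = "A", b1 = "B", b2 = "B")),
               "at least 2")

  ## planted rates 0.5 vs 0.1, 10 species each, 300 mito genes
  set.seed(11)
  hits <- 0L
  for (r in 1:50) {
    fa <- rbinom(10L, 300L, 0.5) / 300
    fb <- rbinom(10L, 300L, 0.1) / 300
    fr <- setNames(c(fa, fb), paste0("s", 1:20))
    gr <- setNames(rep(c("high", "low"), each = 10L), names(fr))
    if (cladeFractionCompare(fr, gr)$p.value < 0.01) hits <- hits + 1L
  }
  expect_gte(hits, 48L)
})

test_that("only the planted category is enriched in a simulated species", {
  cfg <- simulationConfig(nSpeciesPerClade = c(1L, 1L), nGenes = 600L,
                          nMito = 180L, nCore = 72L, nRibosomal = 20L,
                          seed = 2024L)
  sim <- simulateSpecies(cfg, 1, components = "downstream")
  ts <- callTargets(sim$dataset, p3eProfile())
  cats <- mapCategories(sim$orthologs, referenceAnnotation(cfg))
  res <- categoryTest(ts, cats)
  sig <- res$category[res$p_bonferroni < 0.01]
  expect_equal(sig, "mitochondrion")
  ## counts re-derivable by brute-force recount
  mito <- cats$species_gene[cats$compartment == "mitochondrion"]
  row <- res[res$category == "mitochondrion", ]
  expect_equal(row$n_category, length(unique(mito)))
  expect_equal(row$n_category_targets,
               length(intersect(unique(mito), targets(ts))))
  expect_equal(row$n_genome, length(geneUniverse(ts)))
})
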