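## End-to-end orchestration: scan -> null -> window enrichment -> target
## calling -> category enrichment -> clade comparison -> conservation ->
## CAI -> expression -> fitness, driven by a study bundle on disk (the
## layout written by writeSimulatedStudy) and a single seed. Every result is
## written as TSV; a JSON run manifest records the configuration.

.readStudy <- function(studyDir) {
  manifestPath <- file.path(studyDir, "manifest.json")
  if (!file.exists(manifestPath))
    stop("no manifest.json in ", studyDir, call. = FALSE)
  manifest <- jsonlite::read_json(manifestPath, simplifyVector = TRUE)
  sp <- manifest$species
  datasets <- list(); orthologs <- list()
  for (i in seq_len(nrow(sp))) {
    sid <- sp$species_id[i]
    down <- readFasta(file.path(studyDir, "species",
                                paste0(sid, "_downstream.fasta")))
    cds <- readFasta(file.path(studyDir, "species",
                               paste0(sid, "_cds.fasta")))
    datasets[[sid]] <- speciesDataset(sid, down, cds, clade = sp$clade[i],
                                      regionLength = manifest$region_length)
    orthologs[[sid]] <- readOrthologMap(
      file.path(studyDir, "species", paste0(sid, "_orthologs.tsv")), sid)
  }
  loc <- readLocalization(file.path(studyDir, manifest$files$localization))
  fsets <- readFunctionSets(file.path(studyDir, manifest$files$function_sets))
  ribo <- readTable(file.path(studyDir, manifest$files$ribosomal_reference),
                    "gene")$gene
  exprPath <- file.path(studyDir, manifest$files$expression)
  fitPath <- file.path(studyDir, manifest$files$fitness)
  list(manifest = manifest, species = sp, datasets = datasets,
       orthologs = orthologs,
       annotation = annotationTable(localization = loc,
                                    functionSets = fsets),
       ribosomalReference = as.character(ribo),
       expression = if (file.exists(exprPath))
         readExpressionMatrix(exprPath) else NULL,
       fitness = if (file.exists(fitPath))
         readFitnessTable(fitPath) else NULL)
}

## species genes orthologous to a set of reference genes
.mapToSpecies <- function(orthologs, referenceGenes) {
  p <- orthologs@pairs
  unique(p$species_gene[p$reference_gene %in% referenceGenes])
}

## reference genes orthologous to a set of species genes
.mapToReference <- function(orthologs, speciesGenes) {
  p <- orthologs@pairs
  unique(p$reference_gene[p$species_gene %in% speciesGenes])
}

#' Run the full regulon-evolution pipeline on a study bundle
#'
#' Executes every analysis stage on the inputs under `studyDir` (the layout
#' produced by [writeSimulatedStudy()]) and writes one TSV per result table
#' plus a JSON run manifest into `outDir`. Stages relying on optional
#' inputs (expression, fitness) are skipped when the files are absent.
#'
#' @param studyDir directory holding the input bundle and its
#'   `manifest.json`.
#' @param outDir output directory (created if needed).
#' @param profile profile string for the binding element.
#' @param regionLength,windowSize,utrCutoff scan geometry in bp.
#' @param nNull number of random background sequences per species.
#' @param alpha significance level for corrected p-values.
#' @param fold expression fold-change threshold.
#' @param gcMode GC background dialect for the null model
#'   (`"full_region"`, `"utr250"` or `"per_window"`).
#' @param bonferroniScope `"species"` corrects window tests over windows
#'   within a species; `"global"` over windows x species.
#' @param corMethod correlation method for co-expression.
#' @param stages character vector of stages to run (any of `"scan"`,
#'   `"windows"`, `"regression"`, `"categories"`, `"conservation"`,
#'   `"cai"`, `"expression"`, `"fitness"`).
#' @param seed integer seed governing the null-sequence streams.
#' @return invisibly, a list with every stage's in-memory results.
#' @export
runPipeline <- function(studyDir, outDir,
                        profile = "TGTANATA",
                        regionLength = 1000L, windowSize = 50L,
                        utrCutoff = 250L, nNull = 10000L, alpha = 0.01,
                        fold = 1.5,
                        gcMode = c("full_region", "utr250", "per_window"),
                        bonferroniScope = c("species", "global"),
                        corMethod = c("pearson", "spearman"),
                        stages = c("scan", "windows", "regression",
                                   "categories", "conservation", "cai",
                                   "expression", "fitness"),
                        seed = 1L) {
  gcMode <- match.arg(gcMode)
  bonferroniScope <- match.arg(bonferroniScope)
  corMethod <- match.arg(corMethod)
  stages <- match.arg(stages, several.ok = TRUE)
  ## every analysis stage consumes the scan's target sets
  if (length(setdiff(stages, "scan"))) stages <- union("scan", stages)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  logStage <- function(name, ...) {
    message(sprintf("[%7.1fs] %-12s %s", proc.time()[["elapsed"]] - t0,
                    name, paste0(...)))
  }
  study <- .readStudy(studyDir)
  prof <- compileProfile(profile)
  sids <- names(study$datasets)
  cladeOf <- setNames(study$species$clade, study$species$species_id)
  res <- list()

  ## -- scan and target calling ------------------------------------------
  if ("scan" %in% stages) {
    matches <- list(); targetSets <- list(); observed <- list()
    for (sid in sids) {
      ds <- study$datasets[[sid]]
      m <- scanDownstream(ds, prof)
      matches[[sid]] <- m
      observed[[sid]] <- countInWindows(
        m, setNames(width(downstreamSeqs(ds)), names(downstreamSeqs(ds))),
        windowSize, regionLength)
      targetSets[[sid]] <- callTargets(ds, prof, utrCutoff)
      logStage("scan", sid, ": ", nrow(m), " matches, ",
               length(targets(targetSets[[sid]])), " targets")
    }
    allMatches <- do.call(rbind, Map(function(sid, m)
      data.frame(species_id = sid, m), sids, matches))
    writeResultTable(allMatches, file.path(outDir, "matches.tsv"))
    targetTab <- do.call(rbind, lapply(targetSets, function(ts)
      data.frame(species_id = ts@speciesId, gene_id = ts@targets)))
    writeResultTable(targetTab, file.path(outDir, "targets.tsv"))
    res$targetSets <- targetSets
    res$observedCounts <- observed
  }

  ## -- GC-matched null and per-window enrichment ------------------------
  if ("windows" %in% stages) {
    nWindows <- regionLength %/% windowSize
    nComp <- if (bonferroniScope == "global") nWindows * length(sids)
             else nWindows
    enr <- lapply(sids, function(sid) {
      gcm <- estimateGC(study$datasets[[sid]], gcMode, windowSize,
                        regionLength)
      nullCounts <- generateNull(gcm, prof, n = nNull,
                                 length = regionLength,
                                 seed = .deriveSeed(seed, "null", sid),
                                 windowSize = windowSize)
      cbind(species_id = sid,
            windowEnrichmentTest(res$observedCounts[[sid]], nullCounts,
                                 alpha = alpha, nComparisons = nComp))
    })
    enr <- do.call(rbind, enr)
    writeResultTable(enr, file.path(outDir, "window_enrichment.tsv"))
    logStage("windows", sum(enr$significant), " significant windows of ",
             nrow(enr))
    res$windowEnrichment <- enr
  }

  ## -- GC versus motif-gene-count regression ----------------------------
  if ("regression" %in% stages) {
    reg <- gcVsTargetRegression(study$datasets, prof, utrCutoff)
    writeResultTable(data.frame(slope = reg$slope,
                                intercept = reg$intercept,
                                r_squared = reg$r.squared,
                                p.value = reg$p.value),
                     file.path(outDir, "gc_regression.tsv"))
    writeResultTable(reg$data, file.path(outDir, "gc_regression_points.tsv"))
    logStage("regression", "slope = ", signif(reg$slope, 4))
    res$gcRegression <- reg
  }

  ## -- localization-category enrichment and clade comparison ------------
  if ("categories" %in% stages) {
    catTab <- do.call(rbind, lapply(sids, function(sid) {
      cats <- mapCategories(study$orthologs[[sid]], study$annotation)
      categoryTest(res$targetSets[[sid]], cats, alpha = alpha)
    }))
    writeResultTable(catTab, file.path(outDir, "category_enrichment.tsv"))
    mitoRef <- names(localization(study$annotation))[
      localization(study$annotation) == "mitochondrion"]
    frac <- vapply(sids, function(sid) {
      mg <- .mapToSpecies(study$orthologs[[sid]], mitoRef)
      mg <- intersect(mg, geneUniverse(res$targetSets[[sid]]))
      length(intersect(mg, targets(res$targetSets[[sid]]))) / length(mg)
    }, numeric(1L))
    cmp <- cladeFractionCompare(frac, cladeOf)
    writeResultTable(data.frame(species_id = sids, clade = cladeOf[sids],
                                mito_target_fraction = frac),
                     file.path(outDir, "mito_target_fractions.tsv"))
    writeResultTable(data.frame(statistic = cmp$statistic,
                                p.value = cmp$p.value, df = cmp$df,
                                mean_clade1 = cmp$groupMeans[1L],
                                mean_clade2 = cmp$groupMeans[2L]),
                     file.path(outDir, "clade_comparison.tsv"))
    logStage("categories", "clade comparison p = ",
             signif(cmp$p.value, 3))
    res$categoryEnrichment <- catTab
    res$mitoTargetFractions <- frac
    res$cladeComparison <- cmp
  }

  ## -- conservation matrix over the first clade --------------------------
  if ("conservation" %in% stages) {
    clade1 <- study$species$species_id[
      study$species$clade == study$species$clade[1L]]
    mitoRef <- names(localization(study$annotation))[
      localization(study$annotation) == "mitochondrion"]
    cm <- buildConservationMatrix(mitoRef,
                                  res$targetSets[clade1],
                                  study$orthologs[clade1])
    states <- conservationStates(cm)
    writeResultTable(data.frame(gene = rownames(states),
                                row_score = rowScores(cm),
                                as.data.frame(states, optional = TRUE),
                                check.names = FALSE),
                     file.path(outDir, "conservation_matrix.tsv"))
    fset <- functionSets(study$annotation)[["mitochondrial_translation"]]
    win <- min(50L, nrow(states))
    sf <- slidingFunctionFraction(cm, fset, window = win)
    writeResultTable(sf, file.path(outDir, "conservation_fractions.tsv"))
    logStage("conservation", nrow(states), " ortholog groups; top fraction ",
             round(sf$fraction[1L], 3))
    res$conservation <- cm
    res$slidingFractions <- sf
  }

  ## -- codon adaptation index -------------------------------------------
  if ("cai" %in% stages) {
    mitoRef <- names(localization(study$annotation))[
      localization(study$annotation) == "mitochondrion"]
    caiZ <- list()  # pooled per-gene z values by clade x group
    caiRows <- list()
    for (sid in sids) {
      ds <- study$datasets[[sid]]
      om <- study$orthologs[[sid]]
      riboGenes <- .mapToSpecies(om, study$ribosomalReference)
      riboGenes <- intersect(riboGenes, names(cdsSeqs(ds)))
      w <- referenceWeights(cdsSeqs(ds)[riboGenes])
      caiAll <- cai(cdsSeqs(ds), w)
      z <- standardizeCai(caiAll)
      mg <- intersect(.mapToSpecies(om, mitoRef), names(caiAll))
      isTgt <- mg %in% targets(res$targetSets[[sid]])
      for (g in c("with_element", "without_element")) {
        key <- paste(cladeOf[[sid]], g, sep = ".")
        gz <- z[mg[if (g == "with_element") isTgt else !isTgt]]
        caiZ[[key]] <- c(caiZ[[key]], unname(gz))
      }
      caiRows[[sid]] <- data.frame(
        species_id = sid, clade = cladeOf[[sid]],
        group = c("with_element", "without_element"),
        n = c(sum(isTgt), sum(!isTgt)),
        mean_cai = c(mean(caiAll[mg[isTgt]]), mean(caiAll[mg[!isTgt]])),
        mean_cai_z = c(mean(z[mg[isTgt]]), mean(z[mg[!isTgt]])))
    }
    caiTab <- do.call(rbind, caiRows)
    writeResultTable(caiTab, file.path(outDir, "cai_species.tsv"))
    cl <- unique(study$species$clade)
    caiCmp <- do.call(rbind, lapply(
      c("with_element", "without_element"), function(g) {
        cc <- groupCompare(caiZ[[paste(cl[1L], g, sep = ".")]],
                           caiZ[[paste(cl[2L], g, sep = ".")]])
        data.frame(group = g, statistic = cc$statistic,
                   p.value = cc$p.value,
                   mean_clade1 = cc$meanA, mean_clade2 = cc$meanB)
      }))
    writeResultTable(caiCmp, file.path(outDir, "cai_comparison.tsv"))
    logStage("cai", "with-element clade contrast p = ",
             signif(caiCmp$p.value[1L], 3))
    res$caiSpecies <- caiTab
    res$caiComparison <- caiCmp
  }

  ## -- expression association and co-expression -------------------------
  if ("expression" %in% stages && !is.null(study$expression)) {
    X <- study$expression
    mitoRef <- names(localization(study$annotation))[
      localization(study$annotation) == "mitochondrion"]
    focal <- sids[1L]
    focalTargets <- .mapToReference(study$orthologs[[focal]],
                                    targets(res$targetSets[[focal]]))
    mitoExpr <- intersect(mitoRef, rownames(X))
    withG <- intersect(mitoExpr, focalTargets)
    withoutG <- setdiff(mitoExpr, withG)
    ferm <- study$manifest$ferment_condition
    cw <- classifyRegulation(X, ferm, withG, fold)
    cwo <- classifyRegulation(X, ferm, withoutG, fold)
    assoc <- regulationAssociation(cw, cwo)
    writeResultTable(data.frame(group = c("with_element", "without_element"),
                                n_down = c(cw$n_down, cwo$n_down),
                                n_up = c(cw$n_up, cwo$n_up),
                                n_unchanged = c(cw$n_unchanged,
                                                cwo$n_unchanged),
                                down_up_ratio = c(assoc$ratio_with,
                                                  assoc$ratio_without)),
                     file.path(outDir, "regulation_counts.tsv"))
    writeResultTable(data.frame(odds_ratio = assoc$odds.ratio,
                                p.value = assoc$p.value),
                     file.path(outDir, "regulation_association.tsv"))
    pc <- pairwiseCorrelations(X, withG, withoutG, method = corMethod)
    corTab <- data.frame(pair_type = rep(c("within_with", "within_without",
                                           "between"),
                                         c(length(pc$within_a),
                                           length(pc$within_b),
                                           length(pc$between))),
                         r = c(pc$within_a, pc$within_b, pc$between))
    writeResultTable(corTab, file.path(outDir, "correlations.tsv"))
    ttWW <- groupCompare(pc$within_a, pc$within_b)
    ttWB <- groupCompare(pc$within_a, pc$between)
    writeResultTable(data.frame(contrast = c("within_with_vs_within_without",
                                             "within_with_vs_between"),
                                statistic = c(ttWW$statistic,
                                              ttWB$statistic),
                                p.value = c(ttWW$p.value, ttWB$p.value),
                                mean_a = c(ttWW$meanA, ttWB$meanA),
                                mean_b = c(ttWW$meanB, ttWB$meanB)),
                     file.path(outDir, "correlation_comparison.tsv"))
    logStage("expression", "association p = ", signif(assoc$p.value, 3))
    res$regulation <- list(with = cw, without = cwo, association = assoc)
    res$correlations <- pc
    res$correlationComparison <- list(within = ttWW, between = ttWB)
  }

  ## -- deletion fitness ---------------------------------------------------
  if ("fitness" %in% stages && !is.null(study$fitness)) {
    fit <- study$fitness
    mitoRef <- names(localization(study$annotation))[
      localization(study$annotation) == "mitochondrion"]
    focal <- sids[1L]
    focalTargets <- .mapToReference(study$orthologs[[focal]],
                                    targets(res$targetSets[[focal]]))
    fitCmp <- do.call(rbind, lapply(unique(fit$condition), function(cc) {
      sub <- fit[fit$condition == cc & fit$gene %in% mitoRef, ]
      a <- sub$relative_growth[sub$gene %in% focalTargets]
      b <- sub$relative_growth[!sub$gene %in% focalTargets]
      g <- groupCompare(a, b)
      data.frame(condition = cc, statistic = g$statistic,
                 p.value = g$p.value, mean_with = g$meanA,
                 mean_without = g$meanB)
    }))
    writeResultTable(fitCmp, file.path(outDir, "fitness_comparison.tsv"))
    logStage("fitness", "non-fermentative p = ",
             signif(fitCmp$p.value[fitCmp$condition ==
                                     "non_fermentative"][1L], 3))
    res$fitnessComparison <- fitCmp
  }

  runManifest <- list(study_dir = "input", seed = seed, profile = profile,
                      region_length = regionLength,
                      window_size = windowSize, utr_cutoff = utrCutoff,
                      n_null = nNull, alpha = alpha, fold = fold,
                      gc_mode = gcMode, bonferroni_scope = bonferroniScope,
                      cor_method = corMethod, stages = stages,
                      package_version =
                        as.character(packageVersion("PufRegulon")))
  jsonlite::write_json(runManifest, file.path(outDir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}

#' Simulate the demo study and run the full pipeline on it
#'
#' Writes the simulated input bundle to `<dir>/input` and every analysis
#' result to `<dir>/results`.
#'
#' @param dir working directory for the run.
#' @param seed master seed for both simulation and analysis.
#' @param config optional `SimulationConfig`; defaults to the demo
#'   configuration (two clades of 5 species, 1000 genes of which 300
#'   mitochondrial) under the given seed.
#' @param ... further arguments passed to [runPipeline()].
#' @return invisibly, the [runPipeline()] result list.
#' @export
runDemo <- function(dir, seed = 1L,
                    config = simulationConfig(seed = seed), ...) {
  inputDir <- file.path(dir, "input")
  writeSimulatedStudy(config, inputDir)
  runPipeline(inputDir, file.path(dir, "results"),
              profile = config$profile,
              regionLength = config$downstreamLength, seed = seed, ...)
}
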