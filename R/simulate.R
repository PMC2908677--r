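## Seedable multi-species simulator. Generates every input the pipeline
## consumes — downstream sequences with planted motifs, CDS with controlled
## codon bias, ortholog and annotation tables, block-correlated expression,
## and deletion fitness — with all randomness flowing from one master seed
## through per-stage derived streams.

#' Simulation configuration
#'
#' Defines the study conditions for the synthetic multi-species bundle. Two
#' clades are simulated; the first (post-WGD, Saccharomycotina-like) plants
#' the motif in mitochondrial genes at a high mean rate (~0.5), split into a
#' highly conserved core (rate 0.9) and a peripheral tier (rate 0.23) so the
#' conservation ranking has genuine high/low structure; the second clade
#' plants at the background rate throughout. Reference genes are laid out as
#' mitochondrial genes first (core then peripheral), then ribosomal genes
#' (the CAI reference set), then background genes.
#'
#' @param nSpeciesPerClade integer(2), species per clade.
#' @param cladeLabels character(2) clade tags; the first is the post-WGD
#'   clade.
#' @param mitoCoreRate,mitoPeripheralRate,backgroundRate numeric(2) per-clade
#'   motif planting probabilities for core-mito, peripheral-mito and all
#'   other genes.
#' @param gc per-species downstream GC fractions (recycled per clade);
#'   defaults to an even spread over 0.32-0.44 within each clade.
#' @param nGenes,nMito,nCore,nRibosomal genome layout (totals; `nCore <=
#'   nMito`, `nMito + nRibosomal <= nGenes`).
#' @param downstreamLength downstream region length in bp (default 1000).
#' @param motifWindow planted motifs start uniformly so the full element
#'   lies within the first `motifWindow` bp (default 250).
#' @param profile profile string for the planted element.
#' @param cdsCodons internal codons per CDS (ATG and TAA are added).
#' @param biasMean,biasSd distribution of the per-gene preferred-codon
#'   usage probability; `biasRibosomal` is the (high) value for the
#'   ribosomal reference genes.
#' @param caiShift planted codon-bias depression, in units of `biasSd`,
#'   applied to motif-bearing mitochondrial genes of the clades named in
#'   `caiShiftClades` (default: the post-WGD clade); calibrated so the
#'   realized within-species CAI z-shift approximates `caiShift`.
#' @param funSetCoreFraction,funSetPeripheralFraction fractions of core and
#'   peripheral mitochondrial genes placed in the
#'   "mitochondrial_translation" function set.
#' @param nConditions,rho,delta,exprSd expression simulation: number of
#'   conditions, within-block correlation of the motif group, log2
#'   down-shift of the motif group in the fermentative condition, and
#'   per-condition log2 noise sd.
#' @param fermentCondition label of the fermentative condition column.
#' @param fitnessBase,fitnessSd,fitnessEffect deletion-fitness simulation:
#'   baseline relative growth, its sd, and the motif-group deficit (in sd
#'   units) under the non-fermentative condition.
#' @param seed master seed.
#' @return a validated list of class `SimulationConfig`.
#' @export
simulationConfig <- function(nSpeciesPerClade = c(5L, 5L),
                             cladeLabels = c("postWGD", "preWGD"),
                             mitoCoreRate = c(0.9, 0.1),
                             mitoPeripheralRate = c(0.23, 0.1),
                             backgroundRate = c(0.1, 0.1),
                             gc = NULL,
                             nGenes = 1000L, nMito = 300L, nCore = 120L,
                             nRibosomal = 40L,
                             downstreamLength = 1000L, motifWindow = 250L,
                             profile = "TGTANATA",
                             cdsCodons = 120L, biasMean = 0.5,
                             biasSd = 0.12, biasRibosomal = 0.9,
                             caiShift = -0.5,
                             caiShiftClades = cladeLabels[1L],
                             funSetCoreFraction = 0.83,
                             funSetPeripheralFraction = 0.045,
                             nConditions = 50L, rho = 0.5, delta = 1.0,
                             exprSd = 0.5,
                             fermentCondition = "ferm_glucose",
                             fitnessBase = 1.0, fitnessSd = 0.1,
                             fitnessEffect = 1.0,
                             seed = 1L) {
  nSpeciesPerClade <- as.integer(nSpeciesPerClade)
  if (length(nSpeciesPerClade) != 2L || any(nSpeciesPerClade < 1L))
    stop("nSpeciesPerClade must be two positive integers", call. = FALSE)
  if (length(cladeLabels) != 2L || anyDuplicated(cladeLabels))
    stop("two distinct clade labels required", call. = FALSE)
  nGenes <- as.integer(nGenes); nMito <- as.integer(nMito)
  nCore <- as.integer(nCore); nRibosomal <- as.integer(nRibosomal)
  if (nCore > nMito) stop("nCore must not exceed nMito", call. = FALSE)
  if (nMito + nRibosomal > nGenes)
    stop("nMito + nRibosomal must not exceed nGenes", call. = FALSE)
  for (r in list(mitoCoreRate, mitoPeripheralRate, backgroundRate))
    if (length(r) != 2L || any(r < 0) || any(r > 1))
      stop("planting rates must be two probabilities", call. = FALSE)
  if (is.null(gc))
    gc <- unlist(lapply(nSpeciesPerClade, function(k)
      if (k == 1L) 0.38 else seq(0.32, 0.44, length.out = k)))
  gc <- rep_len(gc, sum(nSpeciesPerClade))
  if (any(gc < 0) || any(gc > 1)) stop("gc must lie in [0,1]", call. = FALSE)
  .assertScalarNumber(rho, "rho", 0, 1)
  .assertScalarNumber(motifWindow, "motifWindow", 8, downstreamLength)
  cfg <- list(nSpeciesPerClade = nSpeciesPerClade,
              cladeLabels = as.character(cladeLabels),
              mitoCoreRate = mitoCoreRate,
              mitoPeripheralRate = mitoPeripheralRate,
              backgroundRate = backgroundRate,
              gc = gc, nGenes = nGenes, nMito = nMito, nCore = nCore,
              nRibosomal = nRibosomal,
              downstreamLength = as.integer(downstreamLength),
              motifWindow = as.integer(motifWindow),
              profile = profile,
              cdsCodons = as.integer(cdsCodons), biasMean = biasMean,
              biasSd = biasSd, biasRibosomal = biasRibosomal,
              caiShift = caiShift,
              caiShiftClades = as.character(caiShiftClades),
              funSetCoreFraction = funSetCoreFraction,
              funSetPeripheralFraction = funSetPeripheralFraction,
              nConditions = as.integer(nConditions), rho = rho,
              delta = delta, exprSd = exprSd,
              fermentCondition = fermentCondition,
              fitnessBase = fitnessBase, fitnessSd = fitnessSd,
              fitnessEffect = fitnessEffect,
              seed = as.integer(seed))
  class(cfg) <- "SimulationConfig"
  cfg
}

## reference gene ids and genome layout
.refGenes <- function(config) sprintf("R%04d", seq_len(config$nGenes))

.geneRoles <- function(config) {
  roles <- rep("background", config$nGenes)
  roles[seq_len(config$nMito)] <- "mito_peripheral"
  roles[seq_len(config$nCore)] <- "mito_core"
  if (config$nRibosomal > 0L)
    roles[config$nMito + seq_len(config$nRibosomal)] <- "ribosomal"
  roles
}

#' Reference-species annotation implied by a simulation configuration
#'
#' Mitochondrial genes map to the "mitochondrion" compartment, ribosomal
#' genes to "cytoplasm", remaining genes cycle deterministically through
#' cytoplasm/nucleus/ER/membrane. The "mitochondrial_translation" function
#' set takes the configured fractions of core and peripheral mitochondrial
#' genes.
#'
#' @param config a `SimulationConfig`.
#' @return an [AnnotationTable-class].
#' @export
referenceAnnotation <- function(config) {
  genes <- .refGenes(config)
  roles <- .geneRoles(config)
  comp <- character(config$nGenes)
  comp[roles %in% c("mito_core", "mito_peripheral")] <- "mitochondrion"
  comp[roles == "ribosomal"] <- "cytoplasm"
  bgIdx <- which(roles == "background")
  pool <- c("cytoplasm", "nucleus", "ER", "membrane")
  comp[bgIdx] <- pool[(seq_along(bgIdx) - 1L) %% length(pool) + 1L]
  core <- genes[roles == "mito_core"]
  periph <- genes[roles == "mito_peripheral"]
  ## spread set membership evenly over each tier so it is independent of
  ## the id order used for tie-breaking elsewhere
  pickSpread <- function(x, frac) {
    k <- round(length(x) * frac)
    if (k == 0L) character(0) else x[unique(round(seq(1L, length(x),
                                                      length.out = k)))]
  }
  fset <- c(pickSpread(core, config$funSetCoreFraction),
            pickSpread(periph, config$funSetPeripheralFraction))
  annotationTable(localization = setNames(comp, genes),
                  functionSets = list(mitochondrial_translation = fset))
}

## clade index (1 or 2) of a species
.cladeIndex <- function(config, index) {
  if (index > sum(config$nSpeciesPerClade)) stop("no such species")
  if (index <= config$nSpeciesPerClade[1L]) 1L else 2L
}

## codon machinery shared by the CDS generator
.codonPoolTables <- function() {
  fams <- .codonFamilies()
  sizes <- vapply(fams, length, integer(1L))
  pool <- unlist(fams, use.names = FALSE)
  starts <- cumsum(c(1L, sizes[-length(sizes)]))
  list(pool = pool, sizes = sizes, starts = starts,
       preferred = pool[starts], nFam = length(fams))
}

#' Simulate one species of the study
#'
#' Downstream sequences are i.i.d. draws from the species' GC model; each
#' motif-designated gene receives one element (an admitted 8-mer drawn
#' uniformly from the profile's expansion) overwritten at a uniform
#' admissible start within the placement window, preserving sequence length.
#' CDS are generated codon by codon: with probability equal to the gene's
#' bias parameter the family-preferred codon is used, otherwise a uniform
#' family member; ribosomal genes get high bias and motif-bearing
#' mitochondrial genes of the shifted clade(s) get their bias depressed by
#' `caiShift * biasSd`.
#'
#' @param config a `SimulationConfig`.
#' @param index species index (1-based across both clades).
#' @param components which sequence sets to generate (`"downstream"`,
#'   `"cds"`); designations are drawn either way so results are usable for
#'   any stage.
#' @return list with `dataset` ([SpeciesDataset-class]), `orthologs`
#'   ([OrthologMap-class]), `planted` (logical named by reference gene) and
#'   `bias` (numeric named by reference gene).
#' @export
simulateSpecies <- function(config, index,
                            components = c("downstream", "cds")) {
  stopifnot(inherits(config, "SimulationConfig"))
  components <- match.arg(components, several.ok = TRUE)
  ci <- .cladeIndex(config, index)
  sid <- sprintf("S%02d", index)
  genes <- .refGenes(config)
  roles <- .geneRoles(config)
  spGenes <- sprintf("%s_g%04d", sid, seq_len(config$nGenes))
  rate <- ifelse(roles == "mito_core", config$mitoCoreRate[ci],
          ifelse(roles == "mito_peripheral", config$mitoPeripheralRate[ci],
                 config$backgroundRate[ci]))
  prof <- compileProfile(config$profile)
  out <- .withSeed(.deriveSeed(config$seed, "species", index), {
    planted <- runif(config$nGenes) < rate
    down <- NULL
    if ("downstream" %in% components) {
      M <- .randomCoded(config$nGenes, config$downstreamLength,
                        config$gc[index])
      maxStart <- config$motifWindow - 8L
      for (g in which(planted)) {
        word <- vapply(prof@positions, function(s)
          match(s[sample.int(length(s), 1L)], .NUC), integer(1L))
        at <- sample.int(maxStart + 1L, 1L) - 1L  # 0-based start
        M[(at + 1L):(at + 8L), g] <- word
      }
      down <- vapply(seq_len(config$nGenes), function(i) .decodeSeq(M[, i]),
                     character(1L))
      names(down) <- spGenes
    }
    bias <- rnorm(config$nGenes, config$biasMean, config$biasSd)
    bias[roles == "ribosomal"] <- config$biasRibosomal
    shiftClade <- config$cladeLabels[ci] %in% config$caiShiftClades
    if (shiftClade) {
      hit <- planted & roles %in% c("mito_core", "mito_peripheral")
      ## calibration: codon-sampling noise at the default CDS length
      ## attenuates a bias-scale shift by ~0.7 on the CAI z scale, so the
      ## shift is scaled up to realize ~caiShift standard deviations
      bias[hit] <- bias[hit] + config$caiShift * config$biasSd * 1.45
    }
    bias <- pmin(pmax(bias, 0.02), 0.98)
    cdsSeqs <- NULL
    if ("cds" %in% components) {
      tabs <- .codonPoolTables()
      tot <- config$nGenes * config$cdsCodons
      famIdx <- sample.int(tabs$nFam, tot, replace = TRUE)
      usePref <- runif(tot) < rep(bias, each = config$cdsCodons)
      pick <- tabs$starts[famIdx] +
        as.integer(ceiling(runif(tot) * tabs$sizes[famIdx])) - 1L
      codon <- ifelse(usePref, tabs$preferred[famIdx], tabs$pool[pick])
      cm <- matrix(codon, nrow = config$cdsCodons)
      cdsSeqs <- paste0("ATG", apply(cm, 2L, paste, collapse = ""), "TAA")
      names(cdsSeqs) <- spGenes
    }
    list(down = down, cds = cdsSeqs, planted = planted, bias = bias)
  })
  ds <- speciesDataset(sid,
                       downstream = if (is.null(out$down)) character(0)
                                    else out$down,
                       cds = if (is.null(out$cds)) character(0) else out$cds,
                       clade = config$cladeLabels[ci],
                       regionLength = config$downstreamLength)
  om <- orthologMap(data.frame(species_gene = spGenes,
                               reference_gene = genes,
                               stringsAsFactors = FALSE),
                    speciesId = sid)
  list(dataset = ds, orthologs = om,
       planted = setNames(out$planted, genes),
       bias = setNames(out$bias, genes))
}

#' Simulate a block-correlated expression matrix
#'
#' Gaussian log2 ratios with per-condition sd `exprSd`; genes of the
#' motif-bearing group share a common factor giving within-group correlation
#' `rho`, and are shifted by `-delta` in the fermentative condition (the
#' first column). Other genes are independent.
#'
#' @param config a `SimulationConfig`.
#' @param withGenes,withoutGenes gene ids of the motif-bearing and
#'   motif-free groups.
#' @param seed optional seed; defaults to a stream derived from the master
#'   seed.
#' @return numeric matrix (genes x conditions) with the fermentative
#'   condition as first column.
#' @export
simulateExpression <- function(config, withGenes, withoutGenes,
                               seed = .deriveSeed(config$seed, "expression")) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (config$nConditions < 3L)
    stop("at least 3 conditions required", call. = FALSE)
  genes <- c(withGenes, withoutGenes)
  if (anyDuplicated(genes)) stop("groups must be disjoint", call. = FALSE)
  nw <- length(withGenes); n <- length(genes); nc <- config$nConditions
  .withSeed(seed, {
    eps <- matrix(rnorm(n * nc), nrow = n)
    f <- rnorm(nc)
    X <- eps
    if (nw > 0L && config$rho > 0) {
      X[seq_len(nw), ] <- sqrt(config$rho) * rep(f, each = nw) +
        sqrt(1 - config$rho) * eps[seq_len(nw), , drop = FALSE]
    }
    X <- X * config$exprSd
    X[seq_len(nw), 1L] <- X[seq_len(nw), 1L] - config$delta
    dimnames(X) <- list(genes,
                        c(config$fermentCondition,
                          sprintf("cond%03d", seq_len(nc - 1L) + 1L)))
    X
  })
}

#' Simulate a deletion-fitness table
#'
#' Relative growth of deletion mutants under fermentative and
#' non-fermentative conditions: Gaussian around `fitnessBase`, with the
#' motif-bearing group depressed by `fitnessEffect * fitnessSd` in the
#' non-fermentative condition only.
#'
#' @inheritParams simulateExpression
#' @return data.frame with columns `gene`, `condition`, `relative_growth`.
#' @export
simulateFitness <- function(config, withGenes, withoutGenes,
                            seed = .deriveSeed(config$seed, "fitness")) {
  stopifnot(inherits(config, "SimulationConfig"))
  genes <- c(withGenes, withoutGenes)
  if (anyDuplicated(genes)) stop("groups must be disjoint", call. = FALSE)
  n <- length(genes)
  isWith <- c(rep(TRUE, length(withGenes)), rep(FALSE, length(withoutGenes)))
  .withSeed(seed, {
    ferm <- rnorm(n, config$fitnessBase, config$fitnessSd)
    nonferm <- rnorm(n, config$fitnessBase -
                       ifelse(isWith, config$fitnessEffect * config$fitnessSd,
                              0),
                     config$fitnessSd)
    data.frame(gene = rep(genes, 2L),
               condition = rep(c("fermentative", "non_fermentative"),
                               each = n),
               relative_growth = c(ferm, nonferm),
               stringsAsFactors = FALSE)
  })
}

#' Write a complete simulated input bundle to disk
#'
#' Emits, for every species, downstream and CDS FASTA files and an ortholog
#' TSV, plus shared localization, function-set, ribosomal-reference,
#' expression and fitness tables, the configuration as YAML, and a JSON
#' manifest (species inventory, seed, config hash) sufficient to re-run any
#' stage.
#'
#' The expression and fitness groups are the mitochondrial genes designated
#' motif-bearing in the focal species (the first species of the first
#' clade), mirroring a reference-species analysis.
#'
#' @param config a `SimulationConfig`.
#' @param dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
writeSimulatedStudy <- function(config, dir) {
  stopifnot(inherits(config, "SimulationConfig"))
  dir.create(file.path(dir, "species"), recursive = TRUE,
             showWarnings = FALSE)
  genes <- .refGenes(config)
  roles <- .geneRoles(config)
  ann <- referenceAnnotation(config)
  nSpecies <- sum(config$nSpeciesPerClade)
  speciesTab <- data.frame(species_id = character(0), clade = character(0),
                           gc = numeric(0), stringsAsFactors = FALSE)
  focalPlanted <- NULL
  for (i in seq_len(nSpecies)) {
    sim <- simulateSpecies(config, i)
    sid <- speciesId(sim$dataset)
    writeFasta(downstreamSeqs(sim$dataset),
               file.path(dir, "species", paste0(sid, "_downstream.fasta")))
    writeFasta(cdsSeqs(sim$dataset),
               file.path(dir, "species", paste0(sid, "_cds.fasta")))
    writeResultTable(orthologPairs(sim$orthologs),
                     file.path(dir, "species", paste0(sid, "_orthologs.tsv")))
    speciesTab <- rbind(speciesTab,
                        data.frame(species_id = sid,
                                   clade = clade(sim$dataset),
                                   gc = config$gc[i],
                                   stringsAsFactors = FALSE))
    if (i == 1L) focalPlanted <- sim$planted
  }
  loc <- localization(ann)
  writeResultTable(data.frame(gene = names(loc), compartment = unname(loc)),
                   file.path(dir, "localization.tsv"))
  fs <- functionSets(ann)
  writeResultTable(data.frame(set_name = rep(names(fs), lengths(fs)),
                              gene = unlist(fs, use.names = FALSE)),
                   file.path(dir, "function_sets.tsv"))
  writeResultTable(data.frame(gene = genes[roles == "ribosomal"]),
                   file.path(dir, "ribosomal_reference.tsv"))
  mito <- genes[roles %in% c("mito_core", "mito_peripheral")]
  withG <- mito[focalPlanted[mito]]
  withoutG <- setdiff(mito, withG)
  X <- simulateExpression(config, withG, withoutG)
  writeResultTable(data.frame(gene = rownames(X), as.data.frame(X),
                              check.names = FALSE),
                   file.path(dir, "expression.tsv"))
  writeResultTable(simulateFitness(config, withG, withoutG),
                   file.path(dir, "fitness.tsv"))
  cfgPath <- file.path(dir, "config.yaml")
  yaml::write_yaml(unclass(config), cfgPath)
  manifest <- list(seed = config$seed,
                   config_file = "config.yaml",
                   config_md5 = unname(tools::md5sum(cfgPath)),
                   package_version = as.character(packageVersion("PufRegulon")),
                   profile = config$profile,
                   ferment_condition = config$fermentCondition,
                   region_length = config$downstreamLength,
                   species = speciesTab,
                   files = list(localization = "localization.tsv",
                                function_sets = "function_sets.tsv",
                                ribosomal_reference = "ribosomal_reference.tsv",
                                expression = "expression.tsv",
                                fitness = "fitness.tsv"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
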