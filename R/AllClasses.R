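#' @import methods
#' @importFrom Biostrings DNAStringSet readBStringSet writeXStringSet
#'   alphabetFrequency subseq width GENETIC_CODE
#' @importFrom stats fisher.test lm phyper rnorm runif sd t.test cor var
#'   setNames coef
#' @importFrom utils read.table write.table packageVersion
NULL

## ---------------------------------------------------------------------------
## MotifProfile
## ---------------------------------------------------------------------------

#' MotifProfile: positional nucleotide constraints of a binding element
#'
#' An 8-position profile in which each position carries the set of admitted
#' nucleotides. The default Puf3p-binding-element (P3E) profile fixes seven
#' positions and leaves the fifth free (any of A/C/G/T).
#'
#' @slot name character(1), a label for the profile.
#' @slot positions list of length 8; each element a character vector of
#'   admitted nucleotides drawn from A, C, G, T.
#' @seealso [compileProfile()], [p3eProfile()], [scanSequence()]
#' @exportClass MotifProfile
setClass("MotifProfile",
         representation(name = "character", positions = "list"))

setValidity("MotifProfile", function(object) {
  p <- object@positions
  if (length(p) != 8L)
    return("a motif profile must have exactly 8 positions")
  for (i in seq_along(p)) {
    s <- p[[i]]
    if (!is.character(s) || length(s) < 1L || !all(s %in% .NUC) || anyDuplicated(s))
      return(sprintf("position %d must be a set of nucleotides from {A,C,G,T}", i))
  }
  TRUE
})

#' @describeIn MotifProfile-class compact display
#' @param object a `MotifProfile`
#' @export
setMethod("show", "MotifProfile", function(object) {
  sym <- vapply(object@positions, function(s)
    if (length(s) == 4L) "N" else paste(s, collapse = ""), character(1L))
  cat("MotifProfile '", object@name, "': ",
      paste0("[", sym, "]", collapse = ""), "\n", sep = "")
})

## ---------------------------------------------------------------------------
## SpeciesDataset
## ---------------------------------------------------------------------------

#' SpeciesDataset: sequences of one species
#'
#' Holds the gene-anchored 3' downstream sequences (sense strand, starting at
#' the first base after the stop codon) and the coding sequences of one
#' species, plus a free-text clade tag.
#'
#' @slot speciesId character(1) species identifier.
#' @slot clade character(1) clade tag (e.g. `"postWGD"`).
#' @slot downstream [Biostrings::DNAStringSet] of 3' downstream sequences,
#'   named by gene id, each at most `regionLength` bases.
#' @slot cds [Biostrings::DNAStringSet] of coding sequences, named by gene
#'   id, lengths divisible by 3.
#' @slot regionLength numeric(1) maximum downstream length (default 1000).
#' @seealso [speciesDataset()], [callTargets()], [estimateGC()]
#' @exportClass SpeciesDataset
setClass("SpeciesDataset",
         representation(speciesId = "character", clade = "character",
                        downstream = "DNAStringSet", cds = "DNAStringSet",
                        regionLength = "numeric"),
         prototype(regionLength = 1000))

setValidity("SpeciesDataset", function(object) {
  if (length(object@downstream) > 0L) {
    dn <- names(object@downstream)
    if (is.null(dn) || anyDuplicated(dn) || any(dn == ""))
      return("downstream gene ids must be unique and non-empty")
    if (any(width(object@downstream) < 1L))
      return("downstream sequences must be non-empty")
    if (any(width(object@downstream) > object@regionLength))
      return(sprintf("downstream sequences exceed regionLength (%d bp)",
                     as.integer(object@regionLength)))
  }
  if (length(object@cds) > 0L) {
    cn <- names(object@cds)
    if (is.null(cn) || anyDuplicated(cn) || any(cn == ""))
      return("cds gene ids must be unique and non-empty")
    w <- width(object@cds)
    if (any(w < 3L) || any(w %% 3L != 0L))
      return("cds lengths must be >= 3 and divisible by 3")
  }
  TRUE
})

#' Construct a SpeciesDataset
#'
#' @param speciesId species identifier.
#' @param downstream named `DNAStringSet` (or named character vector) of 3'
#'   downstream sequences.
#' @param cds named `DNAStringSet` (or named character vector) of coding
#'   sequences; may be empty.
#' @param clade clade tag.
#' @param regionLength maximum admitted downstream length in bp.
#' @return a validated [SpeciesDataset-class] object.
#' @examples
#' speciesDataset("sp1", c(g1 = "ACGTACGT"), c(g1 = "ATGAAATAA"))
#' @export
speciesDataset <- function(speciesId, downstream, cds = character(0),
                           clade = "unassigned", regionLength = 1000) {
  if (!is(downstream, "DNAStringSet")) downstream <- DNAStringSet(downstream)
  if (!is(cds, "DNAStringSet")) cds <- DNAStringSet(cds)
  new("SpeciesDataset", speciesId = as.character(speciesId),
      clade = as.character(clade), downstream = downstream, cds = cds,
      regionLength = regionLength)
}

#' @describeIn SpeciesDataset-class compact display
#' @param object a `SpeciesDataset`
#' @export
setMethod("show", "SpeciesDataset", function(object) {
  cat("SpeciesDataset '", object@speciesId, "' (clade ", object@clade, "): ",
      length(object@downstream), " downstream sequences, ",
      length(object@cds), " CDS\n", sep = "")
})

#' @rdname SpeciesDataset-class
#' @param x a `SpeciesDataset`
#' @export
speciesId <- function(x) x@speciesId

#' @rdname SpeciesDataset-class
#' @export
clade <- function(x) x@clade

#' @rdname SpeciesDataset-class
#' @export
downstreamSeqs <- function(x) x@downstream

#' @rdname SpeciesDataset-class
#' @export
cdsSeqs <- function(x) x@cds

## ---------------------------------------------------------------------------
## GCModel
## ---------------------------------------------------------------------------

#' GCModel: background GC composition for null sequences
#'
#' @slot mode one of `"full_region"`, `"utr250"`, `"per_window"`.
#' @slot gc GC fraction in \[0, 1\]; a scalar for the first two modes, a
#'   per-window vector for `"per_window"`.
#' @slot windowSize window size in bp used by `"per_window"` mode.
#' @slot regionLength region length in bp the model describes.
#' @seealso [estimateGC()], [generateNull()]
#' @exportClass GCModel
setClass("GCModel",
         representation(mode = "character", gc = "numeric",
                        windowSize = "integer", regionLength = "integer"))

setValidity("GCModel", function(object) {
  if (!object@mode %in% c("full_region", "utr250", "per_window"))
    return("mode must be full_region, utr250 or per_window")
  if (any(is.na(object@gc)) || any(object@gc < 0) || any(object@gc > 1))
    return("gc must lie in [0, 1]")
  nw <- ceiling(object@regionLength / object@windowSize)
  if (object@mode == "per_window" && length(object@gc) != nw)
    return(sprintf("per_window gc must have %d entries", nw))
  if (object@mode != "per_window" && length(object@gc) != 1L)
    return("scalar gc expected")
  TRUE
})

#' @describeIn GCModel-class compact display
#' @param object a `GCModel`
#' @export
setMethod("show", "GCModel", function(object) {
  cat("GCModel (", object@mode, "): gc = ",
      paste(round(object@gc, 4), collapse = ", "), "\n", sep = "")
})

#' @rdname GCModel-class
#' @param x a `GCModel`
#' @export
gcContent <- function(x) x@gc

## ---------------------------------------------------------------------------
## WindowCounts / NullCounts
## ---------------------------------------------------------------------------

#' WindowCounts: motif occurrences aggregated into fixed windows
#'
#' Matches are assigned to windows by their 0-based start offset; multiple
#' matches falling in one window are counted as independent events.
#' `eligible` holds, per window, the number of scannable start positions
#' summed over sequences (a start `i` is scannable when the full 8-mer fits,
#' `i + 8 <= L`).
#'
#' @slot windowSize window size in bp.
#' @slot regionLength scanned region length in bp.
#' @slot counts integer vector of per-window match counts.
#' @slot eligible numeric vector of per-window eligible start positions.
#' @slot nGenes number of sequences aggregated.
#' @seealso [countInWindows()], [windowEnrichmentTest()]
#' @exportClass WindowCounts
setClass("WindowCounts",
         representation(windowSize = "integer", regionLength = "integer",
                        counts = "integer", eligible = "numeric",
                        nGenes = "integer"))

setValidity("WindowCounts", function(object) {
  nw <- ceiling(object@regionLength / object@windowSize)
  if (length(object@counts) != nw || length(object@eligible) != nw)
    return(sprintf("counts and eligible must have %d windows", nw))
  if (any(object@counts < 0L)) return("negative counts")
  if (any(object@eligible < object@counts))
    return("eligible positions cannot be fewer than counts")
  TRUE
})

#' @describeIn WindowCounts-class compact display
#' @param object a `WindowCounts`
#' @export
setMethod("show", "WindowCounts", function(object) {
  cat(class(object), ": ", length(object@counts), " windows of ",
      object@windowSize, " bp over ", object@nGenes, " sequences; total ",
      sum(object@counts), " matches\n", sep = "")
})

#' @rdname WindowCounts-class
#' @param x a `WindowCounts`
#' @export
motifCounts <- function(x) x@counts

#' @rdname WindowCounts-class
#' @export
eligiblePositions <- function(x) x@eligible

#' NullCounts: window counts over a GC-matched random-sequence background
#'
#' @slot nSequences number of random sequences generated.
#' @slot seqLength length of each random sequence in bp.
#' @slot seed the seed used (NA if none supplied).
#' @slot gcModel the [GCModel-class] the sequences were drawn from.
#' @seealso [generateNull()]
#' @exportClass NullCounts
setClass("NullCounts", contains = "WindowCounts",
         representation(nSequences = "integer", seqLength = "integer",
                        seed = "integer", gcModel = "GCModel"))

## ---------------------------------------------------------------------------
## TargetSet
## ---------------------------------------------------------------------------

#' TargetSet: genes called as regulon targets in one species
#'
#' A gene is a target when at least one motif match lies entirely within the
#' first `utrCutoff` bases of its 3' downstream region (0-based start
#' `<= utrCutoff - 8`).
#'
#' @slot speciesId character(1).
#' @slot targets character vector of target gene ids.
#' @slot universe character vector of all scanned gene ids.
#' @slot utrCutoff integer(1), 3' UTR cutoff in bp (default 250).
#' @seealso [callTargets()], [categoryTest()]
#' @exportClass TargetSet
setClass("TargetSet",
         representation(speciesId = "character", targets = "character",
                        universe = "character", utrCutoff = "integer"))

setValidity("TargetSet", function(object) {
  if (!all(object@targets %in% object@universe))
    return("targets must be a subset of the scanned gene universe")
  if (anyDuplicated(object@targets)) return("duplicate target ids")
  if (object@utrCutoff < 8L) return("utrCutoff must be at least 8 bp")
  TRUE
})

#' @describeIn TargetSet-class compact display
#' @param object a `TargetSet`
#' @export
setMethod("show", "TargetSet", function(object) {
  cat("TargetSet '", object@speciesId, "': ", length(object@targets), " of ",
      length(object@universe), " genes (UTR cutoff ", object@utrCutoff,
      " bp)\n", sep = "")
})

#' @rdname TargetSet-class
#' @param x a `TargetSet`
#' @export
targets <- function(x) x@targets

#' @rdname TargetSet-class
#' @export
geneUniverse <- function(x) x@universe

## ---------------------------------------------------------------------------
## ConservationMatrix
## ---------------------------------------------------------------------------

#' ConservationMatrix: target state of ortholog groups across species
#'
#' Rows are reference genes (ortholog groups), columns species. Cells take
#' one of three states: `"T"` (an ortholog is a called target), `"P"`
#' (orthologs present, none a target), `"A"` (no ortholog). The row score is
#' the fraction of non-absent cells in state `"T"`; rows are stored sorted by
#' decreasing score with ties broken by gene id.
#'
#' @slot states character matrix with values T/P/A, dimnames gene x species.
#' @slot rowScore numeric vector of per-row conservation fractions.
#' @seealso [buildConservationMatrix()], [slidingFunctionFraction()]
#' @exportClass ConservationMatrix
setClass("ConservationMatrix",
         representation(states = "matrix", rowScore = "numeric"))

setValidity("ConservationMatrix", function(object) {
  if (!all(object@states %in% c("T", "P", "A")))
    return("states must be T, P or A")
  if (nrow(object@states) != length(object@rowScore))
    return("one row score per row required")
  if (any(object@rowScore < 0 | object@rowScore > 1))
    return("row scores must lie in [0, 1]")
  TRUE
})

#' @describeIn ConservationMatrix-class compact display
#' @param object a `ConservationMatrix`
#' @export
setMethod("show", "ConservationMatrix", function(object) {
  cat("ConservationMatrix: ", nrow(object@states), " ortholog groups x ",
      ncol(object@states), " species; mean conservation ",
      round(mean(object@rowScore), 3), "\n", sep = "")
})

#' @rdname ConservationMatrix-class
#' @param x a `ConservationMatrix`
#' @export
conservationStates <- function(x) x@states

#' @rdname ConservationMatrix-class
#' @export
rowScores <- function(x) x@rowScore

## ---------------------------------------------------------------------------
## AdaptivenessTable
## ---------------------------------------------------------------------------

#' AdaptivenessTable: relative codon adaptiveness from a reference set
#'
#' For every synonymous-codon family the most used codon in the reference set
#' gets weight 1 and the rest their usage ratio to it. Stop codons and the
#' single-codon families (ATG, TGG) carry no usage information and are
#' excluded.
#'
#' @slot w named numeric vector, codon -> relative adaptiveness in (0, 1\].
#' @slot referenceGeneCount number of reference CDS pooled.
#' @slot excludedCodons codons excluded from CAI computation.
#' @seealso [referenceWeights()], [cai()]
#' @exportClass AdaptivenessTable
setClass("AdaptivenessTable",
         representation(w = "numeric", referenceGeneCount = "integer",
                        excludedCodons = "character"))

setValidity("AdaptivenessTable", function(object) {
  if (is.null(names(object@w))) return("weights must be named by codon")
  if (any(object@w <= 0) || any(object@w > 1))
    return("weights must lie in (0, 1]")
  fams <- .codonFamilies()
  for (f in fams) {
    ww <- object@w[f[f %in% names(object@w)]]
    if (length(ww) && abs(max(ww) - 1) > 1e-12)
      return("every synonymous family must contain a weight-1 codon")
  }
  TRUE
})

#' @describeIn AdaptivenessTable-class compact display
#' @param object an `AdaptivenessTable`
#' @export
setMethod("show", "AdaptivenessTable", function(object) {
  cat("AdaptivenessTable: ", length(object@w), " codon weights from ",
      object@referenceGeneCount, " reference genes\n", sep = "")
})

#' @rdname AdaptivenessTable-class
#' @param x an `AdaptivenessTable`
#' @export
adaptiveness <- function(x) x@w

## ---------------------------------------------------------------------------
## OrthologMap / AnnotationTable
## ---------------------------------------------------------------------------

#' OrthologMap: ortholog pairs between a species and the reference
#'
#' @slot speciesId character(1).
#' @slot referenceId character(1).
#' @slot pairs data.frame with columns `species_gene`, `reference_gene`;
#'   duplicate pairs are not admitted.
#' @seealso [readOrthologMap()], [mapCategories()]
#' @exportClass OrthologMap
setClass("OrthologMap",
         representation(speciesId = "character", referenceId = "character",
                        pairs = "data.frame"))

setValidity("OrthologMap", function(object) {
  p <- object@pairs
  if (!all(c("species_gene", "reference_gene") %in% names(p)))
    return("pairs must have columns species_gene and reference_gene")
  if (anyDuplicated(p[, c("species_gene", "reference_gene")]))
    return("duplicate ortholog pairs")
  TRUE
})

#' Construct an OrthologMap
#'
#' @param pairs data.frame with columns `species_gene`, `reference_gene`.
#' @param speciesId species identifier.
#' @param referenceId reference-species identifier.
#' @return a validated [OrthologMap-class].
#' @export
orthologMap <- function(pairs, speciesId, referenceId = "reference") {
  pairs <- as.data.frame(pairs)[, c("species_gene", "reference_gene")]
  pairs$species_gene <- as.character(pairs$species_gene)
  pairs$reference_gene <- as.character(pairs$reference_gene)
  new("OrthologMap", speciesId = as.character(speciesId),
      referenceId = as.character(referenceId), pairs = pairs)
}

#' @describeIn OrthologMap-class compact display
#' @param object an `OrthologMap`
#' @export
setMethod("show", "OrthologMap", function(object) {
  cat("OrthologMap ", object@speciesId, " <-> ", object@referenceId, ": ",
      nrow(object@pairs), " pairs\n", sep = "")
})

#' @rdname OrthologMap-class
#' @param x an `OrthologMap`
#' @export
orthologPairs <- function(x) x@pairs

#' AnnotationTable: reference-species localization and function sets
#'
#' @slot localization named character vector, reference gene -> compartment.
#' @slot functionSets named list of character vectors of reference genes.
#' @seealso [readLocalization()], [readFunctionSets()], [mapCategories()]
#' @exportClass AnnotationTable
setClass("AnnotationTable",
         representation(localization = "character", functionSets = "list"))

setValidity("AnnotationTable", function(object) {
  if (length(object@localization) &&
      (is.null(names(object@localization)) ||
       anyDuplicated(paste(names(object@localization), object@localization))))
    return("localization must be named by gene without duplicated entries")
  if (any(object@localization == "")) return("empty compartment label")
  if (length(object@functionSets)) {
    if (is.null(names(object@functionSets)))
      return("function sets must be named")
    if (any(vapply(object@functionSets, length, integer(1L)) == 0L))
      return("function sets must be non-empty")
  }
  TRUE
})

#' Construct an AnnotationTable
#'
#' @param localization named character vector (gene -> compartment) or a
#'   data.frame with columns `gene`, `compartment`. A gene may carry several
#'   compartments (one entry each).
#' @param functionSets named list of character vectors of reference genes.
#' @return a validated [AnnotationTable-class].
#' @export
annotationTable <- function(localization = character(0),
                            functionSets = list()) {
  if (is.data.frame(localization)) {
    loc <- as.character(localization$compartment)
    names(loc) <- as.character(localization$gene)
    localization <- loc
  }
  new("AnnotationTable", localization = localization,
      functionSets = functionSets)
}

#' @describeIn AnnotationTable-class compact display
#' @param object an `AnnotationTable`
#' @export
setMethod("show", "AnnotationTable", function(object) {
  cat("AnnotationTable: ", length(object@localization),
      " localization entries, ", length(object@functionSets),
      " function sets\n", sep = "")
})

#' @rdname AnnotationTable-class
#' @param x an `AnnotationTable`
#' @export
localization <- function(x) x@localization

#' @rdname AnnotationTable-class
#' @export
functionSets <- function(x) x@functionSets
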