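## Cross-species conservation matrix of called targets and sliding-window
## functional fractions along the conservation ranking.

#' Build the target-conservation matrix across species
#'
#' Each cell records, for one reference gene in one species: `"A"` when the
#' species has no ortholog, `"T"` when any ortholog is a called target, and
#' `"P"` otherwise. The row score is the fraction of non-absent cells in
#' state `"T"`; rows are sorted by decreasing score, ties broken by gene id,
#' so output is byte-reproducible. Genes absent from every species are
#' dropped with a warning.
#'
#' @param geneSet character vector of reference gene ids (rows).
#' @param targetSets named list of [TargetSet-class], one per species.
#' @param orthologMaps named list of [OrthologMap-class], same names.
#' @return a [ConservationMatrix-class].
#' @export
buildConservationMatrix <- function(geneSet, targetSets, orthologMaps) {
  if (length(geneSet) == 0L) stop("empty gene set", call. = FALSE)
  sp <- names(targetSets)
  if (is.null(sp) || !identical(sort(sp), sort(names(orthologMaps))))
    stop("targetSets and orthologMaps must share species names",
         call. = FALSE)
  geneSet <- sort(unique(geneSet))
  states <- matrix("A", nrow = length(geneSet), ncol = length(sp),
                   dimnames = list(geneSet, sp))
  for (s in sp) {
    pairs <- orthologMaps[[s]]@pairs
    pairs <- pairs[pairs$reference_gene %in% geneSet, , drop = FALSE]
    present <- unique(pairs$reference_gene)
    isTarget <- pairs$species_gene %in% targetSets[[s]]@targets
    tgt <- unique(pairs$reference_gene[isTarget])
    states[present, s] <- "P"
    states[tgt, s] <- "T"
  }
  nonAbsent <- rowSums(states != "A")
  drop <- nonAbsent == 0L
  if (any(drop)) {
    warning(sum(drop), " gene(s) absent from every species dropped")
    states <- states[!drop, , drop = FALSE]
    nonAbsent <- nonAbsent[!drop]
  }
  score <- rowSums(states == "T") / nonAbsent
  ord <- order(-score, rownames(states))
  new("ConservationMatrix", states = states[ord, , drop = FALSE],
      rowScore = unname(score[ord]))
}

#' Sliding-window functional fraction along the conservation ranking
#'
#' With rows sorted by conservation score (as stored in the matrix), the
#' fraction of genes belonging to `functionSet` is computed in consecutive
#' windows of `window` genes from top to bottom.
#'
#' @param matrix a [ConservationMatrix-class].
#' @param functionSet character vector of reference gene ids (e.g. a
#'   mitochondrial-translation set).
#' @param window window size in genes (default 50).
#' @param step step between window starts in genes (default 1).
#' @return data.frame with `window_start` (1-based row index), `fraction`.
#' @export
slidingFunctionFraction <- function(matrix, functionSet, window = 50L,
                                    step = 1L) {
  window <- as.integer(window)
  step <- as.integer(step)
  if (is.na(window) || window <= 0L) stop("window must be > 0", call. = FALSE)
  if (is.na(step) || step <= 0L) stop("step must be > 0", call. = FALSE)
  genes <- rownames(matrix@states)
  n <- length(genes)
  if (window > n)
    stop("window exceeds the number of rows (", n, ")", call. = FALSE)
  inSet <- as.numeric(genes %in% functionSet)
  cs <- c(0, cumsum(inSet))
  starts <- seq.int(1L, n - window + 1L, by = step)
  data.frame(window_start = starts,
             fraction = (cs[starts + window] - cs[starts]) / window)
}
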