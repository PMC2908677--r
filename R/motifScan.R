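## Profile compilation and motif scanning of 3' downstream regions.
##
## The scan is sense-strand only (the element is read on the mRNA), reports
## every 0-based start offset whose full 8-mer satisfies all positional
## constraints, and treats N in a sequence as matching nothing. Overlapping
## matches are all reported.

#' Compile an 8-symbol profile string into a MotifProfile
#'
#' Each symbol is A, C, G, T (a fixed position) or N (a free position
#' admitting all four nucleotides).
#'
#' @param spec character(1) of exactly 8 symbols over A/C/G/T/N.
#' @param name label for the profile; defaults to the profile string.
#' @return a [MotifProfile-class].
#' @examples
#' compileProfile("TGTANATA")
#' @export
compileProfile <- function(spec, name = spec) {
  if (!is.character(spec) || length(spec) != 1L)
    stop("'spec' must be a single string", call. = FALSE)
  chars <- strsplit(toupper(spec), "", fixed = TRUE)[[1L]]
  if (length(chars) != 8L)
    stop("profile spec must have exactly 8 symbols, got ", length(chars),
         call. = FALSE)
  bad <- setdiff(chars, c(.NUC, "N"))
  if (length(bad))
    stop("invalid profile symbol(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  positions <- lapply(chars, function(ch) if (ch == "N") .NUC else ch)
  new("MotifProfile", name = as.character(name), positions = positions)
}

#' The default Puf3p-binding-element profile
#'
#' Seven fixed positions and a free fifth position: `TGTANATA`, the DNA
#' sense-strand rendering of the UGUA-N-AUA core bound by Puf3p.
#'
#' @return a [MotifProfile-class].
#' @export
p3eProfile <- function() compileProfile("TGTANATA", name = "P3E")

## logical lookup tables (length 5, index = code + 1) per profile position
.allowedLookup <- function(profile) {
  lapply(profile@positions, function(s) {
    tab <- logical(5L)
    tab[match(s, .NUC) + 1L] <- TRUE
    tab
  })
}

## Scan one integer-coded sequence; returns 0-based starts.
.scanCoded <- function(codes, lookup) {
  L <- length(codes)
  if (L < 8L) return(integer(0L))
  S <- L - 7L
  ok <- lookup[[1L]][codes[seq_len(S)] + 1L]
  for (k in 2:8) ok <- ok & lookup[[k]][codes[k:(S + k - 1L)] + 1L]
  which(ok) - 1L
}

#' Locate all profile matches in a nucleotide sequence
#'
#' @param seq a nucleotide string (or `DNAString`) over A/C/G/T/N.
#' @param profile a [MotifProfile-class].
#' @return sorted integer vector of 0-based match start offsets; empty for
#'   sequences shorter than the profile.
#' @examples
#' scanSequence("TGTAAATATGTACATA", p3eProfile())
#' @export
scanSequence <- function(seq, profile) {
  stopifnot(is(profile, "MotifProfile"))
  seq <- as.character(seq)
  if (length(seq) != 1L) stop("'seq' must be a single sequence", call. = FALSE)
  .scanCoded(.encodeSeq(toupper(seq)), .allowedLookup(profile))
}

#' Scan every downstream sequence of a dataset
#'
#' @param x a [SpeciesDataset-class] or named `DNAStringSet`.
#' @param profile a [MotifProfile-class].
#' @return data.frame with columns `gene_id`, `start` (0-based), one row per
#'   match, ordered by gene then start.
#' @export
scanDownstream <- function(x, profile) {
  seqs <- if (is(x, "SpeciesDataset")) x@downstream else x
  chars <- as.character(seqs)
  lookup <- .allowedLookup(profile)
  hits <- lapply(chars, function(s) .scanCoded(.encodeSeq(s), lookup))
  n <- lengths(hits)
  data.frame(gene_id = rep(names(seqs), n),
             start = as.integer(unlist(hits, use.names = FALSE)),
             stringsAsFactors = FALSE)
}

#' Aggregate motif matches into fixed-size windows
#'
#' A match is assigned to window `floor(start / windowSize)`; multiple
#' matches in one window count as independent events. Eligible start
#' positions per window account for sequences shorter than the region.
#'
#' @param matches data.frame with columns `gene_id`, `start` as returned by
#'   [scanDownstream()].
#' @param seqLengths named integer vector of sequence lengths (one entry per
#'   scanned gene; defines the gene universe).
#' @param windowSize window size in bp; must divide `regionLength`.
#' @param regionLength scanned region length in bp.
#' @return a [WindowCounts-class].
#' @export
countInWindows <- function(matches, seqLengths, windowSize = 50L,
                           regionLength = 1000L) {
  windowSize <- as.integer(windowSize)
  regionLength <- as.integer(regionLength)
  if (is.na(windowSize) || windowSize <= 0L)
    stop("windowSize must be a positive integer", call. = FALSE)
  if (regionLength %% windowSize != 0L)
    stop("windowSize must divide regionLength", call. = FALSE)
  nw <- regionLength %/% windowSize
  starts <- matches$start
  starts <- starts[starts < regionLength]
  counts <- tabulate(starts %/% windowSize + 1L, nbins = nw)
  ## valid starts per gene: i with i + 8 <= min(L, regionLength)
  nv <- pmax(0L, pmin(as.integer(seqLengths), regionLength) - 7L)
  eligible <- numeric(nw)
  for (w in seq_len(nw)) {
    lo <- (w - 1L) * windowSize
    eligible[w] <- sum(pmax(0L, pmin(nv, w * windowSize) - lo))
  }
  new("WindowCounts", windowSize = windowSize, regionLength = regionLength,
      counts = as.integer(counts), eligible = eligible,
      nGenes = length(seqLengths))
}

#' Call regulon target genes by the 3' UTR cutoff rule
#'
#' A gene is a target when at least one match lies entirely inside the first
#' `utrCutoff` bases of its downstream region, i.e. 0-based start
#' `<= utrCutoff - 8`.
#'
#' @param dataset a [SpeciesDataset-class] (or named `DNAStringSet`).
#' @param profile a [MotifProfile-class].
#' @param utrCutoff 3' UTR cutoff in bp (default 250).
#' @return a [TargetSet-class].
#' @export
callTargets <- function(dataset, profile, utrCutoff = 250L) {
  utrCutoff <- as.integer(utrCutoff)
  if (is.na(utrCutoff) || utrCutoff < 8L)
    stop("utrCutoff must be at least 8 bp", call. = FALSE)
  seqs <- if (is(dataset, "SpeciesDataset")) dataset@downstream else dataset
  sid <- if (is(dataset, "SpeciesDataset")) dataset@speciesId else "unknown"
  m <- scanDownstream(seqs, profile)
  hit <- unique(m$gene_id[m$start + 8L <= utrCutoff])
  new("TargetSet", speciesId = sid, targets = sort(hit),
      universe = names(seqs), utrCutoff = utrCutoff)
}
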