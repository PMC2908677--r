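## Codon adaptation index against a highly expressed reference set, with the
## Sharp & Li conventions: per-family relative adaptiveness, 0.5 pseudo-count
## for unobserved codons, stop codons and the single-codon families (ATG,
## TGG) excluded, CAI as the geometric mean of weights over a gene's codons.

.STOP_CODONS <- c("TAA", "TAG", "TGA")
.SINGLE_CODONS <- c("ATG", "TGG")

## Synonymous families with >= 2 codons, named by amino acid.
.codonFamilies <- function() {
  gc <- Biostrings::GENETIC_CODE
  fams <- split(names(gc), unname(gc))
  fams <- fams[names(fams) != "*"]
  fams[vapply(fams, length, integer(1L)) >= 2L]
}

.splitCodons <- function(s) {
  L <- nchar(s)
  substring(s, seq.int(1L, L, 3L), seq.int(3L, L, 3L))
}

#' Relative codon adaptiveness from a reference gene set
#'
#' Codon counts are pooled over all reference CDS; within each synonymous
#' family the weight of a codon is its count divided by the family maximum,
#' with unobserved codons assigned a count of 0.5 before normalisation.
#'
#' @param referenceCds `DNAStringSet` or character vector of reference
#'   coding sequences (lengths divisible by 3); typically the species'
#'   cytoplasmic ribosomal protein genes, all copies pooled.
#' @return an [AdaptivenessTable-class].
#' @examples
#' refs <- c(paste(rep("GAA", 9), collapse = ""),
#'           paste(rep("GAG", 3), collapse = ""))
#' adaptiveness(referenceWeights(refs))[c("GAA", "GAG")]
#' @export
referenceWeights <- function(referenceCds) {
  seqs <- as.character(referenceCds)
  if (length(seqs) == 0L) stop("empty reference set", call. = FALSE)
  if (any(nchar(seqs) %% 3L != 0L))
    stop("reference CDS lengths must be divisible by 3", call. = FALSE)
  codons <- unlist(lapply(seqs, .splitCodons), use.names = FALSE)
  fams <- .codonFamilies()
  all_codons <- unlist(fams, use.names = FALSE)
  counts <- table(factor(codons, levels = all_codons))
  counts <- as.numeric(counts)
  names(counts) <- all_codons
  counts[counts == 0] <- 0.5
  w <- counts
  for (f in fams) w[f] <- counts[f] / max(counts[f])
  new("AdaptivenessTable", w = w, referenceGeneCount = length(seqs),
      excludedCodons = c(.STOP_CODONS, .SINGLE_CODONS))
}

#' Codon adaptation index of coding sequences
#'
#' Geometric mean of relative adaptiveness over a gene's codons, excluding
#' stop codons, ATG, TGG and any codon containing a non-ACGT character. An
#' internal (non-terminal) stop codon triggers a warning and is excluded.
#'
#' @param cds a single CDS string, a character vector, or a `DNAStringSet`.
#' @param weights an [AdaptivenessTable-class].
#' @return named numeric vector of CAI values in (0, 1].
#' @examples
#' refs <- c(paste(rep("GAA", 9), collapse = ""),
#'           paste(rep("GAG", 3), collapse = ""))
#' cai("GAAGAG", referenceWeights(refs))  # sqrt(1/3)
#' @export
cai <- function(cds, weights) {
  stopifnot(is(weights, "AdaptivenessTable"))
  seqs <- as.character(cds)
  if (length(seqs) == 0L) stop("no sequences", call. = FALSE)
  if (any(nchar(seqs) %% 3L != 0L))
    stop("CDS lengths must be divisible by 3", call. = FALSE)
  logw <- log(weights@w)
  out <- vapply(seq_along(seqs), function(i) {
    codons <- .splitCodons(seqs[[i]])
    nc <- length(codons)
    isStop <- codons %in% .STOP_CODONS
    if (any(isStop[-nc]))
      warning("internal stop codon in ",
              if (!is.null(names(seqs))) names(seqs)[i] else paste0("sequence ", i),
              "; excluded from CAI")
    keep <- codons %in% names(logw)  # drops stops, ATG/TGG, ambiguous
    if (!any(keep))
      stop("no countable codons in sequence ", i, call. = FALSE)
    exp(mean(logw[codons[keep]]))
  }, numeric(1L))
  names(out) <- names(seqs)
  out
}

#' Standardize CAI values within a species
#'
#' Centres and scales to mean 0 and (sample, n-1) standard deviation 1, so
#' codon bias can be compared across species.
#'
#' @param values numeric vector of per-gene CAI values (length >= 2, not all
#'   equal).
#' @return numeric vector of z-scores.
#' @export
standardizeCai <- function(values) {
  if (length(values) < 2L)
    stop("at least 2 values are required", call. = FALSE)
  s <- sd(values)
  if (s == 0) stop("zero variance: all CAI values identical", call. = FALSE)
  (values - mean(values)) / s
}

#' Two-sample comparison of gene-group values
#'
#' Two-tailed Student t-test, pooled variance by default (Welch available),
#' used for pre- versus post-WGD CAI contrasts and deletion-fitness group
#' comparisons.
#'
#' @param valuesA,valuesB numeric vectors (each length >= 2).
#' @param welch use the Welch unequal-variance test.
#' @return list with `statistic`, `p.value`, `df`, `meanA`, `meanB`.
#' @export
groupCompare <- function(valuesA, valuesB, welch = FALSE) {
  if (length(valuesA) < 2L || length(valuesB) < 2L)
    stop("each group needs at least 2 values", call. = FALSE)
  if (sd(valuesA) == 0 && sd(valuesB) == 0 &&
      mean(valuesA) == mean(valuesB))
    return(list(statistic = 0, p.value = 1,
                df = length(valuesA) + length(valuesB) - 2,
                meanA = mean(valuesA), meanB = mean(valuesB)))
  tt <- t.test(valuesA, valuesB, var.equal = !welch)
  list(statistic = unname(tt$statistic), p.value = tt$p.value,
       df = unname(tt$parameter), meanA = mean(valuesA),
       meanB = mean(valuesB))
}
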