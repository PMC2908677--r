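## GC-matched random-sequence null model and per-window enrichment tests.
##
## Random bases are i.i.d. with the symmetric decomposition
## P(G) = P(C) = gc/2 and P(A) = P(T) = (1 - gc)/2; the per_window mode draws
## each 50-bp window with its own GC fraction. The Fisher table unit is motif
## start positions versus eligible start positions, pooled over sequences,
## which is the only construction consistent with counting multiple window
## occurrences as independent events.

#' Estimate the background GC composition of a dataset
#'
#' GC fraction is pooled over the relevant bases of all genes,
#' `(#G + #C) / (#A + #C + #G + #T)`, with N excluded from numerator and
#' denominator.
#'
#' @param x a [SpeciesDataset-class] or `DNAStringSet` of downstream
#'   sequences.
#' @param mode `"full_region"` (all bases), `"utr250"` (first 250 bp of each
#'   sequence) or `"per_window"` (one GC fraction per window).
#' @param windowSize,regionLength window geometry for `"per_window"`.
#' @return a [GCModel-class].
#' @export
estimateGC <- function(x, mode = c("full_region", "utr250", "per_window"),
                       windowSize = 50L, regionLength = 1000L) {
  mode <- match.arg(mode)
  seqs <- if (is(x, "SpeciesDataset")) x@downstream else x
  if (length(seqs) == 0L) stop("empty dataset", call. = FALSE)
  windowSize <- as.integer(windowSize)
  regionLength <- as.integer(regionLength)
  pooledGC <- function(ss) {
    f <- alphabetFrequency(ss, baseOnly = TRUE)
    acgt <- colSums(f[, c("A", "C", "G", "T"), drop = FALSE])
    tot <- sum(acgt)
    if (tot == 0) stop("no countable (non-N) bases", call. = FALSE)
    unname((acgt[["G"]] + acgt[["C"]]) / tot)
  }
  if (mode == "full_region") {
    gc <- pooledGC(seqs)
  } else if (mode == "utr250") {
    gc <- pooledGC(subseq(seqs, 1L, pmin(width(seqs), 250L)))
  } else {
    nw <- ceiling(regionLength / windowSize)
    gc <- vapply(seq_len(nw), function(w) {
      lo <- (w - 1L) * windowSize + 1L
      keep <- width(seqs) >= lo
      if (!any(keep)) stop("no sequence reaches window ", w, call. = FALSE)
      ss <- seqs[keep]
      pooledGC(subseq(ss, lo, pmin(width(ss), w * windowSize)))
    }, numeric(1L))
  }
  new("GCModel", mode = mode, gc = gc, windowSize = windowSize,
      regionLength = regionLength)
}

## Integer-coded random sequence matrix (columns = sequences) under a GC
## model; gc may be scalar or a per-window vector.
.randomCoded <- function(n, len, gc, windowSize = 50L) {
  probs <- function(g) c((1 - g) / 2, g / 2, g / 2, (1 - g) / 2)
  if (length(gc) == 1L) {
    matrix(sample.int(4L, n * len, replace = TRUE, prob = probs(gc)),
           nrow = len, ncol = n)
  } else {
    nw <- ceiling(len / windowSize)
    if (length(gc) != nw)
      stop("per-window gc must have ", nw, " entries", call. = FALSE)
    blocks <- lapply(seq_len(nw), function(w) {
      wlen <- min(windowSize, len - (w - 1L) * windowSize)
      matrix(sample.int(4L, n * wlen, replace = TRUE, prob = probs(gc[w])),
             nrow = wlen, ncol = n)
    })
    do.call(rbind, blocks)
  }
}

#' Generate i.i.d. random nucleotide sequences under a GC model
#'
#' @param n number of sequences.
#' @param length sequence length in bp.
#' @param gc GC fraction; either a scalar or a per-window vector (one value
#'   per `windowSize` block).
#' @param seed optional integer seed (the caller's RNG state is preserved).
#' @param windowSize block size used when `gc` is a vector.
#' @return a named `DNAStringSet`.
#' @export
randomSequences <- function(n, length, gc, seed = NULL, windowSize = 50L) {
  M <- .withSeed(seed, .randomCoded(n, length, gc, windowSize))
  out <- DNAStringSet(vapply(seq_len(n), function(i) .decodeSeq(M[, i]),
                             character(1L)))
  names(out) <- sprintf("rand%05d", seq_len(n))
  out
}

#' Build the GC-matched null window counts from random sequences
#'
#' Generates `n` random sequences of the given length under the GC model and
#' counts profile matches per window, exactly as [countInWindows()] does for
#' observed genes.
#'
#' @param gcModel a [GCModel-class].
#' @param profile a [MotifProfile-class].
#' @param n number of random sequences (default 10000).
#' @param length sequence length in bp (default 1000).
#' @param seed optional integer seed for reproducibility.
#' @param windowSize window size in bp.
#' @return a [NullCounts-class].
#' @export
generateNull <- function(gcModel, profile, n = 10000L, length = 1000L,
                         seed = NULL, windowSize = 50L) {
  stopifnot(is(gcModel, "GCModel"), is(profile, "MotifProfile"))
  n <- as.integer(n)
  length <- as.integer(length)
  windowSize <- as.integer(windowSize)
  if (is.na(n) || n < 1L) stop("n must be >= 1", call. = FALSE)
  if (length %% windowSize != 0L)
    stop("windowSize must divide length", call. = FALSE)
  gc <- gcModel@gc
  if (gcModel@mode == "utr250") gc <- gc  # scalar, applied to full length
  M <- .withSeed(seed, .randomCoded(n, length, gc, windowSize))
  lookup <- .allowedLookup(profile)
  S <- length - 7L
  ## start-position validity across all sequences at once
  V <- lookup[[1L]][M[seq_len(S), , drop = FALSE] + 1L]
  dim(V) <- c(S, n)
  for (k in 2:8) {
    Wk <- lookup[[k]][M[k:(S + k - 1L), , drop = FALSE] + 1L]
    dim(Wk) <- c(S, n)
    V <- V & Wk
  }
  startCounts <- rowSums(V)
  nw <- length %/% windowSize
  win <- (seq_len(S) - 1L) %/% windowSize + 1L
  counts <- vapply(seq_len(nw), function(w) sum(startCounts[win == w]),
                   numeric(1L))
  eligible <- vapply(seq_len(nw), function(w) sum(win == w) * as.numeric(n),
                     numeric(1L))
  new("NullCounts", windowSize = windowSize, regionLength = length,
      counts = as.integer(counts), eligible = eligible, nGenes = n,
      nSequences = n, seqLength = length,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      gcModel = gcModel)
}

#' Per-window motif enrichment against the GC-matched null
#'
#' For each window a 2x2 table of
#' `[[obs, obs_eligible - obs], [null, null_eligible - null]]` is tested with
#' the one-sided (greater) Fisher's exact test; only enrichment is
#' interpreted. Bonferroni correction multiplies by the number of windows
#' tested (or by `nComparisons` when correcting across species).
#'
#' @param observed a [WindowCounts-class] of the scanned genes.
#' @param null a [NullCounts-class] (or `WindowCounts`) of the background.
#' @param alpha significance level applied to the corrected p (default
#'   0.01).
#' @param nComparisons number of tests to Bonferroni-correct over; defaults
#'   to the number of windows (per-species scope). Pass
#'   `nWindows * nSpecies` for a global scope.
#' @return data.frame with one row per window: `window_start`, `window_end`,
#'   `obs`, `obs_eligible`, `null_count`, `null_eligible`, `p_raw`,
#'   `p_bonferroni`, `significant`.
#' @export
windowEnrichmentTest <- function(observed, null, alpha = 0.01,
                                 nComparisons = NULL) {
  stopifnot(is(observed, "WindowCounts"), is(null, "WindowCounts"))
  if (observed@windowSize != null@windowSize ||
      observed@regionLength != null@regionLength)
    stop("observed and null window geometry differ", call. = FALSE)
  .assertScalarNumber(alpha, "alpha", 0, 1)
  a <- observed@counts; ae <- observed@eligible
  c0 <- null@counts; ce <- null@eligible
  if (any(ae < a) || any(ce < c0))
    stop("corrupt counts: eligible < count", call. = FALSE)
  nw <- length(a)
  if (is.null(nComparisons)) nComparisons <- nw
  ## one-sided (greater) Fisher = upper hypergeometric tail
  p_raw <- phyper(a - 1, m = a + c0, n = (ae - a) + (ce - c0), k = ae,
                  lower.tail = FALSE)
  p_bonf <- pmin(1, p_raw * nComparisons)
  data.frame(window_start = (seq_len(nw) - 1L) * observed@windowSize,
             window_end = seq_len(nw) * observed@windowSize,
             obs = a, obs_eligible = ae,
             null_count = c0, null_eligible = ce,
             p_raw = p_raw, p_bonferroni = p_bonf,
             significant = p_bonf < alpha)
}

#' Closed-form per-position match probability of a profile
#'
#' Probability that a random position under the i.i.d. GC model starts a
#' match: the product over positions of the summed base probabilities each
#' position admits.
#'
#' @param profile a [MotifProfile-class].
#' @param gc GC fraction.
#' @return numeric(1) probability.
#' @export
profileMatchProbability <- function(profile, gc) {
  .assertScalarNumber(gc, "gc", 0, 1)
  pbase <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  prod(vapply(profile@positions, function(s) sum(pbase[s]), numeric(1L)))
}

#' Regress per-species motif-gene counts on genomic GC content
#'
#' For each species the number of genes with at least one motif in the 3'
#' UTR cutoff region is regressed (ordinary least squares) on the pooled GC
#' fraction of its downstream sequences. An AT-rich element yields a
#' negative slope.
#'
#' @param datasets list of [SpeciesDataset-class] objects (at least 3).
#' @param profile a [MotifProfile-class].
#' @param utrCutoff 3' UTR cutoff in bp used for target calling.
#' @return list with `slope`, `intercept`, `r.squared`, `p.value` and the
#'   per-species `data` (species_id, gc, n_motif_genes).
#' @export
gcVsTargetRegression <- function(datasets, profile, utrCutoff = 250L) {
  if (length(datasets) < 3L)
    stop("at least 3 species are required for the regression", call. = FALSE)
  gc <- vapply(datasets, function(d) estimateGC(d, "full_region")@gc,
               numeric(1L))
  nt <- vapply(datasets, function(d)
    length(callTargets(d, profile, utrCutoff)@targets), numeric(1L))
  if (isTRUE(all.equal(var(gc), 0)) || var(gc) == 0)
    stop("zero variance in GC content across species", call. = FALSE)
  df <- data.frame(species_id = vapply(datasets, speciesId, character(1L)),
                   gc = gc, n_motif_genes = nt)
  fit <- lm(n_motif_genes ~ gc, data = df)
  s <- summary(fit)
  list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       r.squared = s$r.squared,
       p.value = unname(s$coefficients[2L, 4L]),
       data = df)
}
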