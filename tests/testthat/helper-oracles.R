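## Independent oracles used across test files. These deliberately avoid the
## package's own scanning/counting code paths.

## Character-class regex for a profile string (N -> [ACGT]).
profileRegex <- function(spec) {
  chars <- strsplit(spec, "", fixed = TRUE)[[1L]]
  paste0(ifelse(chars == "N", "[ACGT]", chars), collapse = "")
}

## Overlap-aware regex scan returning 0-based starts.
regexScanOracle <- function(seq, pattern) {
  m <- gregexpr(paste0("(?=", pattern, ")"), seq, perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m) - 1L
}

## i.i.d. random sequence under the symmetric GC model, as a plain string.
randSeq <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

## Upper-tail hypergeometric P(X >= k) by direct log-space summation:
## draw n from a population of N containing K successes.
hyperTailOracle <- function(k, K, n, N) {
  kk <- seq.int(max(k, max(0L, n - (N - K))), min(K, n))
  if (length(kk) == 0L) return(0)
  sum(exp(lchoose(K, kk) + lchoose(N - K, n - kk) - lchoose(N, n)))
}

## Bare WindowCounts builder for constructing test fixtures.
mkWindowCounts <- function(counts, eligible, windowSize, regionLength,
                           nGenes = 1L) {
  new("WindowCounts", windowSize = as.integer(windowSize),
      regionLength = as.integer(regionLength), counts = as.integer(counts),
      eligible = as.numeric(eligible), nGenes = as.integer(nGenes))
}

## A downstream sequence of given length with motifs planted at exact
## 0-based starts, on an otherwise motif-free C background.
plantedSeq <- function(length, starts, word = "TGTAAATA") {
  s <- rep("C", length)
  for (at in starts) s[(at + 1):(at + nchar(word))] <-
      strsplit(word, "")[[1L]]
  paste(s, collapse = "")
}
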