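## Internal helpers shared across modules.

.NUC <- c("A", "C", "G", "T")

## ASCII -> nucleotide code table: A=1, C=2, G=3, T=4, anything else 0.
## Code 0 (including N) never satisfies a profile position.
.ENC <- local({
  tab <- integer(128L)
  tab[utf8ToInt("A")] <- 1L
  tab[utf8ToInt("C")] <- 2L
  tab[utf8ToInt("G")] <- 3L
  tab[utf8ToInt("T")] <- 4L
  tab
})

## Encode a single upper-case nucleotide string as integer codes.
.encodeSeq <- function(x) {
  v <- utf8ToInt(x)
  v[v < 1L | v > 128L] <- 1L  # out-of-range bytes -> code 0 via table slot 1 ("")
  .ENC[v]
}

## Decode integer codes (1..4) to a nucleotide string.
.decodeSeq <- function(codes) {
  intToUtf8(c(65L, 67L, 71L, 84L)[codes])
}

## Deterministic 31-bit seed stream derived from a master seed and labels,
## so every simulation stage is independently reproducible.
.deriveSeed <- function(seed, ...) {
  key <- paste(c(format(seed), vapply(list(...), format, character(1L))),
               collapse = "/")
  v <- utf8ToInt(key)
  h <- 17
  for (x in v) h <- (h * 131 + x) %% 2147483647
  as.integer(h)
}

## Evaluate `expr` under a given seed without disturbing the caller's RNG
## state; seed = NULL leaves the RNG alone.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  expr
}

.assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stop(sprintf("'%s' must be a single number in [%s, %s]", name,
                 format(lower), format(upper)), call. = FALSE)
  invisible(x)
}
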