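## Readers and writers for the plain-text formats every stage consumes:
## FASTA for sequences, headered TSV for everything else.

#' Read a FASTA file of nucleotide sequences
#'
#' Sequences are upper-cased and validated against the A/C/G/T/N alphabet.
#' Headers are truncated at the first whitespace and must be unique. Wrapped
#' and unwrapped sequence lines are read identically.
#'
#' @param path path to a FASTA file.
#' @param ambiguous how to treat IUPAC ambiguity characters other than N:
#'   `"error"` (default, strict) rejects them, `"mapToN"` replaces them by N.
#' @return a named [Biostrings::DNAStringSet].
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">g1", "acgt"), f)
#' readFasta(f)
#' @export
readFasta <- function(path, ambiguous = c("error", "mapToN")) {
  ambiguous <- match.arg(ambiguous)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readBStringSet(path)
  if (length(raw) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(raw))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate id ", dup[[1L]], " in ", path, call. = FALSE)
  seqs <- toupper(as.character(raw))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    if (ambiguous == "error")
      stop("sequence ", ids[which(bad)[1L]],
           " contains characters outside ACGTN", call. = FALSE)
    seqs <- gsub("[^ACGTN]", "N", seqs)
  }
  if (any(nchar(seqs) == 0L))
    stop("empty sequence for id ", ids[which(nchar(seqs) == 0L)[1L]],
         call. = FALSE)
  out <- DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write a named sequence set to FASTA
#'
#' @param seqs a named `DNAStringSet` or character vector.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeFasta <- function(seqs, path) {
  if (!is(seqs, "DNAStringSet")) seqs <- DNAStringSet(seqs)
  writeXStringSet(seqs, filepath = path, width = 80L)
  invisible(path)
}

## Headered TSV reader with schema check.
.readTsv <- function(path, required, colClasses = NA) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.table(path, header = TRUE, sep = "\t", quote = "",
                   comment.char = "", stringsAsFactors = FALSE,
                   check.names = FALSE, colClasses = colClasses)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("%s: missing column(s) %s; expected [%s], found [%s]",
                 path, paste(missing, collapse = ", "),
                 paste(required, collapse = ", "),
                 paste(names(df), collapse = ", ")), call. = FALSE)
  df
}

#' Read a tab-separated table with a required schema
#'
#' @param path path to a TSV file with a header row.
#' @param columns character vector of required column names.
#' @return a data.frame (possibly with zero rows; a header-only file is
#'   valid).
#' @export
readTable <- function(path, columns = character(0)) {
  .readTsv(path, columns)
}

#' Read an ortholog map (species gene to reference gene) from TSV
#'
#' @param path TSV with columns `species_gene`, `reference_gene`.
#' @param speciesId species identifier recorded on the map.
#' @param referenceId reference identifier recorded on the map.
#' @return an [OrthologMap-class].
#' @export
readOrthologMap <- function(path, speciesId, referenceId = "reference") {
  df <- .readTsv(path, c("species_gene", "reference_gene"),
                 colClasses = "character")
  orthologMap(df, speciesId = speciesId, referenceId = referenceId)
}

#' Read a localization table (reference gene to compartment) from TSV
#'
#' @param path TSV with columns `gene`, `compartment`.
#' @return named character vector gene -> compartment (possibly several
#'   entries per gene).
#' @export
readLocalization <- function(path) {
  df <- .readTsv(path, c("gene", "compartment"), colClasses = "character")
  setNames(as.character(df$compartment), as.character(df$gene))
}

#' Read functional gene sets from TSV
#'
#' @param path TSV with columns `set_name`, `gene`.
#' @return named list of character vectors.
#' @export
readFunctionSets <- function(path) {
  df <- .readTsv(path, c("set_name", "gene"), colClasses = "character")
  lapply(split(as.character(df$gene), df$set_name), unique)
}

#' Read an expression matrix (genes x conditions of log2 ratios) from TSV
#'
#' @param path TSV with a `gene` column followed by one numeric column per
#'   condition; empty cells become NA.
#' @return numeric matrix with gene rownames and condition colnames.
#' @export
readExpressionMatrix <- function(path) {
  df <- .readTsv(path, "gene")
  if (ncol(df) < 2L) stop("expression matrix needs at least one condition",
                          call. = FALSE)
  genes <- as.character(df$gene)
  if (anyDuplicated(genes)) stop("duplicate gene ids in expression matrix",
                                 call. = FALSE)
  m <- as.matrix(df[, setdiff(names(df), "gene"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  m
}

#' Read a deletion-fitness table from TSV
#'
#' @param path TSV with columns `gene`, `condition`, `relative_growth`.
#' @return data.frame with typed columns.
#' @export
readFitnessTable <- function(path) {
  df <- .readTsv(path, c("gene", "condition", "relative_growth"))
  df$gene <- as.character(df$gene)
  df$condition <- as.character(df$condition)
  df$relative_growth <- as.numeric(df$relative_growth)
  df
}

#' Write a result table to TSV
#'
#' Probability columns (names starting with `p_` or named `p`/`p.value`) are
#' written in scientific notation at 10 significant digits so that a
#' round-trip through [readResultTable()] reproduces them to the printed
#' precision.
#'
#' @param results a data.frame.
#' @param path output path; the parent directory must exist.
#' @return the path, invisibly.
#' @export
writeResultTable <- function(results, path) {
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path), call. = FALSE)
  out <- as.data.frame(results)
  pcols <- grepl("^p($|_|\\.value)", names(out))
  for (j in which(pcols)) {
    if (is.numeric(out[[j]])) out[[j]] <- sprintf("%.9e", out[[j]])
  }
  write.table(out, file = path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read back a result table written by [writeResultTable()]
#'
#' @param path path to the TSV.
#' @return data.frame with numeric columns restored.
#' @export
readResultTable <- function(path) {
  df <- .readTsv(path, character(0))
  for (j in seq_along(df)) {
    if (is.character(df[[j]]) && length(df[[j]]) &&
        all(grepl("^[-+]?[0-9.]+([eE][-+]?[0-9]+)?$", df[[j]])))
      df[[j]] <- as.numeric(df[[j]])
  }
  df
}
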