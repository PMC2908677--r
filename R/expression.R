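## Expression-shift classification and co-expression correlation analysis of
## target versus non-target genes.

#' Classify genes as up-/down-regulated at a fold-change threshold
#'
#' A gene is down-regulated when its log2 ratio is `<= -log2(fold)` and
#' up-regulated when `>= +log2(fold)` (boundaries inclusive); otherwise
#' unchanged. Missing values are counted as unchanged with a warning.
#'
#' @param matrix numeric expression matrix (genes x conditions, log2
#'   ratios) as returned by [readExpressionMatrix()].
#' @param condition condition (column) name to classify on.
#' @param genes gene ids to classify; defaults to all rows. Ids absent from
#'   the matrix are an error.
#' @param fold fold-change threshold > 1 (default 1.5).
#' @return list with `n_down`, `n_up`, `n_unchanged`, `n_genes`, `fold`.
#' @export
classifyRegulation <- function(matrix, condition, genes = rownames(matrix),
                               fold = 1.5) {
  if (!is.matrix(matrix)) stop("'matrix' must be a matrix", call. = FALSE)
  if (length(condition) != 1L || !condition %in% colnames(matrix))
    stop("unknown condition: ", condition, call. = FALSE)
  .assertScalarNumber(fold, "fold", lower = 1 + 1e-12)
  missingGenes <- setdiff(genes, rownames(matrix))
  if (length(missingGenes))
    stop("gene(s) not in matrix: ", missingGenes[[1L]], call. = FALSE)
  v <- matrix[genes, condition]
  naCount <- sum(is.na(v))
  if (naCount > 0)
    warning(naCount, " missing value(s) treated as unchanged")
  thr <- log2(fold)
  down <- sum(v <= -thr, na.rm = TRUE)
  up <- sum(v >= thr, na.rm = TRUE)
  list(n_down = down, n_up = up,
       n_unchanged = length(v) - down - up,
       n_genes = length(v), fold = fold)
}

#' Association of regulation direction with target status
#'
#' Two-sided Fisher's exact test on the 2x2 table
#' `[[down_with, up_with], [down_without, up_without]]`, plus the
#' down-to-up ratio of each group.
#'
#' @param countsWith,countsWithout regulation counts for the target ("with
#'   element") and non-target groups, as returned by
#'   [classifyRegulation()].
#' @return list with `table`, `odds.ratio` (conditional MLE), `p.value`,
#'   `ratio_with`, `ratio_without` (down/up per group).
#' @export
regulationAssociation <- function(countsWith, countsWithout) {
  dw <- countsWith$n_down; uw <- countsWith$n_up
  dwo <- countsWithout$n_down; uwo <- countsWithout$n_up
  if (dw + uw == 0L || dwo + uwo == 0L)
    stop("a group has no regulated (up or down) genes", call. = FALSE)
  tab <- matrix(c(dw, uw, dwo, uwo), nrow = 2L, byrow = TRUE,
                dimnames = list(c("with", "without"), c("down", "up")))
  ft <- fisher.test(tab, alternative = "two.sided")
  list(table = tab, odds.ratio = unname(ft$estimate), p.value = ft$p.value,
       ratio_with = dw / uw, ratio_without = dwo / uwo)
}

#' Pairwise co-expression correlation distributions
#'
#' Pearson (or Spearman) correlations over pairwise-complete observations
#' for every unordered within-group pair and every between-group pair.
#' Pairs sharing fewer than `minShared` non-missing conditions are skipped
#' with a message. Compare any two of the returned distributions with
#' [groupCompare()].
#'
#' @param matrix numeric expression matrix (genes x conditions).
#' @param groupA,groupB character vectors of gene ids (disjoint).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param minShared minimum shared non-missing conditions per pair.
#' @return list with numeric vectors `within_a`, `within_b`, `between`.
#' @export
pairwiseCorrelations <- function(matrix, groupA, groupB,
                                 method = c("pearson", "spearman"),
                                 minShared = 3L) {
  method <- match.arg(method)
  groupA <- intersect(groupA, rownames(matrix))
  groupB <- intersect(groupB, rownames(matrix))
  if (length(intersect(groupA, groupB)))
    stop("groups must be disjoint", call. = FALSE)
  genes <- c(groupA, groupB)
  sub <- matrix[genes, , drop = FALSE]
  C <- suppressWarnings(cor(t(sub), use = "pairwise.complete.obs",
                            method = method))
  obs <- !is.na(sub)
  shared <- tcrossprod(obs * 1)
  skip <- shared < minShared
  nSkipped <- (sum(skip) - sum(diag(skip))) / 2
  if (nSkipped > 0)
    message(nSkipped, " pair(s) with fewer than ", minShared,
            " shared conditions skipped")
  C[skip] <- NA_real_
  takeUpper <- function(ids) {
    m <- C[ids, ids, drop = FALSE]
    v <- m[upper.tri(m)]
    v[!is.na(v)]
  }
  between <- as.vector(C[groupA, groupB, drop = FALSE])
  list(within_a = takeUpper(groupA),
       within_b = takeUpper(groupB),
       between = between[!is.na(between)])
}
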