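## Ortholog-based localization mapping and hypergeometric category
## enrichment; cross-clade comparison of target fractions.

#' Map species genes to reference compartments through orthology
#'
#' A species gene inherits the compartment(s) of its reference ortholog(s).
#' Genes without an annotated ortholog remain unassigned (they are excluded
#' from category tests but stay in the genome background).
#'
#' @param orthologs an [OrthologMap-class].
#' @param annotations an [AnnotationTable-class] (or a named character
#'   vector gene -> compartment).
#' @param policy `"all"` (default) retains every compartment of every
#'   ortholog (multi-membership); `"best"` keeps only the compartments of
#'   the lexicographically first reference ortholog.
#' @return data.frame with columns `species_gene`, `compartment` (several
#'   rows per gene possible under `"all"`).
#' @export
mapCategories <- function(orthologs, annotations, policy = c("all", "best")) {
  policy <- match.arg(policy)
  loc <- if (is(annotations, "AnnotationTable")) annotations@localization
         else annotations
  pairs <- orthologs@pairs
  if (policy == "best") {
    pairs <- pairs[order(pairs$species_gene, pairs$reference_gene), ]
    pairs <- pairs[!duplicated(pairs$species_gene), ]
  }
  idx <- which(names(loc) %in% pairs$reference_gene)
  ann <- data.frame(reference_gene = names(loc)[idx],
                    compartment = unname(loc[idx]),
                    stringsAsFactors = FALSE)
  out <- merge(pairs, ann, by = "reference_gene")
  out <- unique(out[, c("species_gene", "compartment")])
  out[order(out$species_gene, out$compartment), , drop = FALSE]
}

#' Hypergeometric enrichment of targets in localization categories
#'
#' For each category the upper-tail hypergeometric probability of drawing at
#' least the observed number of targets when sampling the category's genes
#' from the genome background, Bonferroni-corrected over categories.
#'
#' @param targetSet a [TargetSet-class].
#' @param categories data.frame `species_gene`/`compartment` as returned by
#'   [mapCategories()].
#' @param alpha significance level on the corrected p (default 0.01).
#' @param background `"all"` (default): every scanned gene of the species;
#'   `"annotated"`: only genes with a mapped compartment.
#' @return data.frame with one row per category: `species_id`, `category`,
#'   `n_category`, `n_category_targets`, `n_genome`, `n_genome_targets`,
#'   `p_raw`, `p_bonferroni`, `code` (red/black/green as corrected p is
#'   below/at/above `alpha`).
#' @export
categoryTest <- function(targetSet, categories, alpha = 0.01,
                         background = c("all", "annotated")) {
  background <- match.arg(background)
  .assertScalarNumber(alpha, "alpha", 0, 1)
  if (nrow(categories) == 0L) stop("no categories to test", call. = FALSE)
  bg <- if (background == "all") targetSet@universe
        else intersect(targetSet@universe, unique(categories$species_gene))
  N <- length(bg)
  tg <- intersect(targetSet@targets, bg)
  K <- length(tg)
  categories <- categories[categories$species_gene %in% bg, , drop = FALSE]
  cats <- sort(unique(categories$compartment))
  res <- lapply(cats, function(cc) {
    genes <- unique(categories$species_gene[categories$compartment == cc])
    n <- length(genes)
    if (n > N) stop("category larger than genome background", call. = FALSE)
    k <- length(intersect(genes, tg))
    p <- phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
    data.frame(species_id = targetSet@speciesId, category = cc,
               n_category = n, n_category_targets = k,
               n_genome = N, n_genome_targets = K,
               p_raw = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_bonferroni <- pmin(1, out$p_raw * length(cats))
  out$code <- ifelse(out$p_bonferroni < alpha, "red",
                     ifelse(out$p_bonferroni == alpha, "black", "green"))
  out
}

#' Compare per-species target fractions between two clades
#'
#' Two-sample two-tailed t-test (pooled variance) on per-species fractions,
#' e.g. the fraction of mitochondrial genes that are called targets.
#'
#' @param fractions named numeric vector of per-species fractions.
#' @param groups named character vector (same names) assigning each species
#'   to one of exactly two clades, each with at least 2 members.
#' @param welch use the Welch (unequal-variance) test instead of pooled.
#' @return list with `statistic`, `p.value`, `df`, `groupMeans`.
#' @export
cladeFractionCompare <- function(fractions, groups, welch = FALSE) {
  groups <- groups[names(fractions)]
  if (any(is.na(groups)))
    stop("every species needs a clade label", call. = FALSE)
  lev <- sort(unique(groups))
  if (length(lev) != 2L)
    stop("exactly two clades are required", call. = FALSE)
  a <- fractions[groups == lev[1L]]
  b <- fractions[groups == lev[2L]]
  if (length(a) < 2L || length(b) < 2L)
    stop("each clade needs at least 2 species", call. = FALSE)
  if (sd(a) == 0 && sd(b) == 0 && mean(a) == mean(b))
    return(list(statistic = 0, p.value = 1,
                df = length(a) + length(b) - 2,
                groupMeans = setNames(c(mean(a), mean(b)), lev)))
  tt <- t.test(a, b, var.equal = !welch)
  list(statistic = unname(tt$statistic), p.value = tt$p.value,
       df = unname(tt$parameter),
       groupMeans = setNames(c(mean(a), mean(b)), lev))
}
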