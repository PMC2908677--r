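---
title: "Methods: scanning, null models and regulon comparisons in PufRegulon"
author: "PufRegulon authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scanning, null models and regulon comparisons in PufRegulon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

PufRegulon studies how a post-transcriptional regulon — the set of mRNAs
recognised by one RNA-binding protein — is gained and lost across species.
Its model system is the Puf3p regulon of budding yeast: Puf3p binds an
8-nucleotide element (the P3E) in the 3' UTRs of nuclear-encoded
mitochondrial mRNAs and promotes their degradation and localisation. The
package implements the comparative analyses such a study needs and a
simulator that generates complete multi-species input bundles, so every
stage can be exercised and validated without genome downloads.

# The binding-element profile and the scan

The element is represented as an 8-position profile in which each position
carries a set of admitted nucleotides. The default, `TGTANATA` (the DNA
sense-strand rendering of the UGUA-N-AUA core), fixes seven positions and
leaves the fifth free. The profile is an explicit, configurable input
(`compileProfile()`) rather than a hard-coded constant, and all downstream
statistics are profile-agnostic.

Scanning (`scanSequence()`, `scanDownstream()`) is sense-strand only — the
element functions on the mRNA — and reports every 0-based offset whose full
8-mer satisfies all positions. `N` in a sequence matches nothing.
Overlapping matches are all reported; with the default profile overlaps
cannot occur, but degenerate profiles are allowed and the counting rule
("independent events") is honoured throughout.

Two boundary conventions are fixed and tested rather than left implicit:

* A match belongs to the 3' UTR region of width `utrCutoff` (default 250
  bp) only when the **whole** element lies inside it, i.e. 0-based start
  `<= utrCutoff - 8`. A binding site half outside the UTR is not a site.
* A match is assigned to the 50-bp window containing its **start** offset.
  Whether an element may straddle a window boundary is thereby resolved by
  the start-position rule.

# The GC-matched null model

Because the element is AT-rich, raw motif counts confound binding-site
conservation with genomic nucleotide composition. The null model therefore
draws random sequences i.i.d. with `P(G) = P(C) = gc/2` and
`P(A) = P(T) = (1 - gc)/2`, the simplest model matching a measured GC
fraction. Three background dialects are supported (`estimateGC()` modes):
GC of the full 1,000-bp downstream pool (default), of the first 250 bp
only, or per 50-bp window. The default null size is 10,000 sequences of
1,000 bp.

Per-window enrichment (`windowEnrichmentTest()`) uses a 2x2 table of motif
start positions versus eligible start positions (a start is eligible when
the full 8-mer fits), pooled over genes. Counting positions rather than
genes is the only construction consistent with treating multiple
occurrences per window as independent events. The test is one-sided
(greater) Fisher's exact — only enrichment is interpreted — with Bonferroni
correction over the windows tested (20 by default); a global scope across
species is available via `nComparisons`. The default significance level is
0.01 on the corrected p-value. Sequences shorter than the region contribute
eligible positions only where they exist, so truncated genes do not bias
late windows downward.

The closed form `profileMatchProbability()` gives the per-position match
probability as the product over positions of the admitted base
probabilities. Note that the default profile contains one fixed G, so its
match probability vanishes at both GC extremes; the often-quoted
`(1/2)^7` applies only to a G/C-free profile.

# Target calling, category enrichment and clades

Genes with at least one element inside the 250-bp UTR window are the called
target set. Localisation categories are transferred from a reference
species through ortholog tables; a species gene with several annotated
orthologs inherits all their compartments (multi-membership; a "best"
single-ortholog policy is available). Enrichment per category is the
upper-tail hypergeometric probability with the whole scanned gene set as
background (restriction to annotated genes is available), Bonferroni
corrected over categories. Per-species fractions of mitochondrial genes
that are targets are compared between clades with a two-sample pooled
t-test (`cladeFractionCompare()`); Welch's form is a flag.

# Conservation matrix and sliding functional fractions

`buildConservationMatrix()` records, per reference gene and species, one of
three states: target, present-but-not-target, or ortholog absent. The row
score is the fraction of *non-absent* cells in the target state — absence
of the gene is not evidence about the element. Rows are sorted by
decreasing score with ties broken lexicographically by gene id, making
output byte-reproducible. `slidingFunctionFraction()` then reports the
fraction of genes belonging to a function set (e.g. mitochondrial
translation) in overlapping 50-gene windows from the most to the least
conserved row; the step defaults to 1 row for the finest resolution.
In the pipeline the matrix is built over the high-rate clade's species,
where element conservation is informative.

# Codon adaptation index

`referenceWeights()` pools codon counts over the species' cytoplasmic
ribosomal protein genes (all ortholog copies) and assigns each codon its
count divided by the maximum within its synonymous family; unobserved
codons receive a 0.5 pseudo-count before normalisation (the Sharp & Li
convention). Stop codons and the single-codon families ATG and TGG carry no
usage information and are excluded. `cai()` is the geometric mean of the
weights over a gene's codons; internal stop codons are excluded with a
warning. CAI values are standardised within each species to mean 0 and
sample sd 1 so codon bias is comparable across species with different
global usage.

Group contrasts (`groupCompare()`) default to the pooled-variance two-tailed
t-test. The clade contrast in the pipeline compares the **pooled per-gene**
standardised values of each group between clades rather than the five
species means: the per-gene pool carries the same effect estimate with a
well-behaved variance estimate, and the per-species means remain in the
output table for plotting.

One subtlety of within-species standardisation deserves note: when a
subpopulation of genes is shifted, the standardisation baseline moves by
(shifted fraction) x (shift), so the complementary group acquires a small
apparent opposite shift. With realistic proportions (~7% of the genome in
the shifted group) this spillover is below 0.04 standard deviations and the
no-shift contrast stays at chance level; validation allows for it
explicitly.

# Expression and fitness

Expression log2 ratios are classified per condition as down- or
up-regulated at a 1.5-fold threshold with **inclusive** boundaries
(`|log2 ratio| >= log2(1.5)`); missing values count as unchanged, with a
warning. The association between regulation direction and element status is
the two-sided Fisher's exact test on the down/up 2x2 table, reported with
each group's down-to-up ratio. Co-expression is summarised by Pearson
correlations (Spearman by flag) over pairwise-complete observations for all
within- and between-group pairs; pairs sharing fewer than 3 conditions are
skipped and logged. Deletion-fitness tables are compared per condition with
the same two-sample t-test.

# The simulator: what it emulates and what it does not

`simulationConfig()` defines the study conditions; its defaults are the
demo study: two clades of 5 species, 1,000 genes per species of which 300
are mitochondrial and 40 ribosomal, 1,000-bp downstream regions, elements
planted within the first 250 bp, GC fractions spread over 0.32-0.44 within
each clade (a realistic fungal range that also gives the GC regression
genuine spread).

* **Motif planting.** The first clade plants elements in mitochondrial
  genes at a mean rate of ~0.5, split into a conserved core (120 genes at
  rate 0.9) and a peripheral tier (180 genes at 0.23); everything else,
  and the entire second clade, is planted at the 0.1 background rate. The
  two-tier design gives the conservation ranking genuine high/low
  structure: the mitochondrial-translation function set takes 83% of core
  and 4.5% of peripheral genes, so sliding fractions fall from ~0.8 at the
  top of the ranking to ~0.04 at the bottom. Planting overwrites bases
  (length-preserving) with an admitted 8-mer drawn uniformly from the
  profile expansion, at a uniform admissible start.
* **Codon bias.** Each gene carries a preferred-codon usage probability
  `b ~ N(0.5, 0.12)` (ribosomal reference genes: 0.9); codons are drawn
  preferred-vs-uniform-family accordingly. Motif-bearing mitochondrial
  genes of the post-WGD clade have `b` depressed by
  `caiShift x biasSd x 1.45`; the 1.45 calibration compensates the
  attenuation by codon-sampling noise at the default 120-codon CDS length,
  so the realised within-species CAI z-shift approximates `caiShift`
  (default -0.5).
* **Expression.** Log2 ratios are Gaussian with per-condition sd 0.5 — a
  typical two-colour-array noise level — with a shared factor giving the
  motif group within-group correlation 0.5, and a -1.0 log2 shift in the
  labelled fermentative condition. 50 conditions by default; the
  compendium-scale checks use 1,011.
* **Fitness.** Relative growth ~ N(1, 0.1), with the motif group depressed
  by one sd under the non-fermentative condition only.

All randomness flows from one master seed through per-species and per-stage
derived streams, so every stage is independently reproducible and two runs
of the pipeline under one seed produce byte-identical bundles.

The simulator emulates the *statistical* structure the analyses assume. It
does **not** emulate phylogenetic sequence evolution (species are
independent draws, not a tree), indels or length variation, UTR length
distributions, dinucleotide composition, probe-level microarray artefacts,
or duplicate-gene histories beyond the clade labels. Passing validation on
these fixtures therefore demonstrates that the statistics recover planted
structure at realistic effect sizes and error rates — not that any
particular biological dataset will show such structure.

# Validation scale and numerical choices

Validation runs at sizes chosen to finish on a single CPU in minutes while
keeping every test at full statistical strength: oracle equivalence on
1,000 random kilobase sequences per GC level; type-I error over 200
null-model species of 200 genes against one shared 10,000-sequence null
(the species are drawn from the same GC model the null uses); 50-replicate
recovery runs for planted enrichment (1,000 genes, 500 planted), the CAI
contrast (eight species of 1,000 genes, 150 mitochondrial — the same ~7%
shifted fraction a real genome would give) and the expression association;
and a byte-identity check over two full demo runs. The no-shift CAI
contrast is allowed up to 5/50 nominally significant replicates, the a
priori allowance for the standardisation spillover described above.

Numerical conventions: probabilities are written in scientific notation at
10 significant digits and round-trip through the readers to that precision;
hypergeometric tails are computed directly (`phyper`), and the equivalence
with Fisher's one-sided test is asserted, not assumed; ties in conservation
scores are broken by gene id; degenerate inputs (zero-variance groups,
empty categories, all-N sequences, windows larger than the matrix) raise
errors rather than propagating NaN.

# Known limitations

* The i.i.d. GC null ignores dinucleotide and codon-boundary structure;
  a Markov background is out of scope by design.
* Ortholog tables are consumed, never inferred; errors in orthology
  propagate directly into category transfer and conservation states.
* The clade comparison treats species as independent observations; no
  phylogenetic correction is applied.
* CAI uses amino-acid synonymous families; separate treatment of
  serine/leucine sub-families is not implemented.
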