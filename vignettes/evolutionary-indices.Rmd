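---
title: "Evolutionary indices: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolutionary indices: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evoindex)
```

This vignette documents the models behind `evoindex`, the conventions it
fixes where the underlying methods leave room, and what the synthetic-data
generators do and do not emulate.

## Gene age: the phylostratigraphic model

The age of a gene is located on a *lineage tree*: every species is a path of
taxon names from a shared root down to its terminal species taxon, and the
last common ancestor of two species is the end of their longest common name
prefix. Depth is **1-based from the root** (root = 1), so for the 7-level
human lineage a human-specific gene has PAI 7 and a gene shared with all
eukaryotes has PAI 2. Smaller PAI means older. This convention makes the PAI
directly comparable across genes of one target species; it is *not*
comparable across taxonomies of different granularity, because the package
deliberately treats whatever lineage table it is given as the stratum
system — KEGG-style taxonomies and curated phylostrata are both acceptable,
and the choice of table defines the age scale.

Given the set of species bearing orthologs of a gene, the PAI is the
*minimum* LCA depth between the target and any member of the set (the target
is always an implicit member, so the empty set yields the full lineage
length — the youngest possible stratum). Two consequences are used as test
invariants: adding a species can only decrease the PAI, and
1 ≤ PAI ≤ lineage length always.

Design choices here:

* Lineages are matched as **name-prefix paths**, not rank-aligned columns;
  ranks need not be uniform across species.
* Species in the ortholog set but absent from the taxonomy are **skipped
  with a warning** (and recorded in the result) by default; a `strict` flag
  turns this into an error. Partial lineage tables are common enough that a
  hard failure is the wrong default for batch runs.
* When several species attain the minimal depth, the reported
  `most_distant_species` is the lexicographically smallest code — an
  arbitrary but deterministic tie-break.

## Two orthology sources

**KO groups.** The species set of a gene is the union of species over the
gene's own ortholog groups. A species counts once however many paralogs it
contributes, so the PAI is unaffected by the paralog-filter option; the
option instead controls whether same-species co-members (paralogs) are kept
in the member table that downstream steps may consume. Genes without any
group raise an explicit "no KO assignment" error (a realistic condition:
a large fraction of genes lack curated orthology), which batch drivers
degrade to an `NA` cell.

**Best-similarity tables.** Records carry identity (a fraction in [0, 1])
and a Smith–Waterman score; a record passes if
`identity >= identity_min` **and** `sw_score >= sw_min`, both inclusive, so
the default identity threshold 0.5 is usable as an exact boundary. The
default `sw_min = 100` is a conventional protein-search cutoff and is
configurable; both thresholds are echoed into the run metadata. Passing
records collapse to their species set before the PAI computation, making
the result idempotent in per-species record multiplicity.

## The Smith–Waterman scorer

The local aligner is a Gotoh-style affine-gap dynamic program with a score
floor of zero. Conventions that matter for reproducibility:

* A gap run of length $k$ costs `gap_open` $+ k\,\cdot$ `gap_extend`
  (opening charged once per run, extension per gapped position) — the same
  convention as Biostrings' `pairwiseAlignment`, against which the scorer is
  cross-checked in the tests.
* **Identity** is computed from one optimal traceback as identical columns
  divided by *all* alignment columns, gap columns included. Tie-breaks in
  the traceback prefer the diagonal (substitution) move. Identity
  normalised by alignment length is the convention of similarity-table
  exports; callers needing query-length normalisation can rescale using the
  returned alignment length.
* A score of 0 means the empty alignment: identity 0 by definition.
* Default schemes: BLOSUM62 with open −10 / extend −1 for proteins;
  match +1 / mismatch −1 (open −2 / extend −1) for nucleotide fixtures.

The test suite also checks the scorer against a brute-force oracle that
enumerates every local alignment as a pair of matched-position subsets —
exhaustively for all sequence pairs up to length 3 and on random pairs up
to length 6.

## dN/dS: NG86 with Jukes–Cantor correction

The divergence estimator is the Nei–Gojobori (1986) counting method. For
each codon, each of the three positions contributes the fraction of its
three possible changes that are synonymous; **changes to stop codons count
as nonsynonymous**, which is what makes the site identity
$S + N = \text{sequence length}$ hold exactly (a tested invariant). Site
counts are averaged over the two sequences. Codons differing at several
positions are scored by averaging the synonymous/nonsynonymous step counts
over all substitution pathways (orderings of the differing positions);
pathways passing through a stop codon are excluded. In the rare case that
*every* pathway is blocked by a stop, the average over all pathways is used
rather than dropping the codon — a documented fallback that keeps the
difference counts defined.

The proportions $p_S = S_d/S$ and $p_N = N_d/N$ are corrected with
$d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$, undefined for $p \ge 3/4$.
Policies for the degenerate cases are explicit and flagged in the result
object rather than silently patched:

* $dS = 0$: the ratio is undefined; the pair is flagged `dS_zero` and
  excluded from DI averaging (treating it as an infinite ratio would make
  DI non-finite; the exclusion count is reported).
* $p \ge 3/4$: flagged `correction_out_of_range` and excluded. Note that
  very short pairs can hit this boundary with a *single* substitution — two
  codons with a synonymous change between them have only $1/3$ synonymous
  sites each, giving $p_S = 3$.
* Sequences must be **codon-aligned and of equal length**; indel handling
  and codon-aware alignment are out of scope. A shared terminal stop codon
  is tolerated and dropped before counting. Only the standard genetic code
  is supported, enforced at parse time.

The estimator name (`NG86+JC69`) is recorded in every result so values are
not mistaken for maximum-likelihood (codeml/yn00-style) estimates, which
this package intentionally does not implement: a counting estimator is
deterministic, dependency-free, and verifiable against an independent
pathway-enumeration oracle, which the tests do exactly for all pairs of up
to five codons.

The **divergence index** of a gene is the arithmetic mean of the defined
ratios over its homolog pairs; with one homolog it equals that pair's
ratio. The comparison set is chosen either explicitly (validated species
codes) or by *taxonomic level* $k$: all species sharing at least the first
$L - k$ taxa with the target's lineage of length $L$, so level 1 is the
target's genus, level 2 its family, and so on. Multiple homologs within one
comparison species are all used as separate pairs.

## TAI and TDI

Both transcriptome indices are expression-weighted means,
$\mathrm{TAI}_s = \sum_i ps_i e_{is} / \sum_i e_{is}$ and
$\mathrm{TDI}_s = \sum_i DI_i e_{is} / \sum_i e_{is}$, computed per
condition over the genes present in both the expression matrix and the
index map. Exact consequences used as test oracles: uniform expression
reduces TAI to the arithmetic mean PAI; rescaling a condition column by any
$c > 0$ changes nothing (to 1e-12 in the tests); the value is bounded by
the min and max of the participating indices; and inflating the expression
of the maximal-PAI gene never lowers TAI.

Expressed genes without a PAI (or DI) are **dropped with a message** and
counted, because real expression tables routinely contain unannotated
genes; a `strict` flag turns the drop into an error. Expression values are
used exactly as supplied — the package performs no normalisation, and the
indices are only as comparable across conditions as the input
normalisation makes them. A condition whose usable expression sums to zero
yields an `NA` cell with an explicit reason, never an abort of the other
conditions.

## Networks

Networks are undirected (STRING semantics). The TSV importer accepts the
STRING export dialect (header with `node1`/`node2` and an optional
`combined_score` mapped to the edge weight) or headerless two/three-column
edge lists; weights outside [0, 1] are a hard error naming the row.
Duplicate undirected edges merge keeping the **maximum** weight
(deterministic and conservative for confidence scores); self-loops are kept
but reported. Annotation never changes node/edge sets or weights.

The PAI colour scale is a fixed 10-entry light-to-dark sequential palette:
within a stratum range of at most 10 the mapping is injective
(stratum → palette entry); wider ranges are binned evenly, preserving
monotonicity. Unscored nodes are white (`#FFFFFF`), the neutral colour also
used for non-gene entities in pathway renderings. TSV export is lossless
for node/edge sets and weights provided every node has at least one edge
(the format carries no isolated-node records); GraphML and Cytoscape JSON
carry all node attributes including the colour.

## Synthetic data and what passing tests mean

The generators exist to make recovery *exact*, not to be realistic:

* `gen_taxonomy` builds a random lineage trie (shared root, random
  branching, termination depths between 2 and `max_depth`, at least two
  species at the maximum depth).
* `gen_ortholog_data` draws each gene's true stratum $d$ uniformly from the
  depths actually attainable against the target and places orthologs in
  exactly the species with LCA depth ≥ $d$ — so the minimum is $d$ by
  construction and both the KO and the similarity route must recover it
  for 100 % of genes. True orthologs get identity/score above the default
  thresholds (0.55–0.95 / 150–900), decoys below both (< 0.5 / < 100).
* `gen_codon_pair` plants exactly the requested synonymous and
  nonsynonymous substitution counts with **at most one substitution per
  codon**, never creating stops. One substitution per codon makes NG86's
  pathway averaging exact against the planted truth; multi-hit codons are
  exercised separately against the enumeration oracle, where the expected
  values are computed rather than planted.
* `gen_expression` offers uniform (the TAI = mean-PAI hook), random, and
  oldest-biased profiles; the bias weights expression by
  $\max(ps) - ps_i + 1$, which provably pulls TAI below the uniform value
  whenever PAIs vary.
* All generators are pure functions of their seed and parameters
  (Mersenne–Twister, seeded locally without touching the caller's random
  state) — reruns are identical.

None of this emulates real molecular evolution: there is no
transition/transversion bias, no rate heterogeneity, no indels, no
correlation between gene age and sequence divergence, and similarity scores
are drawn, not computed from sequences. Passing recovery tests therefore
demonstrates that the *computations* are correct on inputs satisfying their
contracts — not that the indices are robust to alignment error, annotation
noise, or taxonomy misspecification in real data.

Problem sizes used by the standard checks — 50 species at depth ≤ 8 with
100 genes for recovery; 1,000 random pairs for site conservation; 200 pairs
of ≤ 5 codons against the enumeration oracle; 500 random pairs (plus the
exhaustive length ≤ 3 set) for the aligner; 1,000 taxonomy/species-set
cases for monotonicity — keep the whole suite in the low minutes on one CPU
while exercising every branch; they are fixed in the tests rather than
scaled to the machine.

## Known limitations

* No alignment of unaligned CDS: dN/dS requires codon-aligned input.
* Counting-based dN/dS only; no ML models, no branch/site heterogeneity.
* The PAI is only as good as the supplied lineage table and homolog
  detection; the package does not model homology-detection failure, the
  best-known systematic bias of phylostratigraphic age estimates.
* The pure-R aligner is quadratic and intended for building small
  similarity tables, not genome-scale searches.
* TSV network export cannot represent isolated nodes.
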