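Package: evoindex
Title: Phylostratigraphic Age and Divergence Indices for Genes and Gene Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Offline computation of evolutionary indices for genes, gene
    sets and gene networks. Implements phylostratigraphic age indices (PAI)
    from ortholog distributions over a taxonomic lineage table, either via
    ortholog-group (KO) membership or via best-similarity tables filtered by
    sequence identity and Smith-Waterman score; pairwise dN/dS by
    Nei-Gojobori (1986) codon counting with Jukes-Cantor correction,
    aggregated into a per-gene divergence index (DI); expression-weighted
    transcriptome age and divergence indices (TAI/TDI); and import,
    annotation and export of gene networks in the STRING edge-list dialect.
    Includes seeded synthetic-data generators that plant known ground truth
    for every input the pipeline consumes, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
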