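test_that("gen_taxonomy is deterministic and satisfies its contract", {
  t1 <- gen_taxonomy(1L, 10L, 5L)
  t2 <- gen_taxonomy(1L, 10L, 5L)
  expect_identical(t1, t2)
  expect_false(identical(t1, gen_taxonomy(2L, 10L, 5L)))

  depths <- vapply(species_codes(t1), function(s)
    length(lineage(t1, s)), integer(1L))
  expect_gte(sum(depths == 5L), 2L)  # at least two species at max depth
  expect_true(all(depths >= 2L & depths <= 5L))
  roots <- vapply(species_codes(t1), function(s)
    lineage(t1, s)[1L], character(1L))
  expect_identical(unique(roots), "root")

  two <- gen_taxonomy(3L, 2L, 3L)
  expect_length(unique(species_codes(two)), 2L)
  expect_error(gen_taxonomy(1L, 1L, 5L), "n_species")
  expect_error(gen_taxonomy(1L, 5L, 1L), "max_depth")
})

test_that("planted gene ages are recovered by pai from both data sources", {
  tax <- gen_taxonomy(5L, 20L, 6L)
  od <- gen_ortholog_data(6L, tax, 30L)
  expect_identical(od, gen_ortholog_data(6L, tax, 30L))  # deterministic
  thr <- homolog_thresholds()
  for (gene in names(od$truth)) {
    sp <- species_with_orthologs_ko(gene, od$komap)
    expect_identical(pai(od$target, sp, tax, gene = gene)$pai,
                     od$truth[[gene]], info = gene)
    rec <- od$similarity[od$similarity$query_gene == gene, , drop = FALSE]
    expect_identical(
      pai_bst(gene, rec, thr, tax, od$target)$pai, od$truth[[gene]],
      info = gene)
  }
  # decoy records never pass the default thresholds
  decoys <- od$similarity[od$similarity$subject_gene !=
                            od$similarity$query_gene, , drop = FALSE]
  expect_identical(nrow(filter_homologs(decoys, thr)), 0L)
})

test_that("a gene planted at the deepest stratum stays species-restricted", {
  tax <- gen_taxonomy(5L, 12L, 5L)
  od <- gen_ortholog_data(8L, tax, 40L)
  L <- length(lineage(tax, od$target))
  deep <- names(od$truth)[od$truth == L]
  expect_gt(length(deep), 0L)
  for (gene in deep) {
    members <- attr(species_with_orthologs_ko(gene, od$komap), "members")
    expect_identical(unique(members$species), od$target)
  }
})

test_that("gen_codon_pair plants exact substitution counts", {
  p <- gen_codon_pair(9L, 100L, 5L, 0L)
  r <- ng86_pair(p$a, p$b)
  expect_identical(r$syn_diffs, 5)
  expect_identical(r$nonsyn_diffs, 0)

  q <- gen_codon_pair(9L, 100L, 0L, 4L)
  rq <- ng86_pair(q$a, q$b)
  expect_identical(rq$syn_diffs, 0)
  expect_identical(rq$nonsyn_diffs, 4)

  none <- gen_codon_pair(9L, 100L, 0L, 0L)
  expect_identical(none$a$nt, none$b$nt)
  expect_identical(gen_codon_pair(9L, 50L, 3L, 2L),
                   gen_codon_pair(9L, 50L, 3L, 2L))
  expect_error(gen_codon_pair(9L, 4L, 3L, 2L), "exceed")
})

test_that("gen_expression honours its profile contract", {
  genes <- sprintf("g%d", 1:6)
  uni <- gen_expression(10L, genes, c("a", "b"), "uniform")
  expect_identical(length(unique(as.vector(uni$values))), 1L)
  expect_identical(gen_expression(10L, genes, "a", "random"),
                   gen_expression(10L, genes, "a", "random"))
  expect_error(gen_expression(10L, character(0L), "a"), "non-empty")

  ps <- stats::setNames(c(1, 1, 2, 3, 5, 5), genes)
  biased <- gen_expression(11L, genes, "a", "oldest_biased", pai = ps)
  e_uni <- stats::setNames(uni$values[, "a"], genes)
  e_bias <- stats::setNames(biased$values[, "a"], genes)
  # weight on low-PAI (old) genes pulls TAI below the uniform value
  expect_lt(tai(ps, e_bias)$value, tai(ps, e_uni)$value)
  expect_error(gen_expression(11L, genes, "a", "oldest_biased"), "needs")
})

test_that("gen_network writes valid STRING-dialect TSV", {
  genes <- sprintf("g%d", 1:8)
  lines <- gen_network(12L, genes, 10L)
  expect_identical(lines, gen_network(12L, genes, 10L))
  f <- withr::local_tempfile(lines = lines)
  net <- parse_network_tsv(f)
  expect_identical(nrow(net$edges), 10L)
  expect_true(all(net$edges$weight >= 0 & net$edges$weight <= 1))
  expect_false(any(duplicated(net$edges[, c("node1", "node2")])))
  expect_error(gen_network(12L, genes, 100L), "exceeds")
})

test_that("the fixture bundle writes every pipeline input re-parseably", {
  dir <- withr::local_tempdir()
  paths <- write_fixture_bundle(dir, seed = 13L, n_species = 12L,
                                max_depth = 5L, n_genes = 8L,
                                n_conditions = 3L)
  expect_true(all(file.exists(unlist(paths))))
  tax <- parse_lineage_table(paths$lineage)
  expect_length(species_codes(tax), 12L)
  komap <- parse_ko_table(paths$ko)
  sim <- parse_similarity_table(paths$similarity)
  cds <- read_cds_fasta(paths$cds)
  em <- parse_expression_matrix(paths$expression)
  net <- parse_network_tsv(paths$network)
  truth <- jsonlite::read_json(paths$truth)
  expect_length(truth$pai, 8L)
  expect_identical(em$conditions, sprintf("cond%02d", 1:3))
  expect_identical(sort(names(truth$pai)), sort(em$genes))
  # planted per-pair substitution classes are recovered by NG86 counting
  target <- truth$target
  for (key in names(truth$pairs)[1:4]) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1L]]
    ti <- which(vapply(cds, function(s)
      s$gene_id == parts[1L] && s$species_code == target, logical(1L)))
    hi <- which(vapply(cds, function(s)
      s$gene_id == parts[1L] && s$species_code == parts[2L], logical(1L)))
    r <- ng86_pair(cds[[ti]], cds[[hi]])
    expect_identical(r$syn_diffs, as.numeric(truth$pairs[[key]]$syn))
    expect_identical(r$nonsyn_diffs, as.numeric(truth$pairs[[key]]$nonsyn))
  }
})
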