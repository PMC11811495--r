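# End-to-end drivers on a small fixture bundle.

local_bundle <- function(seed = 17L, env = parent.frame()) {
  dir <- withr::local_tempdir(.local_envir = env)
  paths <- write_fixture_bundle(dir, seed = seed, n_species = 15L,
                                max_depth = 6L, n_genes = 12L,
                                n_conditions = 3L)
  truth <- jsonlite::read_json(paths$truth)
  list(dir = dir, paths = paths, truth = truth,
       out = file.path(dir, "out"),
       pai_truth = unlist(truth$pai), target = truth$target)
}

test_that("run_pai recovers planted PAIs under both methods", {
  b <- local_bundle()
  cfg_ko <- run_config(out = b$out, method = "KO",
                       taxonomy = b$paths$lineage, genes = b$paths$genes,
                       ko = b$paths$ko, target = b$target)
  res_ko <- run_pai(cfg_ko)
  expect_identical(res_ko$Gene, names(b$pai_truth))  # input order preserved
  expect_identical(res_ko$PAI, unname(as.numeric(b$pai_truth)))

  cfg_bst <- run_config(out = file.path(b$dir, "out_bst"), method = "BST",
                        taxonomy = b$paths$lineage, genes = b$paths$genes,
                        similarity = b$paths$similarity, target = b$target)
  res_bst <- run_pai(cfg_bst)
  expect_identical(res_bst$PAI, res_ko$PAI)  # both modes see the same truth

  lines <- readLines(file.path(b$out, "gene_index.tsv"))
  expect_identical(lines[1L], "Gene\tLabel\tPAI\tDI")
  expect_true(file.exists(file.path(b$out, "run_metadata.json")))
})

test_that("genes absent from the inputs degrade to NA rows, not aborts", {
  b <- local_bundle()
  glist <- file.path(b$dir, "genes_extra.txt")
  writeLines(c(names(b$pai_truth)[1:3], "not_a_gene"), glist)
  cfg <- run_config(out = b$out, method = "KO", taxonomy = b$paths$lineage,
                    genes = glist, ko = b$paths$ko, target = b$target)
  expect_warning(res <- run_pai(cfg), "not_a_gene")
  expect_identical(nrow(res), 4L)
  expect_true(is.na(res$PAI[4L]))
  expect_false(anyNA(res$PAI[1:3]))
  # strict mode aborts instead
  cfg$strict <- TRUE
  expect_error(run_pai(cfg), "no KO assignment")
})

test_that("run_di fills DI from codon-aligned homolog pairs", {
  b <- local_bundle()
  cfg <- run_config(out = b$out, method = "KO", taxonomy = b$paths$lineage,
                    genes = b$paths$genes, ko = b$paths$ko,
                    target = b$target)
  run_pai(cfg)
  cfg$cds <- b$paths$cds
  cfg$organisms <- unlist(b$truth$comparison_species)
  res <- run_di(cfg)
  expect_identical(res$Gene, names(b$pai_truth))
  expect_identical(res$PAI, unname(as.numeric(b$pai_truth)))  # preserved
  expect_true(all(is.finite(res$DI)))
  expect_true(all(res$DI >= 0))

  # a single-organism comparison set makes DI that pair's dN/dS
  cds <- read_cds_fasta(cfg$cds)
  sp1 <- cfg$organisms[1L]
  cfg1 <- cfg
  cfg1$out <- file.path(b$dir, "out_single")
  cfg1$organisms <- sp1
  res1 <- run_di(cfg1)
  gene <- res1$Gene[1L]
  seq_of <- function(sp) cds[[which(vapply(cds, function(s)
    s$gene_id == gene && s$species_code == sp, logical(1L)))]]
  expect_equal(res1$DI[1L],
               ng86_pair(seq_of(b$target), seq_of(sp1))$ratio)
})

test_that("run_phylo writes the Data/TAI/TDI table from the gene index", {
  b <- local_bundle()
  cfg <- run_config(out = b$out, method = "KO", taxonomy = b$paths$lineage,
                    genes = b$paths$genes, ko = b$paths$ko,
                    target = b$target, expression = b$paths$expression,
                    cds = b$paths$cds,
                    organisms = unlist(b$truth$comparison_species))
  run_pai(cfg)
  run_di(cfg)
  prof <- run_phylo(cfg)
  expect_identical(prof$Data, sprintf("cond%02d", 1:3))
  lines <- readLines(file.path(b$out, "profile.tsv"))
  expect_identical(lines[1L], "Data\tTAI\tTDI")
  expect_identical(length(lines), 4L)

  # uniform expression: TAI equals the mean planted PAI in every condition
  uni <- gen_expression(99L, names(b$pai_truth), c("u1", "u2"), "uniform")
  pu <- phylo_profile(uni, stats::setNames(as.numeric(b$pai_truth),
                                           names(b$pai_truth)))
  expect_equal(pu$TAI, rep(mean(as.numeric(b$pai_truth)), 2L))
})

test_that("run_network colours nodes by planted PAI and round-trips", {
  b <- local_bundle()
  cfg <- run_config(out = b$out, method = "KO", taxonomy = b$paths$lineage,
                    genes = b$paths$genes, ko = b$paths$ko,
                    target = b$target, network = b$paths$network)
  run_pai(cfg)
  net <- suppressMessages(run_network(cfg))
  expect_true(all(file.exists(file.path(b$out, c(
    "network_annotated.tsv", "network.graphml", "network.json")))))
  # colours follow the planted strata deterministically
  rng <- range(b$pai_truth)
  expected <- vapply(unname(b$pai_truth[net$nodes$gene]), pai_color,
                     character(1L), pai_min = rng[1L], pai_max = rng[2L])
  expect_identical(net$nodes$color, expected)
  back <- parse_network_tsv(file.path(b$out, "network_annotated.tsv"))
  expect_identical(back$edges, net$edges)
  expect_identical(back$nodes$gene, net$nodes$gene)
})

test_that("missing required inputs fail with a clear message", {
  cfg <- run_config(out = withr::local_tempdir(), method = "KO")
  expect_error(run_pai(cfg), "missing required field")
  cfg2 <- run_config(out = withr::local_tempdir(), method = "KO",
                     taxonomy = "/nonexistent/lineage.tsv",
                     genes = "/nonexistent/genes.txt", ko = "/nonexistent/ko",
                     target = "sp001")
  expect_error(run_pai(cfg2), "not found")
})

test_that("the command-line script drives the full pipeline with exit 0", {
  exe <- file.path(system.file(package = "evoindex"), "exec", "evoindex")
  expect_true(file.exists(exe))
  b <- local_bundle()
  rlibs <- paste(.libPaths(), collapse = .Platform$path.sep)
  run_cli <- function(...) {
    withr::local_envvar(R_LIBS = rlibs, R_LIBS_USER = rlibs)
    suppressWarnings(system2("Rscript", c(exe, ...), stdout = TRUE,
                             stderr = TRUE))
  }
  out <- file.path(b$dir, "cli_out")
  r1 <- run_cli("pai", "--method", "ko", "--taxonomy", b$paths$lineage,
                "--genes", b$paths$genes, "--ko", b$paths$ko,
                "--target", b$target, "--out", out)
  expect_null(attr(r1, "status"))
  idx <- read_gene_index(file.path(out, "gene_index.tsv"))
  expect_identical(idx$PAI, unname(as.numeric(b$pai_truth)))
  r2 <- run_cli("phylo", "--expression", b$paths$expression, "--out", out)
  expect_null(attr(r2, "status"))
  expect_true(file.exists(file.path(out, "profile.tsv")))
  # a bad input yields a nonzero exit, not a traceback
  r3 <- run_cli("pai", "--method", "ko", "--out", out)
  expect_identical(attr(r3, "status"), 1L)
})
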