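test_that("codon sequences enforce frame, alphabet and stop constraints", {
  expect_s3_class(codon_sequence("g", "sp", "ATGAAATGA"), "codon_sequence")
  expect_error(codon_sequence("g", "sp", "ATGAA"), "divisible by 3")
  expect_error(codon_sequence("g", "sp", "ATGTAAAAA"), "internal stop")
  expect_error(codon_sequence("g", "sp", "ATGAAN"), "non-ACGT symbol 'N'")
  expect_error(codon_sequence("g", "sp", ""), "empty")
})

test_that("identical sequences give zero distances and a dS_zero flag", {
  a <- codon_sequence("g", "spA", "ATGAAACCTGGG")
  r <- ng86_pair(a, a)
  expect_identical(r$syn_diffs, 0)
  expect_identical(r$nonsyn_diffs, 0)
  expect_identical(r$dS, 0)
  expect_identical(r$dN, 0)
  expect_identical(r$excluded, "dS_zero")
  expect_true(is.na(r$ratio))
})

test_that("a single synonymous substitution is counted as Sd=1, Nd=0", {
  # AAA -> AAG is Lys -> Lys: purely synonymous
  a <- codon_sequence("g", "spA", "ATGAAA")
  b <- codon_sequence("g", "spB", "ATGAAG")
  r <- ng86_pair(a, b)
  expect_identical(unname(c(r$syn_diffs, r$nonsyn_diffs)),
                   unname(oracle_ng86_pair_diffs("ATGAAA", "ATGAAG")))
  expect_identical(r$syn_diffs, 1)
  expect_identical(r$nonsyn_diffs, 0)
  expect_identical(r$dN, 0)
  # with only 1/3 synonymous sites in this pair, pS = 3 exceeds the
  # Jukes-Cantor domain, so the pair is excluded rather than given a ratio
  expect_identical(r$excluded, "correction_out_of_range")
  # diluted over 20 codons (Leu codons contribute synonymous sites) the
  # same substitution gives dS > 0 and ratio 0
  pad <- strrep("CTG", 19L)
  r2 <- ng86_pair(codon_sequence("g", "spA", paste0(pad, "AAA")),
                  codon_sequence("g", "spB", paste0(pad, "AAG")))
  expect_gt(r2$dS, 0)
  expect_identical(r2$dN, 0)
  expect_identical(r2$ratio, 0)
})

test_that("input contract violations raise distinct errors", {
  a <- codon_sequence("g", "spA", "ATGAAA")
  b <- codon_sequence("g", "spB", "ATGAAAATG")
  expect_error(ng86_pair(a, b), "differ in length")
})

test_that("a shared terminal stop codon is ignored in counting", {
  a <- codon_sequence("g", "spA", "ATGAAATAA")
  b <- codon_sequence("g", "spB", "ATGAAGTAA")
  r <- ng86_pair(a, b)
  expect_equal(r$syn_sites + r$nonsyn_sites, 6)
  expect_identical(r$syn_diffs, 1)
})

test_that("site counts conserve sequence length and the pair is symmetric", {
  set.seed(41)
  for (i in 1:60) {
    n <- sample(2:12, 1L)
    a <- codon_sequence("g", "spA", random_cds(n))
    b <- codon_sequence("g", "spB", random_cds(n))
    r <- ng86_pair(a, b)
    expect_equal(r$syn_sites + r$nonsyn_sites, 3 * n, tolerance = 1e-9)
    s <- ng86_pair(b, a)
    expect_equal(r$syn_diffs, s$syn_diffs)
    expect_equal(r$nonsyn_diffs, s$nonsyn_diffs)
    expect_equal(r$syn_sites, s$syn_sites)
  }
})

test_that("difference counts match the pathway-enumeration oracle", {
  set.seed(42)
  for (i in 1:60) {
    n <- sample(1:5, 1L)
    nta <- random_cds(n); ntb <- random_cds(n)
    r <- ng86_pair(codon_sequence("g", "spA", nta),
                   codon_sequence("g", "spB", ntb))
    o <- oracle_ng86_pair_diffs(nta, ntb)
    expect_equal(r$syn_diffs, unname(o["syn"]), info = paste(nta, ntb))
    expect_equal(r$nonsyn_diffs, unname(o["nonsyn"]), info = paste(nta, ntb))
  }
})

test_that("pure selection regimes give the expected zero distance", {
  for (seed in 1:20) {
    syn <- ng86_pair(gen_codon_pair(seed, 100L, 5L, 0L)$a,
                     gen_codon_pair(seed, 100L, 5L, 0L)$b)
    expect_identical(syn$dN, 0)
    expect_gt(syn$dS, 0)
    expect_identical(syn$ratio, 0)
    non <- ng86_pair(gen_codon_pair(seed, 100L, 0L, 5L)$a,
                     gen_codon_pair(seed, 100L, 0L, 5L)$b)
    expect_identical(non$dS, 0)
    expect_identical(non$excluded, "dS_zero")
  }
})

test_that("weak purifying selection pushes the ratio below one", {
  # nonsynonymous rate below the synonymous rate over a long sequence
  pair <- gen_codon_pair(7L, 10000L, 300L, 60L)
  r <- ng86_pair(pair$a, pair$b)
  expect_lt(r$ratio, 1)
})

test_that("comparison species are selected by depth or explicit codes", {
  tab <- hominid_taxonomy()
  expect_identical(select_comparison_species("hsa", tab, level = 1L),
                   character(0L))  # no other species in genus Homo
  expect_identical(select_comparison_species("hsa", tab, level = 2L),
                   c("ggo", "ptr"))  # family level: the other hominids
  expect_identical(select_comparison_species("hsa", tab, level = 3L),
                   c("ggo", "mmu", "ptr"))
  expect_identical(select_comparison_species("hsa", tab,
                                             organisms = "ggo"), "ggo")
  expect_error(select_comparison_species("hsa", tab, organisms = "xxx"),
               "unknown species")
  expect_error(select_comparison_species("hsa", tab, level = 4L), "level")
  expect_error(select_comparison_species("hsa", tab), "exactly one")
  expect_error(select_comparison_species("hsa", tab, level = 1L,
                                         organisms = "ggo"), "exactly one")
})

test_that("DI averages defined ratios and counts exclusions", {
  target <- gen_codon_pair(51L, 80L, 4L, 3L)$a
  hom1 <- gen_codon_pair(51L, 80L, 4L, 3L)$b
  hom2 <- evoindex:::derive_copy(52L, target, "spC", 2L, 5L)
  r1 <- ng86_pair(target, hom1)$ratio
  r2 <- ng86_pair(target, hom2)$ratio
  # single homolog: DI is that pair's ratio
  single <- divergence_index(target, list(hom1))
  expect_identical(single$di, r1)
  expect_identical(single$n_pairs_used, 1L)
  # two homologs: arithmetic mean of the two ratios
  both <- divergence_index(target, list(hom1, hom2))
  expect_equal(both$di, mean(c(r1, r2)))
  # an identical homolog is excluded (dS_zero) but counted
  same <- codon_sequence("g1", "spD", target$nt)
  mix <- divergence_index(target, list(same, hom1))
  expect_identical(mix$di, r1)
  expect_identical(mix$n_pairs_excluded, 1L)
  # no homologs: undefined
  none <- divergence_index(target, list())
  expect_true(is.na(none$di))
  expect_identical(none$n_pairs_used, 0L)
})

test_that("DI of identical ratios is that ratio (mean idempotence)", {
  target <- gen_codon_pair(61L, 80L, 3L, 3L)$a
  hom <- gen_codon_pair(61L, 80L, 3L, 3L)$b
  r <- ng86_pair(target, hom)$ratio
  copies <- lapply(c("s1", "s2", "s3"), function(sp)
    codon_sequence("g1", sp, hom$nt))
  expect_equal(divergence_index(target, copies)$di, r)
})

test_that("CDS FASTA reads into codon sequences with species|gene headers", {
  f <- withr::local_tempfile(lines = c(">hsa|g1", "ATGAAACCC",
                                       ">mmu|g1", "ATGAAGCCC"))
  cds <- read_cds_fasta(f)
  expect_length(cds, 2L)
  expect_identical(cds[[1L]]$species_code, "hsa")
  expect_identical(cds[[2L]]$gene_id, "g1")
  bad <- withr::local_tempfile(lines = c(">justonefield", "ATG"))
  expect_error(read_cds_fasta(bad), "species_code\\|gene_id")
})
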