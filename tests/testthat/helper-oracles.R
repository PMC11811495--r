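# Independent brute-force oracles, kept deliberately naive: they enumerate
# the full solution space rather than sharing any dynamic-programming or
# table-driven machinery with the implementation under test.

# Brute-force Smith-Waterman: maximize over every pair of equal-size
# increasing position subsets (i1<...<ik of a, j1<...<jk of b), i.e. over
# every local alignment written as substitution columns separated by gap
# runs. A gap run of length g costs gap_open + g * gap_extend per sequence.
# Score floor 0 (the empty alignment).
oracle_sw_score <- function(a, b, scheme) {
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  n <- length(av); m <- length(bv)
  if (n == 0L || m == 0L) return(0)
  sub <- scheme$substitution
  gap_cost <- function(g) if (g > 0L) scheme$gap_open + g * scheme$gap_extend
                          else 0
  best <- 0
  for (k in seq_len(min(n, m))) {
    ia <- t(utils::combn(n, k))
    jb <- t(utils::combn(m, k))
    for (r in seq_len(nrow(ia))) for (s in seq_len(nrow(jb))) {
      I <- ia[r, ]; J <- jb[s, ]
      sc <- sum(sub[cbind(av[I], bv[J])])
      if (k > 1L)
        for (t in seq_len(k - 1L))
          sc <- sc + gap_cost(I[t + 1L] - I[t] - 1L) +
                     gap_cost(J[t + 1L] - J[t] - 1L)
      if (sc > best) best <- sc
    }
  }
  best
}

# Independent NG86 difference counter: enumerates every ordering of the
# differing codon positions by depth-first search, translating with
# Biostrings' genetic code at each step; orderings whose intermediate
# codons are stops are discarded (all orderings are used if none survive).
oracle_ng86_diffs <- function(codon_a, codon_b) {
  code <- Biostrings::GENETIC_CODE
  x <- strsplit(codon_a, "")[[1L]]
  y <- strsplit(codon_b, "")[[1L]]
  pos <- which(x != y)
  if (!length(pos)) return(c(syn = 0, nonsyn = 0))
  acc <- list()
  walk <- function(cur, remaining, syn, nonsyn, blocked) {
    if (!length(remaining)) {
      acc[[length(acc) + 1L]] <<- c(syn, nonsyn, blocked)
      return(invisible())
    }
    for (p in remaining) {
      nxt <- cur; nxt[p] <- y[p]
      is_stop <- code[[paste(nxt, collapse = "")]] == "*" &&
        length(remaining) > 1L
      step_syn <- code[[paste(cur, collapse = "")]] ==
        code[[paste(nxt, collapse = "")]]
      walk(nxt, setdiff(remaining, p),
           syn + step_syn, nonsyn + !step_syn, blocked || is_stop)
    }
  }
  walk(x, pos, 0, 0, FALSE)
  m <- do.call(rbind, acc)
  open <- m[m[, 3L] == 0, , drop = FALSE]
  use <- if (nrow(open)) open else m
  c(syn = mean(use[, 1L]), nonsyn = mean(use[, 2L]))
}

oracle_ng86_pair_diffs <- function(nt_a, nt_b) {
  ca <- substring(nt_a, seq(1L, nchar(nt_a), 3L), seq(3L, nchar(nt_a), 3L))
  cb <- substring(nt_b, seq(1L, nchar(nt_b), 3L), seq(3L, nchar(nt_b), 3L))
  d <- vapply(seq_along(ca), function(i) oracle_ng86_diffs(ca[i], cb[i]),
              numeric(2L))
  c(syn = sum(d["syn", ]), nonsyn = sum(d["nonsyn", ]))
}

# Random stop-free codon string of n codons (helper for fuzz cases).
random_cds <- function(n_codons) {
  code <- Biostrings::GENETIC_CODE
  non_stop <- names(code)[code != "*"]
  paste(sample(non_stop, n_codons, replace = TRUE), collapse = "")
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Toy primate/rodent lineage table reused across tests.
toy_taxonomy <- function() {
  taxonomy_table(list(
    hsa = c("Root", "Eukaryota", "Metazoa", "Mammalia",
            "Primates", "Homo", "Homo sapiens"),
    mmu = c("Root", "Eukaryota", "Metazoa", "Mammalia",
            "Rodentia", "Mus", "Mus musculus")))
}

hominid_taxonomy <- function() {
  taxonomy_table(list(
    hsa = c("Root", "Hominidae", "Homo", "H.sapiens"),
    ptr = c("Root", "Hominidae", "Pan", "P.troglodytes"),
    ggo = c("Root", "Hominidae", "Gorilla", "G.gorilla"),
    mmu = c("Root", "Muridae", "Mus", "M.musculus")))
}
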