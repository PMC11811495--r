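# Seeded generators for every input the pipeline consumes, with planted
# ground truth so recovery tests are exact. All randomness goes through
# with_seed(); every generator is a pure function of (seed, parameters).

#' Generate a random taxonomy table
#'
#' Builds a random rooted path system (a lineage trie) with a shared root.
#' Species terminate at random depths between 2 and \code{max_depth}; at
#' least two species attain depth \code{max_depth} exactly. Internal taxa
#' are named \code{cladeNNN}, terminal taxa \code{<code>_sp}.
#'
#' @param seed Integer seed.
#' @param n_species Number of species (>= 2).
#' @param max_depth Maximum lineage length (>= 2).
#' @return A \code{\link{taxonomy_table}}.
#' @export
gen_taxonomy <- function(seed, n_species, max_depth) {
  if (n_species < 2L) stop("n_species must be >= 2", call. = FALSE)
  if (max_depth < 2L) stop("max_depth must be >= 2", call. = FALSE)
  with_seed(seed, {
    codes <- sprintf("sp%03d", seq_len(n_species))
    term_depth <- c(max_depth, max_depth,
                    if (n_species > 2L)
                      sample(2:max_depth, n_species - 2L, replace = TRUE))
    names(term_depth) <- codes
    env <- new.env()
    env$lineages <- list()
    env$clade <- 0L
    new_clade <- function() {
      env$clade <- env$clade + 1L
      sprintf("clade%03d", env$clade)
    }
    descend <- function(members, prefix) {
      depth_next <- length(prefix) + 1L
      stop_here <- members[term_depth[members] == depth_next]
      for (code in stop_here)
        env$lineages[[code]] <- c(prefix, paste0(code, "_sp"))
      go_on <- setdiff(members, stop_here)
      if (!length(go_on)) return(invisible())
      k <- sample.int(min(3L, length(go_on)), 1L)
      grp <- sample.int(k, length(go_on), replace = TRUE)
      grp[sample.int(length(go_on), min(k, length(go_on)))] <- seq_len(
        min(k, length(go_on)))  # every group non-empty
      for (g in unique(grp))
        descend(go_on[grp == g], c(prefix, new_clade()))
    }
    descend(codes, "root")
    taxonomy_table(env$lineages[codes])
  })
}

#' Generate ortholog data with planted gene ages
#'
#' For each gene a true phylostratum \eqn{d} is drawn from the depths
#' actually attainable against the target species; orthologs are placed in
#' exactly the species whose lineage shares at least \eqn{d} taxa with the
#' target (so the minimum LCA depth over the set is \eqn{d} by
#' construction). Both a KO membership map and a best-similarity table are
#' emitted: true orthologs receive identity/score above the default
#' thresholds, decoy records (non-ortholog species) fall below both.
#'
#' @param seed Integer seed.
#' @param taxonomy A \code{\link{taxonomy_table}}.
#' @param n_genes Number of genes.
#' @param target Target species code; defaults to the (lexicographically
#'   first) species with the longest lineage.
#' @param decoy_rate Probability that a non-ortholog species contributes a
#'   below-threshold decoy similarity record.
#' @return List with components \code{komap} (a \code{ko_group_map}),
#'   \code{similarity} (similarity-record data frame), \code{truth} (named
#'   integer vector of planted PAIs), and \code{target}.
#' @export
gen_ortholog_data <- function(seed, taxonomy, n_genes, target = NULL,
                              decoy_rate = 0.3) {
  codes <- species_codes(taxonomy)
  if (is.null(target)) {
    lens <- vapply(codes, function(s) length(lineage(taxonomy, s)),
                   integer(1L))
    target <- sort(codes[lens == max(lens)])[1L]
  }
  target_lin <- lineage(taxonomy, target)
  depth_of <- vapply(codes, function(s)
    lca_depth(target_lin, lineage(taxonomy, s)), integer(1L))
  achievable <- sort(unique(depth_of))
  with_seed(seed, {
    genes <- sprintf("g%04d", seq_len(n_genes))
    truth <- stats::setNames(
      achievable[sample.int(length(achievable), n_genes, replace = TRUE)],
      genes)
    ko_rows <- list(); sim_rows <- list(); k <- 0L
    for (gi in seq_len(n_genes)) {
      gene <- genes[gi]
      d <- truth[[gene]]
      ortho_sp <- codes[depth_of >= d]
      decoy_sp <- codes[depth_of < d]
      k <- k + 1L
      ko_rows[[k]] <- data.frame(group = sprintf("K%04d", gi),
                                 species = ortho_sp, gene = gene,
                                 stringsAsFactors = FALSE)
      others <- setdiff(ortho_sp, target)
      if (length(others))
        sim_rows[[length(sim_rows) + 1L]] <- data.frame(
          query_gene = gene, subject_gene = gene, subject_species = others,
          identity = round(stats::runif(length(others), 0.55, 0.95), 3L),
          sw_score = round(stats::runif(length(others), 150, 900), 1L),
          stringsAsFactors = FALSE)
      decoys <- decoy_sp[stats::runif(length(decoy_sp)) < decoy_rate]
      if (length(decoys))
        sim_rows[[length(sim_rows) + 1L]] <- data.frame(
          query_gene = gene, subject_gene = paste0(gene, "x"),
          subject_species = decoys,
          identity = round(stats::runif(length(decoys), 0.05, 0.45), 3L),
          sw_score = round(stats::runif(length(decoys), 0, 90), 1L),
          stringsAsFactors = FALSE)
    }
    similarity <- do.call(rbind, sim_rows)
    if (is.null(similarity))
      similarity <- data.frame(query_gene = character(0),
                               subject_gene = character(0),
                               subject_species = character(0),
                               identity = numeric(0), sw_score = numeric(0))
    list(komap = ko_group_map(do.call(rbind, ko_rows)),
         similarity = similarity, truth = truth, target = target)
  })
}

#' Generate a codon-aligned sequence pair with planted substitution counts
#'
#' Draws a random stop-free ancestor of \code{n_codons} codons, then derives
#' a copy carrying exactly \code{syn_subs} synonymous and
#' \code{nonsyn_subs} nonsynonymous single-nucleotide substitutions, never
#' creating a stop codon and with at most one substitution per codon (so
#' NG86 pathway averaging recovers the planted counts exactly).
#'
#' @param seed Integer seed.
#' @param n_codons Number of codons.
#' @param syn_subs,nonsyn_subs Planted substitution counts;
#'   \code{syn_subs + nonsyn_subs <= n_codons}.
#' @param gene_id,species_a,species_b Identifiers for the two sequences.
#' @return List with \code{a}, \code{b} (\code{\link{codon_sequence}}s) and
#'   \code{truth} (list with \code{syn} and \code{nonsyn}).
#' @export
gen_codon_pair <- function(seed, n_codons, syn_subs, nonsyn_subs,
                           gene_id = "g1", species_a = "spA",
                           species_b = "spB") {
  if (syn_subs + nonsyn_subs > n_codons)
    stop("requested ", syn_subs + nonsyn_subs, " substitutions exceed ",
         n_codons, " codons (one substitution per codon)", call. = FALSE)
  tab <- codon_tables()
  non_stop <- setdiff(names(tab$code), tab$stops)
  syn_capable <- non_stop[lengths(tab$syn_nbr[non_stop]) > 0L]
  nonsyn_capable <- non_stop[lengths(tab$nonsyn_nbr[non_stop]) > 0L]
  with_seed(seed, {
    anc <- sample(non_stop, n_codons, replace = TRUE)
    slots <- sample.int(n_codons, syn_subs + nonsyn_subs)
    syn_slots <- slots[seq_len(syn_subs)]
    nonsyn_slots <- setdiff(slots, syn_slots)
    # make the chosen codons capable of the required substitution class
    anc[syn_slots] <- sample(syn_capable, syn_subs, replace = TRUE)
    anc[nonsyn_slots] <- sample(nonsyn_capable, nonsyn_subs, replace = TRUE)
    der <- anc
    for (i in syn_slots) {
      nbr <- tab$syn_nbr[[anc[i]]]
      der[i] <- nbr[sample.int(length(nbr), 1L)]
    }
    for (i in nonsyn_slots) {
      nbr <- tab$nonsyn_nbr[[anc[i]]]
      der[i] <- nbr[sample.int(length(nbr), 1L)]
    }
    list(a = codon_sequence(gene_id, species_a, paste(anc, collapse = "")),
         b = codon_sequence(gene_id, species_b, paste(der, collapse = "")),
         truth = list(syn = syn_subs, nonsyn = nonsyn_subs))
  })
}

#' Generate an expression matrix
#'
#' @param seed Integer seed.
#' @param genes Character vector of gene ids.
#' @param conditions Character vector of condition labels.
#' @param profile \code{"uniform"} (all values equal — the TAI = mean-PAI
#'   test hook), \code{"random"} (independent uniform values), or
#'   \code{"oldest_biased"} (expression proportional to
#'   \code{max(pai) - pai + 1}, concentrating weight on low-PAI, i.e.
#'   evolutionarily old, genes; requires \code{pai}).
#' @param pai Named PAI vector covering \code{genes}; only used (and
#'   required) for \code{profile = "oldest_biased"}.
#' @return An \code{\link{expression_matrix}}.
#' @export
gen_expression <- function(seed, genes, conditions,
                           profile = c("uniform", "random", "oldest_biased"),
                           pai = NULL) {
  profile <- match.arg(profile)
  if (!length(genes) || !length(conditions))
    stop("genes and conditions must be non-empty", call. = FALSE)
  with_seed(seed, {
    n <- length(genes); m <- length(conditions)
    vals <- switch(profile,
      uniform = matrix(10, n, m),
      random = matrix(stats::runif(n * m, 0, 100), n, m),
      oldest_biased = {
        if (is.null(pai) || !all(genes %in% names(pai)))
          stop("profile 'oldest_biased' needs a PAI for every gene",
               call. = FALSE)
        w <- max(pai[genes]) - pai[genes] + 1
        # per-condition positive scaling; TAI/TDI are scale-invariant
        outer(as.numeric(w), stats::runif(m, 0.5, 2))
      })
    dimnames(vals) <- list(genes, conditions)
    expression_matrix(vals)
  })
}

#' Generate a random gene network as STRING-dialect TSV
#'
#' Samples \code{n_edges} distinct undirected pairs of genes and assigns
#' each a confidence weight uniform in [0, 1], written in the STRING export
#' dialect (\code{node1}, \code{node2}, \code{combined_score}).
#'
#' @param seed Integer seed.
#' @param genes Character vector of gene ids (>= 2).
#' @param n_edges Number of edges; at most \code{choose(length(genes), 2)}.
#' @return Character vector of TSV lines (header first).
#' @export
gen_network <- function(seed, genes, n_edges) {
  n <- length(genes)
  if (n < 2L) stop("need at least 2 genes", call. = FALSE)
  if (n_edges > choose(n, 2L))
    stop("n_edges exceeds the ", choose(n, 2L),
         " distinct undirected pairs available", call. = FALSE)
  with_seed(seed, {
    pick <- sample.int(choose(n, 2L), n_edges)
    # unrank: pair index -> (i, j), i < j, row-major over the strict
    # upper triangle
    pairs <- t(vapply(pick, function(k) {
      i <- 1L
      while (k > n - i) { k <- k - (n - i); i <- i + 1L }
      c(i, i + k)
    }, integer(2L)))
    w <- round(stats::runif(n_edges), 3L)
    c("node1\tnode2\tcombined_score",
      sprintf("%s\t%s\t%s", genes[pairs[, 1L]], genes[pairs[, 2L]],
              format(w, scientific = FALSE, trim = TRUE)))
  })
}

#' Generate and write a complete fixture bundle
#'
#' Produces every input the pipeline consumes — lineage TSV, KO membership
#' TSV, best-similarity TSV, codon-aligned CDS FASTA, expression TSV and
#' network TSV — plus a \code{truth.json} recording the planted PAI per gene
#' and the planted substitution-class counts per homolog pair. The CDS set
#' contains, per gene, the target-species sequence and one homolog per
#' comparison species, each derived from the target with planted
#' synonymous/nonsynonymous substitution counts.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param n_species,max_depth Passed to \code{\link{gen_taxonomy}}.
#' @param n_genes Number of genes.
#' @param n_conditions Number of expression conditions.
#' @param n_codons Codons per CDS.
#' @param syn_subs,nonsyn_subs Planted substitution counts per homolog pair.
#' @param n_cds_species Number of comparison species receiving a homolog
#'   CDS per gene.
#' @param expression_profile Passed to \code{\link{gen_expression}}.
#' @return Invisibly, a named list of the file paths written.
#' @export
write_fixture_bundle <- function(dir, seed, n_species = 50L, max_depth = 8L,
                                 n_genes = 100L, n_conditions = 4L,
                                 n_codons = 60L, syn_subs = 3L,
                                 nonsyn_subs = 2L, n_cds_species = 3L,
                                 expression_profile = "random") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  taxonomy <- gen_taxonomy(seed, n_species, max_depth)
  ortho <- gen_ortholog_data(seed + 1L, taxonomy, n_genes)
  genes <- names(ortho$truth)
  target <- ortho$target

  paths <- list(
    lineage = file.path(dir, "lineage.tsv"),
    ko = file.path(dir, "ko.tsv"),
    similarity = file.path(dir, "similarity.tsv"),
    cds = file.path(dir, "cds.fasta"),
    expression = file.path(dir, "expression.tsv"),
    network = file.path(dir, "network.tsv"),
    genes = file.path(dir, "genes.txt"),
    truth = file.path(dir, "truth.json"))

  write_lineage_table(taxonomy, paths$lineage)

  ko_lines <- unlist(lapply(names(ortho$komap$group_members), function(grp) {
    m <- ortho$komap$group_members[[grp]]
    sprintf("%s\t%s\t%s", grp, m$species, m$gene)
  }))
  writeLines(ko_lines, paths$ko)

  s <- ortho$similarity
  writeLines(c("query_gene\tsubject_gene\tsubject_species\tidentity\tsw_score",
               sprintf("%s\t%s\t%s\t%s\t%s", s$query_gene, s$subject_gene,
                       s$subject_species,
                       format(s$identity, scientific = FALSE, trim = TRUE),
                       format(s$sw_score, scientific = FALSE, trim = TRUE))),
             paths$similarity)

  # CDS: per gene, target sequence + homologs in the n_cds_species species
  # closest to the target (largest LCA depth), with planted substitutions
  codes <- setdiff(species_codes(taxonomy), target)
  target_lin <- lineage(taxonomy, target)
  depth_of <- vapply(codes, function(x)
    lca_depth(target_lin, lineage(taxonomy, x)), integer(1L))
  cds_species <- codes[order(-depth_of, codes)][seq_len(
    min(n_cds_species, length(codes)))]
  fasta <- character(0L)
  pair_truth <- list()
  for (gi in seq_along(genes)) {
    gene <- genes[gi]
    base <- gen_codon_pair(seed + 1000L + gi, n_codons, syn_subs,
                           nonsyn_subs, gene_id = gene,
                           species_a = target, species_b = cds_species[1L])
    fasta <- c(fasta, paste0(">", target, "|", gene), base$a$nt)
    for (si in seq_along(cds_species)) {
      sp <- cds_species[si]
      # every homolog is derived from the same target ancestor with a
      # species-specific seed, so each pair carries the planted counts
      hom <- if (si == 1L) base$b else
        derive_copy(seed + 1000L + gi + 7919L * si, base$a, sp,
                    syn_subs, nonsyn_subs)
      fasta <- c(fasta, paste0(">", sp, "|", gene), hom$nt)
      pair_truth[[paste(gene, sp, sep = "|")]] <-
        list(syn = syn_subs, nonsyn = nonsyn_subs)
    }
  }
  writeLines(fasta, paths$cds)

  expr <- gen_expression(seed + 2L, genes, sprintf("cond%02d",
                                                   seq_len(n_conditions)),
                         profile = expression_profile, pai = ortho$truth)
  utils::write.table(
    data.frame(Gene = expr$genes, expr$values, check.names = FALSE),
    paths$expression, sep = "\t", quote = FALSE, row.names = FALSE)

  writeLines(gen_network(seed + 3L, genes,
                         n_edges = min(3L * length(genes),
                                       choose(length(genes), 2L))),
             paths$network)
  writeLines(genes, paths$genes)

  jsonlite::write_json(
    list(seed = seed, target = target,
         pai = as.list(ortho$truth),
         pairs = pair_truth,
         comparison_species = cds_species),
    paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

# Derived copy of an existing codon sequence with planted substitution
# counts (one substituted codon is never reused).
derive_copy <- function(seed, ancestor, species, syn_subs, nonsyn_subs) {
  tab <- codon_tables()
  with_seed(seed, {
    cod <- ancestor$codons
    syn_ok <- which(lengths(tab$syn_nbr[cod]) > 0L)
    nonsyn_ok <- which(lengths(tab$nonsyn_nbr[cod]) > 0L)
    syn_slots <- syn_ok[sample.int(length(syn_ok), syn_subs)]
    pool <- setdiff(nonsyn_ok, syn_slots)
    nonsyn_slots <- pool[sample.int(length(pool), nonsyn_subs)]
    for (i in syn_slots) {
      nbr <- tab$syn_nbr[[cod[i]]]
      cod[i] <- nbr[sample.int(length(nbr), 1L)]
    }
    for (i in nonsyn_slots) {
      nbr <- tab$nonsyn_nbr[[cod[i]]]
      cod[i] <- nbr[sample.int(length(nbr), 1L)]
    }
    codon_sequence(ancestor$gene_id, species, paste(cod, collapse = ""))
  })
}
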