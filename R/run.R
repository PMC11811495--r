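# Pipeline drivers behind the command-line interface: each run_* function
# takes a run_config(), reads the configured inputs, writes the tabular
# outputs and a run-metadata log, and returns its result invisibly.

#' Assemble a run configuration
#'
#' Collects every path and option a pipeline run needs. Unused fields may be
#' left \code{NULL}; each \code{run_*} function validates the fields it
#' requires. The configuration (minus \code{NULL}s) is echoed into
#' \code{run_metadata.json} next to the outputs for provenance.
#'
#' @param out Output directory (created if needed).
#' @param method PAI method: \code{"KO"} (ortholog groups) or \code{"BST"}
#'   (best-similarity table).
#' @param taxonomy Path to the lineage TSV.
#' @param genes Path to the gene list (one id per line) or a network TSV
#'   (genes taken from edge endpoints).
#' @param ko Path to the KO membership TSV (method \code{"KO"}).
#' @param similarity Path to the best-similarity TSV (method \code{"BST"}).
#' @param cds Path to the codon-aligned CDS FASTA
#'   (\code{"species|gene"} headers) for DI.
#' @param expression Path to the expression TSV for TAI/TDI.
#' @param network Path to the network TSV for annotation.
#' @param labels Optional two-column TSV mapping gene id to a secondary
#'   label for the \code{Label} output column.
#' @param target Target species code.
#' @param identity_min,sw_min Homolog filter thresholds (method
#'   \code{"BST"}).
#' @param paralog_filter Restrict KO groups to the query gene's own groups
#'   with one representative per species (see
#'   \code{\link{species_with_orthologs_ko}}).
#' @param dnds_level Taxonomic depth for the dN/dS comparison set
#'   (mutually exclusive with \code{organisms}).
#' @param organisms Explicit comparison species codes.
#' @param strict Error on recoverable per-gene problems instead of emitting
#'   \code{NA} cells.
#' @param seed Integer seed recorded in the metadata and used by
#'   \code{\link{run_simulate}}.
#' @return An object of class \code{run_config}.
#' @export
run_config <- function(out = ".", method = c("KO", "BST"), taxonomy = NULL,
                       genes = NULL, ko = NULL, similarity = NULL,
                       cds = NULL, expression = NULL, network = NULL,
                       labels = NULL, target = NULL, identity_min = 0.5,
                       sw_min = 100, paralog_filter = FALSE,
                       dnds_level = NULL, organisms = NULL, strict = FALSE,
                       seed = 1L) {
  method <- match.arg(method)
  structure(list(out = out, method = method, taxonomy = taxonomy,
                 genes = genes, ko = ko, similarity = similarity, cds = cds,
                 expression = expression, network = network, labels = labels,
                 target = target,
                 thresholds = homolog_thresholds(identity_min, sw_min),
                 paralog_filter = isTRUE(paralog_filter),
                 dnds_level = dnds_level, organisms = organisms,
                 strict = isTRUE(strict), seed = as.integer(seed)),
            class = "run_config")
}

require_fields <- function(config, fields) {
  for (f in fields)
    if (is.null(config[[f]]))
      stop("run configuration is missing required field '", f, "'",
           call. = FALSE)
  for (f in intersect(fields, c("taxonomy", "genes", "ko", "similarity",
                                "cds", "expression", "network", "labels")))
    if (!file.exists(config[[f]]))
      stop("input file not found: ", config[[f]], call. = FALSE)
}

write_run_metadata <- function(config, extra = list()) {
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  meta <- c(unclass(config), extra)
  meta$thresholds <- unclass(meta$thresholds)
  meta <- meta[!vapply(meta, is.null, logical(1L))]
  jsonlite::write_json(meta, file.path(config$out, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA)
}

# Gene source: a one-id-per-line list, or a network TSV (detected by a tab
# in the first non-comment line), whose edge endpoints become the genes.
read_gene_list <- function(file) {
  tsv <- read_tsv_lines(file)
  if (!length(tsv$lines)) return(character(0L))
  if (grepl("\t", tsv$lines[1L], fixed = TRUE))
    parse_network_tsv(file)$nodes$gene
  else
    trimws(tsv$lines)
}

read_label_map <- function(file) {
  if (is.null(file)) return(stats::setNames(character(0L), character(0L)))
  tsv <- read_tsv_lines(file)
  fields <- split_tsv(tsv$lines)
  stats::setNames(vapply(fields, `[`, character(1L), 2L),
                  vapply(fields, `[`, character(1L), 1L))
}

gene_index_path <- function(config) file.path(config$out, "gene_index.tsv")

#' Write a gene index table as TSV
#'
#' Four tab-separated columns with header \code{Gene}, \code{Label},
#' \code{PAI}, \code{DI}; undefined cells are the literal \code{NA}.
#'
#' @param records Data frame with columns \code{Gene}, \code{Label},
#'   \code{PAI}, \code{DI}.
#' @param file Output path.
#' @return Invisibly, \code{file}.
#' @export
write_gene_index <- function(records, file) {
  lines <- c("Gene\tLabel\tPAI\tDI",
             vapply(seq_len(nrow(records)), function(i)
               paste(records$Gene[i], records$Label[i],
                     na_cell(records$PAI[i]), na_cell(records$DI[i]),
                     sep = "\t"),
               character(1L)))
  writeLines(lines, file)
  invisible(file)
}

#' Read a gene index table written by \code{\link{run_pai}}/\code{run_di}
#' @param file Path to a gene index TSV.
#' @return Data frame with columns \code{Gene}, \code{Label}, \code{PAI},
#'   \code{DI}.
#' @export
read_gene_index <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE,
                          na.strings = "NA", colClasses = c(
                            Gene = "character", Label = "character",
                            PAI = "numeric", DI = "numeric"))
  df$Label[is.na(df$Label)] <- ""
  df
}

#' Compute PAIs for a gene list and write the gene index table
#'
#' For every input gene (order preserved) the set of ortholog-bearing
#' species is derived — from KO-group membership (method \code{"KO"}) or
#' from the thresholded best-similarity table (method \code{"BST"}) — and
#' the PAI is computed against the taxonomy. Per-gene failures (no KO
#' assignment, no records) degrade to an \code{NA} cell with a warning
#' unless \code{strict}.
#'
#' @param config A \code{\link{run_config}} with \code{taxonomy},
#'   \code{genes}, \code{target}, \code{out} and the method-specific input
#'   (\code{ko} or \code{similarity}).
#' @return Invisibly, the gene index data frame (also written to
#'   \code{<out>/gene_index.tsv}).
#' @export
run_pai <- function(config) {
  stopifnot(inherits(config, "run_config"))
  require_fields(config, c("taxonomy", "genes", "target", "out",
                           if (config$method == "KO") "ko" else "similarity"))
  table <- parse_lineage_table(config$taxonomy)
  genes <- read_gene_list(config$genes)
  labels <- read_label_map(config$labels)
  komap <- if (config$method == "KO") parse_ko_table(config$ko)
  sim <- if (config$method == "BST")
    parse_similarity_table(config$similarity)

  one_gene <- function(gene) {
    if (config$method == "KO") {
      sp <- species_with_orthologs_ko(gene, komap, config$paralog_filter)
      pai(config$target, sp, table, strict = config$strict, gene = gene,
          method = "KO")$pai
    } else {
      rec <- sim[sim$query_gene == gene, , drop = FALSE]
      pai_bst(gene, rec, config$thresholds, table, config$target,
              strict = config$strict)$pai
    }
  }
  pais <- vapply(genes, function(g) {
    if (config$strict) return(as.numeric(one_gene(g)))
    tryCatch(as.numeric(one_gene(g)), error = function(e) {
      warning("gene '", g, "': ", conditionMessage(e), call. = FALSE)
      NA_real_
    })
  }, numeric(1L))

  records <- data.frame(Gene = genes,
                        Label = ifelse(genes %in% names(labels),
                                       labels[genes], ""),
                        PAI = pais, DI = NA_real_,
                        stringsAsFactors = FALSE)
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  write_gene_index(records, gene_index_path(config))
  write_run_metadata(config, list(command = "pai",
                                  n_genes = length(genes),
                                  n_na = sum(is.na(pais))))
  invisible(records)
}

#' Compute divergence indices and fill the DI column of the gene index
#'
#' For each gene, homologs are the CDS entries sharing the gene id in the
#' comparison species (selected by \code{dnds_level} or \code{organisms});
#' the DI is the mean defined dN/dS over those pairs
#' (\code{\link{divergence_index}}). Genes without a target sequence or
#' without any valid pair get \code{NA}. If \code{run_pai} already wrote a
#' gene index into \code{out}, its PAI column is preserved.
#'
#' @param config A \code{\link{run_config}} with \code{taxonomy},
#'   \code{cds}, \code{target}, \code{out}, and \code{dnds_level} or
#'   \code{organisms}; \code{genes} is optional (defaults to the target's
#'   genes in the CDS file, in file order).
#' @return Invisibly, the gene index data frame with DI filled.
#' @export
run_di <- function(config) {
  stopifnot(inherits(config, "run_config"))
  require_fields(config, c("taxonomy", "cds", "target", "out"))
  table <- parse_lineage_table(config$taxonomy)
  comparison <- select_comparison_species(config$target, table,
                                          level = config$dnds_level,
                                          organisms = config$organisms)
  cds <- read_cds_fasta(config$cds)
  cds_species <- vapply(cds, `[[`, character(1L), "species_code")
  cds_genes <- vapply(cds, `[[`, character(1L), "gene_id")
  genes <- if (!is.null(config$genes)) read_gene_list(config$genes)
           else unique(cds_genes[cds_species == config$target])
  labels <- read_label_map(config$labels)

  one_gene <- function(gene) {
    ti <- which(cds_genes == gene & cds_species == config$target)
    if (!length(ti))
      stop("no CDS for gene '", gene, "' in target species '",
           config$target, "'", call. = FALSE)
    hi <- which(cds_genes == gene & cds_species %in% comparison)
    if (!length(hi)) return(NA_real_)
    divergence_index(cds[[ti[1L]]], cds[hi])$di
  }
  dis <- vapply(genes, function(g) {
    if (config$strict) return(one_gene(g))
    tryCatch(one_gene(g), error = function(e) {
      warning("gene '", g, "': ", conditionMessage(e), call. = FALSE)
      NA_real_
    })
  }, numeric(1L))

  idx_file <- gene_index_path(config)
  if (file.exists(idx_file)) {
    records <- read_gene_index(idx_file)
    m <- match(records$Gene, genes)
    records$DI <- ifelse(is.na(m), records$DI, dis[m])
    extra <- setdiff(genes, records$Gene)
    if (length(extra))
      records <- rbind(records, data.frame(
        Gene = extra,
        Label = ifelse(extra %in% names(labels), labels[extra], ""),
        PAI = NA_real_, DI = dis[match(extra, genes)],
        stringsAsFactors = FALSE))
  } else {
    records <- data.frame(Gene = genes,
                          Label = ifelse(genes %in% names(labels),
                                         labels[genes], ""),
                          PAI = NA_real_, DI = dis, stringsAsFactors = FALSE)
  }
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  write_gene_index(records, idx_file)
  write_run_metadata(config, list(command = "di",
                                  estimator = "NG86+JC69",
                                  comparison_species = comparison,
                                  n_genes = length(genes),
                                  n_na = sum(is.na(dis))))
  invisible(records)
}

#' Compute the condition-wise TAI/TDI profile table
#'
#' Reads the expression matrix and the per-gene PAI/DI values (from the gene
#' index previously written into \code{out}, unless passed directly) and
#' writes \code{profile.tsv} with header \code{Data}, \code{TAI},
#' \code{TDI}, one row per condition in input column order.
#'
#' @param config A \code{\link{run_config}} with \code{expression} and
#'   \code{out}.
#' @param pai_by_gene,di_by_gene Optional named vectors overriding the gene
#'   index on disk.
#' @return Invisibly, the profile data frame.
#' @export
run_phylo <- function(config, pai_by_gene = NULL, di_by_gene = NULL) {
  stopifnot(inherits(config, "run_config"))
  require_fields(config, c("expression", "out"))
  expr <- parse_expression_matrix(config$expression)
  if (is.null(pai_by_gene) || is.null(di_by_gene)) {
    idx_file <- gene_index_path(config)
    if (!file.exists(idx_file))
      stop("no gene index in '", config$out,
           "': run the PAI/DI steps first or pass pai_by_gene/di_by_gene",
           call. = FALSE)
    idx <- read_gene_index(idx_file)
    if (is.null(pai_by_gene))
      pai_by_gene <- stats::setNames(idx$PAI, idx$Gene)
    if (is.null(di_by_gene))
      di_by_gene <- stats::setNames(idx$DI, idx$Gene)
  }
  prof <- phylo_profile(expr, pai_by_gene, di_by_gene,
                        strict = config$strict)
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  write_profile(prof, file.path(config$out, "profile.tsv"))
  write_run_metadata(config, list(command = "phylo",
                                  n_conditions = nrow(prof)))
  invisible(prof)
}

#' Annotate a network with PAI/DI and export it
#'
#' Imports the network TSV, annotates nodes with the indices from the gene
#' index in \code{out} (or the supplied vectors) and a PAI colour, and
#' writes \code{network_annotated.tsv}, \code{network.graphml} and
#' \code{network.json}.
#'
#' @param config A \code{\link{run_config}} with \code{network} and
#'   \code{out}.
#' @param pai_by_gene,di_by_gene Optional named vectors overriding the gene
#'   index on disk.
#' @return Invisibly, the annotated \code{\link{gene_network}}.
#' @export
run_network <- function(config, pai_by_gene = NULL, di_by_gene = NULL) {
  stopifnot(inherits(config, "run_config"))
  require_fields(config, c("network", "out"))
  net <- parse_network_tsv(config$network)
  if (is.null(pai_by_gene) && is.null(di_by_gene)) {
    idx_file <- gene_index_path(config)
    if (file.exists(idx_file)) {
      idx <- read_gene_index(idx_file)
      pai_by_gene <- stats::setNames(idx$PAI, idx$Gene)
      di_by_gene <- stats::setNames(idx$DI, idx$Gene)
    }
  }
  net <- annotate_network(net, pai_by_gene, di_by_gene)
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  export_network(net, file.path(config$out, "network_annotated.tsv"), "tsv")
  export_network(net, file.path(config$out, "network.graphml"), "graphml")
  export_network(net, file.path(config$out, "network.json"),
                 "cytoscape_json")
  write_run_metadata(config, list(command = "network",
                                  n_nodes = nrow(net$nodes),
                                  n_edges = nrow(net$edges)))
  invisible(net)
}

#' Write a synthetic fixture bundle (CLI backend)
#'
#' Thin wrapper over \code{\link{write_fixture_bundle}} driven by a
#' \code{\link{run_config}}: writes a complete input set with planted ground
#' truth into \code{config$out} using \code{config$seed}.
#'
#' @param config A \code{\link{run_config}} (only \code{out} and \code{seed}
#'   are used).
#' @param ... Passed through to \code{\link{write_fixture_bundle}}.
#' @return Invisibly, the named list of file paths written.
#' @export
run_simulate <- function(config, ...) {
  stopifnot(inherits(config, "run_config"))
  paths <- write_fixture_bundle(config$out, config$seed, ...)
  write_run_metadata(config, list(command = "simulate"))
  invisible(paths)
}
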