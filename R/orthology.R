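#' Construct a KO group map
#'
#' Ortholog-group membership: which genes belong to which ortholog (KO)
#' groups, and which (species, gene) pairs each group contains.
#'
#' @param members Data frame with columns \code{group}, \code{species},
#'   \code{gene} — one row per group member.
#' @return An object of class \code{ko_group_map} with components
#'   \code{gene_to_groups} (named list: gene id to character vector of group
#'   ids) and \code{group_members} (named list: group id to data frame with
#'   columns \code{species}, \code{gene}).
#' @export
ko_group_map <- function(members) {
  stopifnot(is.data.frame(members),
            all(c("group", "species", "gene") %in% names(members)))
  members <- unique(members[, c("group", "species", "gene")])
  group_members <- split(members[, c("species", "gene")], members$group)
  gene_groups <- unique(members[, c("gene", "group")])
  gene_to_groups <- split(gene_groups$group, gene_groups$gene)
  structure(list(gene_to_groups = gene_to_groups,
                 group_members = group_members),
            class = "ko_group_map")
}

#' Parse a KO membership table from TSV
#'
#' Three tab-separated columns: group id, species code, gene id. Comment
#' (\code{#}) and blank lines are ignored.
#'
#' @param file Path to the TSV file.
#' @return A \code{ko_group_map}.
#' @export
parse_ko_table <- function(file) {
  tsv <- read_tsv_lines(file)
  fields <- split_tsv(tsv$lines)
  fname <- if (is.character(file)) file else "connection"
  bad <- which(lengths(fields) != 3L)
  if (length(bad))
    stop_parse(fname, tsv$rows[bad[1L]], "expected 3 tab-separated columns")
  m <- do.call(rbind, fields)
  ko_group_map(data.frame(group = m[, 1L], species = m[, 2L], gene = m[, 3L],
                          stringsAsFactors = FALSE))
}

#' Species bearing orthologs of a gene, from KO groups
#'
#' Collects the species represented in the gene's ortholog groups. A species
#' contributes once no matter how many paralogs it has in a group, so the
#' species set (and hence the PAI) is the same with the paralog filter on or
#' off; the flag controls whether within-species paralogs are retained in
#' the returned member table for downstream comparison sets.
#'
#' @param gene Gene identifier.
#' @param komap A \code{ko_group_map}.
#' @param paralog_filter If \code{TRUE}, within each of the gene's groups the
#'   gene's own species is represented only by the gene itself (paralogs in
#'   the same species are dropped from the member attribute).
#' @return Character vector of species codes (sorted). The attribute
#'   \code{members} carries the (species, gene) pairs that produced it.
#' @export
species_with_orthologs_ko <- function(gene, komap, paralog_filter = FALSE) {
  groups <- komap$gene_to_groups[[gene]]
  if (is.null(groups))
    stop("no KO assignment for gene '", gene,
         "' (gene absent from every ortholog group)", call. = FALSE)
  members <- unique(do.call(rbind, komap$group_members[groups]))
  if (paralog_filter) {
    own_species <- unique(members$species[members$gene == gene])
    keep <- members$gene == gene | !(members$species %in% own_species)
    members <- members[keep, , drop = FALSE]
  }
  structure(sort(unique(members$species)), members = members)
}

#' Homolog filtering thresholds
#'
#' Thresholds applied to best-similarity records; both are inclusive
#' (a record passes at exactly the threshold value).
#'
#' @param identity_min Minimum sequence identity, a fraction in [0, 1].
#'   Default 0.5.
#' @param sw_min Minimum Smith-Waterman alignment score. Default 100.
#' @return An object of class \code{homolog_thresholds}.
#' @export
homolog_thresholds <- function(identity_min = 0.5, sw_min = 100) {
  if (!is.numeric(identity_min) || identity_min < 0 || identity_min > 1)
    stop("identity_min must be a fraction in [0, 1]", call. = FALSE)
  if (!is.numeric(sw_min) || sw_min < 0)
    stop("sw_min must be non-negative", call. = FALSE)
  structure(list(identity_min = identity_min, sw_min = sw_min),
            class = "homolog_thresholds")
}

#' Parse a best-similarity table from TSV
#'
#' Five tab-separated columns: query gene, subject gene, subject species,
#' identity (fraction in [0, 1]) and Smith-Waterman score. A header row
#' starting with \code{query_gene} is permitted and skipped.
#'
#' @param file Path to the TSV file.
#' @return Data frame with columns \code{query_gene}, \code{subject_gene},
#'   \code{subject_species}, \code{identity}, \code{sw_score}.
#' @export
parse_similarity_table <- function(file) {
  tsv <- read_tsv_lines(file)
  fname <- if (is.character(file)) file else "connection"
  lines <- tsv$lines
  rows <- tsv$rows
  if (length(lines) && startsWith(lines[1L], "query_gene")) {
    lines <- lines[-1L]; rows <- rows[-1L]
  }
  fields <- split_tsv(lines)
  bad <- which(lengths(fields) != 5L)
  if (length(bad))
    stop_parse(fname, rows[bad[1L]], "expected 5 tab-separated columns")
  m <- do.call(rbind, fields)
  if (is.null(m))
    return(data.frame(query_gene = character(0), subject_gene = character(0),
                      subject_species = character(0), identity = numeric(0),
                      sw_score = numeric(0)))
  rec <- data.frame(query_gene = m[, 1L], subject_gene = m[, 2L],
                    subject_species = m[, 3L],
                    identity = as.numeric(m[, 4L]),
                    sw_score = as.numeric(m[, 5L]),
                    stringsAsFactors = FALSE)
  bad <- which(is.na(rec$identity) | rec$identity < 0 | rec$identity > 1)
  if (length(bad))
    stop_parse(fname, rows[bad[1L]], "identity must be a fraction in [0, 1]")
  bad <- which(is.na(rec$sw_score) | rec$sw_score < 0)
  if (length(bad))
    stop_parse(fname, rows[bad[1L]], "sw_score must be non-negative")
  rec
}

#' Filter similarity records by identity and score thresholds
#'
#' Keeps exactly the records with \code{identity >= identity_min} AND
#' \code{sw_score >= sw_min} (both inclusive); input order is preserved.
#'
#' @param records Data frame of similarity records (see
#'   \code{\link{parse_similarity_table}}).
#' @param thresholds A \code{\link{homolog_thresholds}} object.
#' @return The passing subset of \code{records}.
#' @export
filter_homologs <- function(records, thresholds = homolog_thresholds()) {
  stopifnot(inherits(thresholds, "homolog_thresholds"))
  keep <- records$identity >= thresholds$identity_min &
    records$sw_score >= thresholds$sw_min
  records[keep, , drop = FALSE]
}

#' PAI from a best-similarity table
#'
#' Filters the gene's similarity records by the thresholds, collapses the
#' passing records to their species set (a species with several passing
#' homologs counts once) and computes the phylostratigraphic age index.
#'
#' @param gene Gene identifier; all \code{records} must have this gene as
#'   their query.
#' @param records Data frame of similarity records for the gene.
#' @param thresholds A \code{\link{homolog_thresholds}} object.
#' @param table A \code{taxonomy_table}.
#' @param target Species code of the species under study.
#' @param strict Passed to \code{\link{pai}}.
#' @return A \code{phylostratum_assignment} with method \code{"BST"}.
#' @export
pai_bst <- function(gene, records, thresholds = homolog_thresholds(),
                    table, target, strict = FALSE) {
  if (nrow(records) && any(records$query_gene != gene))
    stop("records contain queries other than gene '", gene, "'",
         call. = FALSE)
  passing <- filter_homologs(records, thresholds)
  pai(target, unique(passing$subject_species), table, strict = strict,
      gene = gene, method = "BST")
}
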