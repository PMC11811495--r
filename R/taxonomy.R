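#' Construct a taxonomy table
#'
#' A taxonomy table maps short species codes (KEGG-style, e.g. \code{"hsa"})
#' to taxonomic lineages: ordered vectors of taxon names running from the
#' root of the taxonomy (index 1) down to the terminal species taxon.
#' Lineages are matched as name-prefix paths; ranks are not assumed to be
#' uniform across species. The table is the coordinate system in which the
#' phylostratigraphic age index (PAI) is a depth.
#'
#' @param lineages Named list. Names are species codes; each element is a
#'   character vector of taxon names ordered root to species.
#' @return An object of class \code{taxonomy_table}.
#' @examples
#' tab <- taxonomy_table(list(
#'   hsa = c("Root", "Eukaryota", "Metazoa", "Mammalia",
#'           "Primates", "Homo", "Homo sapiens"),
#'   mmu = c("Root", "Eukaryota", "Metazoa", "Mammalia",
#'           "Rodentia", "Mus", "Mus musculus")))
#' lca_depth(lineage(tab, "hsa"), lineage(tab, "mmu"))  # 4
#' @export
taxonomy_table <- function(lineages) {
  codes <- names(lineages)
  if (is.null(codes) || any(!nzchar(codes)))
    stop("every lineage must be named by a non-empty species code",
         call. = FALSE)
  dup <- codes[duplicated(codes)]
  if (length(dup))
    stop("duplicate species code: '", dup[1L], "'", call. = FALSE)
  for (code in codes) {
    lin <- lineages[[code]]
    if (!is.character(lin) || length(lin) < 1L || anyNA(lin) ||
        any(!nzchar(lin)))
      stop("empty lineage for species '", code, "'", call. = FALSE)
    if (anyDuplicated(lin))
      stop("duplicate taxon '", lin[duplicated(lin)][1L],
           "' within lineage of '", code, "'", call. = FALSE)
  }
  roots <- vapply(lineages, `[`, character(1L), 1L)
  if (length(unique(roots)) > 1L)
    stop("inconsistent root taxa across lineages: ",
         paste(sQuote(unique(roots)), collapse = ", "), call. = FALSE)
  structure(list(lineages = lineages), class = "taxonomy_table")
}

#' @export
print.taxonomy_table <- function(x, ...) {
  n <- length(x$lineages)
  depths <- vapply(x$lineages, length, integer(1L))
  cat(sprintf("taxonomy_table: %d species, depth %d-%d, root '%s'\n",
              n, min(depths), max(depths), x$lineages[[1L]][1L]))
  invisible(x)
}

#' Species codes of a taxonomy table
#' @param table A \code{taxonomy_table}.
#' @return Character vector of species codes.
#' @export
species_codes <- function(table) names(table$lineages)

#' Look up a lineage by species code
#' @param table A \code{taxonomy_table}.
#' @param code Species code.
#' @return Character vector of taxon names, root first.
#' @export
lineage <- function(table, code) {
  lin <- table$lineages[[code]]
  if (is.null(lin))
    stop("species '", code, "' not present in the taxonomy table",
         call. = FALSE)
  lin
}

#' Parse a taxonomic lineage table from TSV
#'
#' Reads a two-column tab-delimited file: species code, then the
#' semicolon-delimited lineage from the root to the species. Lines starting
#' with \code{#} and blank lines are ignored; no quoting is supported.
#' All rows must share the same root taxon.
#'
#' @param file Path to the TSV file (or a connection).
#' @return A \code{taxonomy_table}.
#' @export
parse_lineage_table <- function(file) {
  tsv <- read_tsv_lines(file)
  fields <- split_tsv(tsv$lines)
  lineages <- list()
  fname <- if (is.character(file)) file else "connection"
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    row <- tsv$rows[i]
    if (length(f) != 2L)
      stop_parse(fname, row, "expected 2 tab-separated columns")
    code <- trimws(f[1L])
    taxa <- trimws(strsplit(f[2L], ";", fixed = TRUE)[[1L]])
    taxa <- taxa[nzchar(taxa)]
    if (!nzchar(code))
      stop_parse(fname, row, "empty species code")
    if (!length(taxa))
      stop_parse(fname, row, sprintf("empty lineage for species '%s'", code))
    if (code %in% names(lineages))
      stop_parse(fname, row, sprintf("duplicate species code '%s'", code))
    if (length(lineages) && taxa[1L] != lineages[[1L]][1L])
      stop_parse(fname, row,
                 sprintf("root taxon '%s' inconsistent with '%s'",
                         taxa[1L], lineages[[1L]][1L]))
    lineages[[code]] <- taxa
  }
  taxonomy_table(lineages)
}

#' Write a taxonomy table as lineage TSV
#' @param table A \code{taxonomy_table}.
#' @param file Output path.
#' @return Invisibly, \code{file}.
#' @export
write_lineage_table <- function(table, file) {
  lines <- vapply(names(table$lineages), function(code)
    paste0(code, "\t", paste(table$lineages[[code]], collapse = ";")),
    character(1L))
  writeLines(lines, file)
  invisible(file)
}

#' Depth of the last common ancestor of two lineages
#'
#' Returns the 1-based length of the longest common prefix of the two
#' lineages, i.e. the depth (from the root, root = 1) of the most recent
#' common ancestor of the two species on the lineage tree.
#'
#' @param a,b Character vectors of taxon names (root first), as stored in a
#'   \code{taxonomy_table}.
#' @return Positive integer depth.
#' @export
lca_depth <- function(a, b) {
  if (!length(a) || !length(b))
    stop("lineages must be non-empty", call. = FALSE)
  if (a[1L] != b[1L])
    stop("lineages have different roots ('", a[1L], "' vs '", b[1L],
         "'): no common ancestor", call. = FALSE)
  n <- min(length(a), length(b))
  same <- a[seq_len(n)] == b[seq_len(n)]
  if (all(same)) n else which(!same)[1L] - 1L
}

#' Phylostratigraphic age index of a gene
#'
#' The PAI of a gene is the depth, counted from the root of the taxonomy
#' (root = 1), of the most recent common ancestor of the target species and
#' its most distantly related ortholog-bearing species. A gene whose
#' orthologs are confined to the target species receives the full lineage
#' length (evolutionarily youngest); smaller PAI means older.
#'
#' @param target Species code of the species under study; always treated as
#'   an implicit member of \code{ortholog_species}.
#' @param ortholog_species Character vector of species codes in which
#'   orthologs of the gene were found.
#' @param table A \code{taxonomy_table}.
#' @param strict If \code{TRUE}, a non-target species missing from the
#'   taxonomy is an error; otherwise it is skipped with a warning and
#'   recorded in \code{skipped_species}.
#' @param gene Optional gene identifier carried into the result.
#' @param method Provenance tag, \code{"KO"} or \code{"BST"}.
#' @return An object of class \code{phylostratum_assignment} with fields
#'   \code{gene_id}, \code{pai}, \code{method}, \code{most_distant_species}
#'   (lexicographically smallest code attaining the minimum depth) and
#'   \code{skipped_species}.
#' @export
pai <- function(target, ortholog_species, table, strict = FALSE,
                gene = NA_character_, method = c("KO", "BST")) {
  method <- match.arg(method)
  target_lin <- lineage(table, target)  # errors if target missing
  species <- unique(c(target, ortholog_species))
  known <- species %in% species_codes(table)
  skipped <- character(0L)
  if (any(!known)) {
    missing <- species[!known]
    if (strict)
      stop("species not in taxonomy table: ",
           paste(sQuote(missing), collapse = ", "), call. = FALSE)
    warning("skipping ", length(missing),
            " species absent from the taxonomy table: ",
            paste(missing, collapse = ", "), call. = FALSE)
    skipped <- sort(missing)
    species <- species[known]
  }
  depths <- vapply(species, function(s)
    lca_depth(target_lin, lineage(table, s)), integer(1L))
  d <- min(depths)
  attaining <- sort(species[depths == d])
  structure(list(gene_id = gene,
                 pai = as.integer(d),
                 method = method,
                 most_distant_species = attaining[1L],
                 skipped_species = skipped),
            class = "phylostratum_assignment")
}

#' @export
print.phylostratum_assignment <- function(x, ...) {
  cat(sprintf("PAI = %d (%s method; most distant ortholog in '%s')\n",
              x$pai, x$method, x$most_distant_species))
  if (length(x$skipped_species))
    cat("  skipped species:", paste(x$skipped_species, collapse = ", "), "\n")
  invisible(x)
}
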