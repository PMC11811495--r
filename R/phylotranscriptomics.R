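#' Construct an expression matrix
#'
#' Normalised, non-negative expression values: one row per gene, one column
#' per condition. No internal normalisation is applied; values are used as
#' weights exactly as supplied.
#'
#' @param values Numeric matrix (genes x conditions) with unique, non-empty
#'   row names (gene ids) and at least one named column (condition labels).
#' @return An object of class \code{expression_matrix}.
#' @export
expression_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)) ||
      any(!nzchar(rownames(values))))
    stop("gene ids (row names) must be unique and non-empty", call. = FALSE)
  if (ncol(values) < 1L || is.null(colnames(values)))
    stop("at least one named condition column is required", call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0))
    stop("expression values must be finite and non-negative", call. = FALSE)
  structure(list(genes = rownames(values), conditions = colnames(values),
                 values = values),
            class = "expression_matrix")
}

#' Parse an expression matrix from TSV
#'
#' First column: gene ids; header row: condition labels. Tab-delimited, no
#' quoting.
#'
#' @param file Path to the TSV file.
#' @return An \code{expression_matrix}.
#' @export
parse_expression_matrix <- function(file) {
  df <- utils::read.delim(file, check.names = FALSE,
                          stringsAsFactors = FALSE)
  fname <- if (is.character(file)) file else "connection"
  if (ncol(df) < 2L)
    stop("expression table ", fname,
         " needs a gene column plus at least one condition column",
         call. = FALSE)
  genes <- as.character(df[[1L]])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(is.na(suppressWarnings(as.numeric(vals))) & !is.na(vals),
                 arr.ind = TRUE)
    stop(sprintf("non-numeric expression value at gene '%s', condition '%s'",
                 genes[bad[1L, 1L]], colnames(vals)[bad[1L, 2L]]),
         call. = FALSE)
  }
  rownames(vals) <- genes
  expression_matrix(vals)
}

# Shared core of TAI and TDI: expression-weighted mean of a per-gene index.
weighted_index <- function(index_by_gene, expr, strict, what) {
  if (!length(expr) || is.null(names(expr)))
    stop("expression column must be a named numeric vector", call. = FALSE)
  common <- intersect(names(expr), names(index_by_gene))
  usable <- common[!is.na(index_by_gene[common])]
  dropped <- setdiff(names(expr), usable)
  if (length(dropped)) {
    if (strict)
      stop(length(dropped), " expressed gene(s) lack a ", what,
           " value: ", paste(utils::head(dropped, 5L), collapse = ", "),
           call. = FALSE)
    message("dropping ", length(dropped), " expressed gene(s) without a ",
            what, " value")
  }
  if (!length(usable))
    return(list(value = NA_real_, n_used = 0L, reason = paste0("no_", what)))
  e <- expr[usable]
  tot <- sum(e)
  if (tot == 0)
    return(list(value = NA_real_, n_used = 0L,
                reason = "zero_total_expression"))
  list(value = sum(index_by_gene[usable] * e) / tot,
       n_used = length(usable), reason = NA_character_)
}

#' Transcriptome age index of one condition
#'
#' The TAI is the expression-weighted mean phylostratigraphic age:
#' \deqn{TAI = \sum_i ps_i e_i / \sum_i e_i} over the genes present in both
#' inputs, where \eqn{ps_i} is gene i's PAI and \eqn{e_i} its expression
#' under the condition. Higher TAI means a larger contribution from
#' evolutionarily younger genes. Expressed genes without a PAI are dropped
#' with a message (or an error when \code{strict}).
#'
#' @param pai_by_gene Named numeric/integer vector: gene id to PAI.
#' @param expr Named numeric vector: one expression column.
#' @param strict Error instead of dropping genes without a PAI.
#' @return List with \code{value} (\code{NA} when undefined), \code{n_used}
#'   and \code{reason} (why the value is undefined, else \code{NA}).
#' @export
tai <- function(pai_by_gene, expr, strict = FALSE) {
  weighted_index(pai_by_gene, expr, strict, "PAI")
}

#' Transcriptome divergence index of one condition
#'
#' The TDI is the expression-weighted mean divergence index:
#' \deqn{TDI = \sum_i DI_i e_i / \sum_i e_i}; higher TDI means a larger
#' contribution from more variable (less conserved) genes.
#'
#' @inheritParams tai
#' @param di_by_gene Named numeric vector: gene id to DI.
#' @return As \code{\link{tai}}.
#' @export
tdi <- function(di_by_gene, expr, strict = FALSE) {
  weighted_index(di_by_gene, expr, strict, "DI")
}

#' Condition-wise TAI/TDI profile
#'
#' Computes TAI and TDI for every condition of an expression matrix, in
#' input column order. A condition where the index is undefined (e.g. all
#' zero expression) yields an \code{NA} cell, not an error.
#'
#' @param matrix An \code{\link{expression_matrix}}.
#' @param pai_by_gene Named vector of PAIs (or \code{NULL} to leave TAI
#'   \code{NA}).
#' @param di_by_gene Named vector of DIs (or \code{NULL} to leave TDI
#'   \code{NA}).
#' @param strict Passed to \code{\link{tai}}/\code{\link{tdi}}.
#' @return Data frame with columns \code{Data}, \code{TAI}, \code{TDI},
#'   \code{n_genes_used_tai}, \code{n_genes_used_tdi} (one row per
#'   condition).
#' @export
phylo_profile <- function(matrix, pai_by_gene = NULL, di_by_gene = NULL,
                          strict = FALSE) {
  stopifnot(inherits(matrix, "expression_matrix"))
  rows <- lapply(matrix$conditions, function(cond) {
    expr <- stats::setNames(matrix$values[, cond], matrix$genes)
    a <- if (is.null(pai_by_gene)) list(value = NA_real_, n_used = 0L)
         else tai(pai_by_gene, expr, strict)
    d <- if (is.null(di_by_gene)) list(value = NA_real_, n_used = 0L)
         else tdi(di_by_gene, expr, strict)
    data.frame(Data = cond, TAI = a$value, TDI = d$value,
               n_genes_used_tai = a$n_used, n_genes_used_tdi = d$n_used,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a TAI/TDI profile as TSV
#'
#' Three tab-separated columns with header \code{Data}, \code{TAI},
#' \code{TDI}; undefined cells are rendered as the literal \code{NA}.
#'
#' @param profile Data frame from \code{\link{phylo_profile}}.
#' @param file Output path.
#' @return Invisibly, \code{file}.
#' @export
write_profile <- function(profile, file) {
  lines <- c("Data\tTAI\tTDI",
             vapply(seq_len(nrow(profile)), function(i)
               paste(profile$Data[i], na_cell(profile$TAI[i]),
                     na_cell(profile$TDI[i]), sep = "\t"),
               character(1L)))
  writeLines(lines, file)
  invisible(file)
}
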