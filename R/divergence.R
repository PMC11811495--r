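# NG86 codon counting with Jukes-Cantor correction, comparison-set
# selection by taxonomic depth, and the per-gene divergence index.

NT <- c("A", "C", "G", "T")

# Codon lookup tables, built once at load from the standard genetic code
# (translation table 1). For each non-stop codon:
#   syn_sites    - number of synonymous sites (sum over the 3 positions of
#                  the fraction of the 3 possible changes that preserve the
#                  amino acid; changes to stop codons count as nonsynonymous)
#   syn_nbr      - single-nucleotide neighbours encoding the same amino acid
#   nonsyn_nbr   - non-stop neighbours encoding a different amino acid
codon_env <- new.env(parent = emptyenv())

codon_tables <- function() {
  if (!is.null(codon_env$tab)) return(codon_env$tab)
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)
  syn_sites <- numeric(length(codons))
  syn_nbr <- nonsyn_nbr <- vector("list", length(codons))
  names(syn_sites) <- names(syn_nbr) <- names(nonsyn_nbr) <- codons
  for (cod in codons) {
    if (gc[[cod]] == "*") next
    chars <- strsplit(cod, "")[[1L]]
    s <- 0; sn <- character(0L); nn <- character(0L)
    for (pos in 1:3) for (nt in setdiff(NT, chars[pos])) {
      mut <- chars; mut[pos] <- nt
      mutc <- paste(mut, collapse = "")
      if (gc[[mutc]] == gc[[cod]]) {
        s <- s + 1 / 3
        sn <- c(sn, mutc)
      } else if (gc[[mutc]] != "*") {
        nn <- c(nn, mutc)
      }
    }
    syn_sites[[cod]] <- s
    syn_nbr[[cod]] <- sn
    nonsyn_nbr[[cod]] <- nn
  }
  codon_env$tab <- list(code = gc, syn_sites = syn_sites,
                        syn_nbr = syn_nbr, nonsyn_nbr = nonsyn_nbr,
                        stops = codons[gc == "*"])
  codon_env$tab
}

#' Construct a codon sequence
#'
#' An in-frame coding sequence over \{A, C, G, T\}: length divisible by
#' three and no internal stop codon under the standard genetic code. A
#' terminal stop codon is accepted (and ignored by \code{\link{ng86_pair}}).
#'
#' @param gene_id Gene identifier.
#' @param species_code Species code.
#' @param nt Nucleotide string.
#' @return An object of class \code{codon_sequence}.
#' @export
codon_sequence <- function(gene_id, species_code, nt) {
  nt <- toupper(nt)
  chars <- strsplit(nt, "")[[1L]]
  if (!length(chars))
    stop("empty coding sequence for gene '", gene_id, "'", call. = FALSE)
  bad <- which(!(chars %in% NT))
  if (length(bad))
    stop("non-ACGT symbol '", chars[bad[1L]], "' at position ", bad[1L],
         " in gene '", gene_id, "'", call. = FALSE)
  if (length(chars) %% 3L != 0L)
    stop("sequence length ", length(chars), " of gene '", gene_id,
         "' is not divisible by 3", call. = FALSE)
  codons <- substring(nt, seq(1L, nchar(nt), 3L), seq(3L, nchar(nt), 3L))
  tab <- codon_tables()
  internal <- codons[-length(codons)]
  if (any(internal %in% tab$stops))
    stop("internal stop codon in gene '", gene_id, "' (codon ",
         which(internal %in% tab$stops)[1L], ")", call. = FALSE)
  structure(list(gene_id = gene_id, species_code = species_code,
                 nt = nt, codons = codons),
            class = "codon_sequence")
}

# Average synonymous/nonsynonymous substitution counts between two codons,
# over all substitution pathways; pathways passing through a stop codon are
# excluded. If every pathway is blocked by a stop, the average over all
# pathways is used instead (stop-crossing steps scored by amino-acid
# change as usual).
codon_path_diffs <- function(c1, c2, tab = codon_tables()) {
  if (c1 == c2) return(c(syn = 0, nonsyn = 0))
  x <- strsplit(c1, "")[[1L]]
  y <- strsplit(c2, "")[[1L]]
  pos <- which(x != y)
  paths <- if (length(pos) == 1L) list(pos) else
    apply(permn_matrix(length(pos)), 1L, function(p) pos[p], simplify = FALSE)
  score_path <- function(p) {
    cur <- x; syn <- 0; nonsyn <- 0; blocked <- FALSE
    for (k in p) {
      nxt <- cur; nxt[k] <- y[k]
      from <- paste(cur, collapse = ""); to <- paste(nxt, collapse = "")
      if (tab$code[[to]] == "*" && !identical(to, c2)) blocked <- TRUE
      if (tab$code[[from]] == tab$code[[to]]) syn <- syn + 1
      else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    c(syn = syn, nonsyn = nonsyn, blocked = as.numeric(blocked))
  }
  scored <- vapply(paths, score_path, numeric(3L))
  open <- scored[, scored["blocked", ] == 0, drop = FALSE]
  use <- if (ncol(open)) open else scored
  c(syn = mean(use["syn", ]), nonsyn = mean(use["nonsyn", ]))
}

# All permutations of 1..n as rows (n <= 3 in practice).
permn_matrix <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permn_matrix(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, sub + (sub >= k))))
}

jc_correct <- function(p) {
  if (is.na(p) || p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

#' Pairwise dN/dS by Nei-Gojobori (1986) counting
#'
#' Counts synonymous and nonsynonymous sites and differences between two
#' codon-aligned sequences, applies the Jukes-Cantor multiple-hit
#' correction to each proportion, and reports the dN/dS ratio. Site counts
#' are per-codon fractions averaged over the two sequences; codons differing
#' at several positions are scored by averaging over all substitution
#' pathways, excluding pathways through stop codons. A shared terminal stop
#' codon is dropped before counting.
#'
#' The ratio is undefined (excluded) when dS = 0 (flag \code{"dS_zero"}) or
#' when either proportion reaches the Jukes-Cantor domain boundary p >= 3/4
#' (flag \code{"correction_out_of_range"}).
#'
#' @param a,b \code{\link{codon_sequence}} objects of equal length
#'   (codon-aligned, no indels).
#' @return An object of class \code{dnds_result}: \code{syn_sites} (S),
#'   \code{nonsyn_sites} (N), \code{syn_diffs} (Sd), \code{nonsyn_diffs}
#'   (Nd), \code{pS}, \code{pN}, \code{dS}, \code{dN}, \code{ratio},
#'   \code{excluded} (\code{NA}, \code{"dS_zero"} or
#'   \code{"correction_out_of_range"}) and \code{estimator}
#'   (\code{"NG86+JC69"}).
#' @export
ng86_pair <- function(a, b) {
  stopifnot(inherits(a, "codon_sequence"), inherits(b, "codon_sequence"))
  if (nchar(a$nt) != nchar(b$nt))
    stop("sequences differ in length (", nchar(a$nt), " vs ", nchar(b$nt),
         "); codon-aligned input required", call. = FALSE)
  tab <- codon_tables()
  ca <- a$codons; cb <- b$codons
  # drop a terminal stop (if either sequence ends in one, drop the pair)
  nc <- length(ca)
  if (ca[nc] %in% tab$stops || cb[nc] %in% tab$stops) {
    ca <- ca[-nc]; cb <- cb[-nc]
    if (!length(ca))
      stop("no codons left after removing the terminal stop", call. = FALSE)
  }
  L <- 3L * length(ca)
  S <- (sum(tab$syn_sites[ca]) + sum(tab$syn_sites[cb])) / 2
  N <- L - S
  diffs <- vapply(seq_along(ca), function(i)
    codon_path_diffs(ca[i], cb[i], tab), numeric(2L))
  Sd <- sum(diffs["syn", ])
  Nd <- sum(diffs["nonsyn", ])
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  dS <- jc_correct(pS)
  dN <- jc_correct(pN)
  excluded <- NA_character_
  ratio <- NA_real_
  if ((!is.na(pS) && pS >= 0.75) || (!is.na(pN) && pN >= 0.75)) {
    excluded <- "correction_out_of_range"
  } else if (is.na(dS) || dS == 0) {
    excluded <- "dS_zero"
  } else {
    ratio <- dN / dS
  }
  structure(list(gene_a = a$gene_id, gene_b = b$gene_id,
                 species_a = a$species_code, species_b = b$species_code,
                 syn_sites = S, nonsyn_sites = N,
                 syn_diffs = Sd, nonsyn_diffs = Nd,
                 pS = pS, pN = pN, dS = dS, dN = dN,
                 ratio = ratio, excluded = excluded,
                 estimator = "NG86+JC69"),
            class = "dnds_result")
}

#' @export
print.dnds_result <- function(x, ...) {
  cat(sprintf("dN/dS (%s): S=%.3f N=%.3f Sd=%.3f Nd=%.3f dS=%s dN=%s\n",
              x$estimator, x$syn_sites, x$nonsyn_sites, x$syn_diffs,
              x$nonsyn_diffs, format(x$dS), format(x$dN)))
  if (is.na(x$excluded))
    cat(sprintf("  ratio = %.4f\n", x$ratio))
  else
    cat(sprintf("  ratio undefined (%s)\n", x$excluded))
  invisible(x)
}

#' Select comparison species by taxonomic depth or explicit list
#'
#' Either an explicit list of species codes is validated and returned, or a
#' taxonomic level \eqn{k} selects every species (other than the target)
#' whose lineage shares at least the first \eqn{L - k} taxa with the
#' target's lineage of length \eqn{L}. Level 1 restricts the comparison to
#' the target's genus; level 2 to its family; and so on up the lineage.
#'
#' @param target Species code of the species under study.
#' @param table A \code{taxonomy_table}.
#' @param level Positive integer taxonomic depth (mutually exclusive with
#'   \code{organisms}).
#' @param organisms Explicit character vector of species codes (mutually
#'   exclusive with \code{level}).
#' @return Sorted character vector of species codes, never including the
#'   target.
#' @export
select_comparison_species <- function(target, table, level = NULL,
                                      organisms = NULL) {
  if (is.null(level) == is.null(organisms))
    stop("exactly one of 'level' and 'organisms' must be given",
         call. = FALSE)
  target_lin <- lineage(table, target)
  if (!is.null(organisms)) {
    unknown <- setdiff(organisms, species_codes(table))
    if (length(unknown))
      stop("unknown species code(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    return(sort(setdiff(unique(organisms), target)))
  }
  L <- length(target_lin)
  if (level < 1L || level >= L)
    stop("level must be between 1 and ", L - 1L,
         " for a target lineage of length ", L, call. = FALSE)
  others <- setdiff(species_codes(table), target)
  shared <- vapply(others, function(s)
    lca_depth(target_lin, lineage(table, s)), integer(1L))
  sort(others[shared >= L - level])
}

#' Divergence index of a gene
#'
#' The DI is the arithmetic mean of the defined dN/dS ratios between the
#' target sequence and each homolog; with a single homolog it equals that
#' pair's ratio. Pairs whose ratio is undefined (dS = 0 or Jukes-Cantor
#' out of range) are excluded from the mean and counted.
#'
#' @param target A \code{\link{codon_sequence}}.
#' @param homologs List of \code{codon_sequence} objects, each codon-aligned
#'   to the target.
#' @return An object of class \code{divergence_index}: \code{gene_id},
#'   \code{di} (\code{NA} when no pair has a defined ratio),
#'   \code{n_pairs_used}, \code{n_pairs_excluded} and \code{pairs} (the list
#'   of \code{dnds_result}s).
#' @export
divergence_index <- function(target, homologs) {
  stopifnot(inherits(target, "codon_sequence"))
  pairs <- lapply(homologs, function(h) ng86_pair(target, h))
  ratios <- vapply(pairs, `[[`, numeric(1L), "ratio")
  used <- !is.na(ratios)
  structure(list(gene_id = target$gene_id,
                 di = if (any(used)) mean(ratios[used]) else NA_real_,
                 n_pairs_used = sum(used),
                 n_pairs_excluded = sum(!used),
                 pairs = pairs),
            class = "divergence_index")
}

#' @export
print.divergence_index <- function(x, ...) {
  cat(sprintf("DI(%s) = %s  [%d pair(s) used, %d excluded]\n",
              x$gene_id, if (is.na(x$di)) "NA" else sprintf("%.4f", x$di),
              x$n_pairs_used, x$n_pairs_excluded))
  invisible(x)
}

#' Read coding sequences from FASTA
#'
#' Headers must follow the \code{"species_code|gene_id"} convention.
#' Sequences are validated as in-frame CDS (see
#' \code{\link{codon_sequence}}).
#'
#' @param file Path to a FASTA file of in-frame coding sequences.
#' @return Named list of \code{codon_sequence} objects (names are the FASTA
#'   headers).
#' @export
read_cds_fasta <- function(file) {
  set <- Biostrings::readDNAStringSet(file)
  ids <- strsplit(names(set), "|", fixed = TRUE)
  if (any(lengths(ids) != 2L))
    stop("FASTA headers must follow 'species_code|gene_id'", call. = FALSE)
  out <- lapply(seq_along(set), function(i)
    codon_sequence(gene_id = ids[[i]][2L], species_code = ids[[i]][1L],
                   nt = as.character(set[[i]])))
  names(out) <- names(set)
  out
}
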